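# Small in-code fixtures shared across the suite.

# three biallelic SNPs with fixed, distinct flanks
tiny_library <- function() {
  reel_library(rbind(
    snp_record("rs1", c("A", "G"), "A", strrep("C", 15), strrep("T", 15),
               locus = "L1"),
    snp_record("rs2", c("C", "T"), "T", strrep("A", 15), strrep("G", 15),
               locus = "L1"),
    snp_record("rs3", c("G", "C"), "G",
               "ACGTACGTACGTACG", "TGCATGCATGCATGC", locus = "L2")
  ))
}

# a reel_counts with constant count `fill` everywhere, for hand-editing
flat_counts <- function(lib = tiny_library(), fill = 10,
                        cycles = c(1, 4, 7, 10), replicates = 1:5) {
  reg <- library_regions(lib)
  labels <- count_labels(cycles = cycles, replicates = replicates)
  m <- matrix(fill, nrow(reg), nrow(labels))
  reel_counts(m, reg[, c("snp_id", "allele", "is_risk")], labels)
}

# peptide-count table builder: rows named, 2 replicate columns per bait
peptide_table <- function(rows, baits = c("baitA", "baitB", "baitC")) {
  m <- do.call(rbind, rows)
  colnames(m) <- paste0(rep(baits, each = 2), "_", 1:2)
  peptide_counts(m)
}
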