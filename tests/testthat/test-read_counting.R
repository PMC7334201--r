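# helper: write a FASTQ from bare read strings
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- paste0("r", seq_along(reads))
  Biostrings::writeXStringSet(x, path, format = "fastq")
  path
}

small_barcodes <- function(lib_labels) {
  make_barcode_map(lib_labels, barcode_length = 6, seed = 31)
}

test_that("reads are assigned only on exact barcode, primer and 31-mer match", {
  lib <- tiny_library()
  labels <- count_labels(cycles = c(1, 4, 7, 10), replicates = 1:5)
  bc <- small_barcodes(labels)
  snp <- lib$records[1, ]
  good <- paste0(bc$barcode[1], assemble_construct(lib, snp, "A"))
  # one mismatch inside the 31-mer
  region_bad <- good
  substr(region_bad, 6 + 22 + 16, 6 + 22 + 16) <- "T"  # SNP position -> T (not an allele here? T not in {A,G} for rs1)
  primer_bad <- good
  substr(primer_bad, 7, 7) <- ifelse(substr(good, 7, 7) == "A", "C", "A")
  unused_bc <- setdiff(c("AAAAAA", "TTTTTT", "ACACAC"), bc$barcode)[1]
  barcode_bad <- paste0(unused_bc, assemble_construct(lib, snp, "G"))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(c(good, region_bad, primer_bad, barcode_bad), fq)
  x <- count_reads(fq, bc, lib, orient = "forward")
  expect_equal(unname(x$counts["rs1|A", bc$label[1]]), 1)
  expect_equal(sum(x$counts), 1)
  st <- x$stats[x$stats$label == bc$label[1], ]
  expect_equal(st$region_mismatch, 1)
  expect_equal(st$primer_mismatch, 1)
  bad_bc <- attr(x$stats, "bad_barcode_reads")
  expect_true(bad_bc >= 1)
  # read conservation: assigned + discarded = total input reads
  expect_equal(sum(x$stats$total_reads) + bad_bc, 4)
})

test_that("reverse-complement reads are accepted only when enabled", {
  lib <- tiny_library()
  bc <- small_barcodes(count_labels())
  fwd_read <- paste0(bc$barcode[3], assemble_construct(lib, lib$records[2, ], "T"))
  rc_read <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd_read)))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(c(fwd_read, rc_read), fq)
  both <- count_reads(fq, bc, lib, orient = "both")
  expect_equal(unname(both$counts["rs2|T", bc$label[3]]), 2)
  fwd_only <- count_reads(fq, bc, lib, orient = "forward")
  expect_equal(unname(fwd_only$counts["rs2|T", bc$label[3]]), 1)
  expect_equal(attr(fwd_only$stats, "bad_barcode_reads"), 1)
})

test_that("counting emitted error-free FASTQ is the identity on counts", {
  lib <- random_library(20, seed = 33)
  cfg <- simulation_config(n_snps = 20, depth = 2000, seed = 34)
  sim <- simulate_screen(lib, cfg)
  bc <- make_barcode_map(sim$counts$labels, seed = 35)
  fq <- withr::local_tempfile(fileext = ".fastq.gz")
  emit_fastq(sim$counts, lib, bc, fq)
  x <- count_reads(fq, bc, lib)
  expect_equal(unname(x$counts[rownames(sim$counts$counts),
                               colnames(sim$counts$counts)]) * 1,
               unname(sim$counts$counts) * 1)
  expect_equal(match_rate(x)$overall, 1)
})

test_that("per-base errors reduce the perfect-match rate as (1-e)^L", {
  lib <- random_library(20, seed = 36)
  cfg <- simulation_config(n_snps = 20, depth = 2500, seed = 37)
  sim <- simulate_screen(lib, cfg)   # 1e5 reads over 40 libraries
  bc <- make_barcode_map(sim$counts$labels, seed = 38)
  fq <- withr::local_tempfile(fileext = ".fastq.gz")
  e <- 0.01
  emit_fastq(sim$counts, lib, bc, fq, error_rate = e, seed = 39)
  x <- count_reads(fq, bc, lib)
  rate <- match_rate(x)$overall
  read_len <- 8 + 22 + 31 + 22
  expect_lt(rate, 1)
  expect_equal(rate, (1 - e)^read_len, tolerance = 0.02)
  # discard reasons are tallied
  expect_gt(sum(x$stats$primer_mismatch) + sum(x$stats$region_mismatch) +
              attr(x$stats, "bad_barcode_reads"), 0)
})

test_that("match_rate requires reads and barcode maps must be prefix-free", {
  lib <- tiny_library()
  bc <- small_barcodes(count_labels())
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0), fq)
  x <- count_reads(fq, bc, lib)
  expect_error(match_rate(x), "no reads")
  bad_bc <- bc
  bad_bc$barcode[2] <- paste0(bad_bc$barcode[1], "AC")
  expect_error(count_reads(fq, bad_bc, lib), "prefix")
  expect_error(count_reads(fq, bc[0, ], lib), "empty barcode map")
})

test_that("completeness QC keeps a SNP only if every allele covers all libraries", {
  x <- flat_counts(fill = 5)
  res <- qc_complete(x)
  expect_equal(nrow(res$dropped), 0)
  expect_equal(nrow(res$counts$counts), nrow(x$counts))

  # zero out the rs1 risk allele in control replicate 3 at cycle 7
  x2 <- x
  x2$counts["rs1|A", "c7_control_r3"] <- 0
  res2 <- qc_complete(x2)
  expect_equal(res2$dropped$snp_id, "rs1")
  expect_equal(res2$dropped$allele, "A")
  expect_equal(res2$dropped$label, "c7_control_r3")
  expect_false("rs1" %in% res2$counts$seq_info$snp_id)
  expect_true(all(c("rs2", "rs3") %in% res2$counts$seq_info$snp_id))

  # min_count threshold is configurable
  expect_equal(nrow(qc_complete(x, min_count = 6)$counts$counts), 0)

  # monotone: adding reads never drops a retained SNP
  x3 <- x2
  x3$counts <- x2$counts + 3
  expect_equal(nrow(qc_complete(x3)$dropped), 0)
})

test_that("count matrix long-TSV round trip preserves counts and stats", {
  lib <- random_library(10, seed = 41)
  cfg <- simulation_config(n_snps = 10, depth = 1000, seed = 42)
  sim <- simulate_screen(lib, cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(sim$counts, path)
  x <- read_counts(path)
  expect_equal(x$counts[rownames(sim$counts$counts),
                        colnames(sim$counts$counts)],
               sim$counts$counts)
  expect_equal(x$seq_info, sim$counts$seq_info)
})
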