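# Representation of a Reel-seq SNP library: 31-bp SNP-centered variable
# regions (15-nt flanks either side of a single-nucleotide variant) placed
# between two constant amplification primers.

#' Default amplification primers
#'
#' The screened construct is `fwd_primer + 31-bp variable region + rev_primer`.
#' With the default 22-nt primers the unshifted construct is 75 bp, the band
#' length recovered from the native gel at each selection cycle. Primer
#' sequences are configuration, not biology: any pair may be supplied to
#' [reel_library()].
#'
#' @return A single DNA string.
#' @export
default_fwd_primer <- function() "GTTCAGAGTTCTACAGTCCGAC"

#' @rdname default_fwd_primer
#' @export
default_rev_primer <- function() "TGGAATTCTCGGGTGCCAAGGT"

VARIABLE_REGION_LEN <- 31L
FLANK_LEN <- 15L

is_dna <- function(x) {
  !is.na(x) & nchar(x) > 0 & !grepl("[^ACGT]", x)
}

#' Create a single SNP record
#'
#' A record holds everything needed to synthesize the allele-specific
#' variable regions for one SNP: 15-nt flanks on both sides and 2--4 distinct
#' single-nucleotide alleles, one of which is designated the risk allele.
#' The SNP always sits at position 16 (1-based) of the 31-nt variable region.
#'
#' @param snp_id SNP identifier (typically an rsID); must be unique within a
#'   library.
#' @param alleles Character vector of 2--4 distinct single nucleotides from
#'   `A`, `C`, `G`, `T`.
#' @param risk_allele One of `alleles`.
#' @param flank5,flank3 15-nt DNA strings flanking the variant position.
#' @param locus Optional gene/locus label.
#'
#' @return A one-row `data.frame` with columns `snp_id`, `locus`, `alleles`
#'   (comma-joined), `risk_allele`, `flank5`, `flank3`.
#' @examples
#' snp_record("rs0001", c("A", "G"), "A",
#'            strrep("C", 15), strrep("T", 15))
#' @export
snp_record <- function(snp_id, alleles, risk_allele, flank5, flank3,
                       locus = NA_character_) {
  rec <- data.frame(
    snp_id = as.character(snp_id),
    locus = as.character(locus),
    alleles = paste(alleles, collapse = ","),
    risk_allele = as.character(risk_allele),
    flank5 = as.character(flank5),
    flank3 = as.character(flank3),
    stringsAsFactors = FALSE
  )
  validate_records(rec)
  rec
}

split_alleles <- function(x) strsplit(x, ",", fixed = TRUE)

validate_records <- function(records) {
  required <- c("snp_id", "alleles", "risk_allele", "flank5", "flank3")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("library records lack column(s): ", paste(missing, collapse = ", "))
  }
  if (!"locus" %in% names(records)) records$locus <- NA_character_
  al <- split_alleles(records$alleles)
  for (i in seq_len(nrow(records))) {
    id <- records$snp_id[i]
    a <- al[[i]]
    if (length(a) < 2 || length(a) > 4) {
      stop("row ", i, " (", id, "): expected 2-4 alleles, got ", length(a))
    }
    if (anyDuplicated(a) || !all(a %in% c("A", "C", "G", "T")) ||
        any(nchar(a) != 1)) {
      stop("row ", i, " (", id,
           "): alleles must be distinct single nucleotides in ACGT")
    }
    if (!records$risk_allele[i] %in% a) {
      stop("row ", i, " (", id, "): risk allele '", records$risk_allele[i],
           "' is not among alleles ", records$alleles[i])
    }
    for (fl in c("flank5", "flank3")) {
      f <- records[[fl]][i]
      if (!is_dna(f) || nchar(f) != FLANK_LEN) {
        stop("row ", i, " (", id, "): ", fl, " must be a ", FLANK_LEN,
             "-nt ACGT string")
      }
    }
  }
  dup <- records$snp_id[duplicated(records$snp_id)]
  if (length(dup) > 0) {
    stop("duplicate snp_id: ", paste(unique(dup), collapse = ", "))
  }
  invisible(records)
}

#' Assemble a SNP library
#'
#' Validates all record invariants and the library-wide requirement that
#' every allele-specific 31-mer is unique (exact-match read counting must be
#' unambiguous).
#'
#' @param records A `data.frame` of SNP records, one row per SNP, with the
#'   columns produced by [snp_record()] (rows may be `rbind`-ed records).
#' @param fwd_primer,rev_primer Constant primers flanking the variable
#'   region in the synthesized construct.
#'
#' @return An object of class `reel_library`.
#' @examples
#' lib <- reel_library(rbind(
#'   snp_record("rs1", c("A", "G"), "A", strrep("C", 15), strrep("T", 15)),
#'   snp_record("rs2", c("C", "T"), "T", strrep("A", 15), strrep("G", 15))
#' ))
#' enumerate_sequences(lib)
#' @export
reel_library <- function(records, fwd_primer = default_fwd_primer(),
                         rev_primer = default_rev_primer()) {
  if (!is.data.frame(records)) stop("records must be a data.frame")
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  rownames(records) <- NULL
  validate_records(records)
  for (p in list(fwd_primer, rev_primer)) {
    if (length(p) != 1 || (nchar(p) > 0 && !is_dna(p))) {
      stop("primers must be single (possibly empty) ACGT strings")
    }
  }
  lib <- structure(
    list(records = records, fwd_primer = fwd_primer, rev_primer = rev_primer),
    class = "reel_library"
  )
  regions <- library_regions(lib)
  dup <- duplicated(regions$region)
  if (any(dup)) {
    stop("variable regions are not unique across the library; first clash: ",
         regions$snp_id[dup][1], " allele ", regions$allele[dup][1])
  }
  lib
}

#' @export
print.reel_library <- function(x, ...) {
  n_al <- lengths(split_alleles(x$records$alleles))
  cat("reel_library:", nrow(x$records), "SNPs,", sum(n_al),
      "allele-specific sequences\n")
  cat("  construct length:",
      nchar(x$fwd_primer) + VARIABLE_REGION_LEN + nchar(x$rev_primer),
      "bp (primers", nchar(x$fwd_primer), "+ 31 +",
      nchar(x$rev_primer), ")\n")
  invisible(x)
}

get_record <- function(lib, snp_id) {
  i <- match(snp_id, lib$records$snp_id)
  if (is.na(i)) stop("unknown snp_id: ", snp_id)
  lib$records[i, , drop = FALSE]
}

#' Build the 31-nt variable region for one allele
#'
#' @param snp A one-row SNP record (see [snp_record()]).
#' @param allele A single nucleotide; must be one of the record's alleles.
#'
#' @return The 31-nt string `flank5 + allele + flank3`; the allele occupies
#'   position 16 (1-based).
#' @export
build_variable_region <- function(snp, allele) {
  alleles <- split_alleles(snp$alleles)[[1]]
  if (length(allele) != 1 || !allele %in% alleles) {
    stop("invalid allele '", allele, "' for ", snp$snp_id,
         " (alleles: ", snp$alleles, ")")
  }
  paste0(snp$flank5, allele, snp$flank3)
}

#' Assemble the full synthesized construct for one allele
#'
#' @inheritParams build_variable_region
#' @param lib A [reel_library()] (source of the constant primers).
#'
#' @return `fwd_primer + variable region + rev_primer`.
#' @export
assemble_construct <- function(lib, snp, allele) {
  paste0(lib$fwd_primer, build_variable_region(snp, allele), lib$rev_primer)
}

#' Count allele-specific sequences in a library
#'
#' The screened sequence count is the sum over SNPs of their allele numbers
#' (a biallelic SNP contributes 2, a tri-allelic 3, ...).
#'
#' @param lib A [reel_library()].
#' @return Integer count.
#' @export
enumerate_sequences <- function(lib) {
  sum(lengths(split_alleles(lib$records$alleles)))
}

#' Enumerate all allele-specific variable regions
#'
#' @param lib A [reel_library()].
#' @return A `data.frame` with one row per (SNP, allele): `snp_id`, `allele`,
#'   `is_risk`, `region` (the 31-mer).
#' @export
library_regions <- function(lib) {
  al <- split_alleles(lib$records$alleles)
  n <- lengths(al)
  idx <- rep(seq_len(nrow(lib$records)), n)
  allele <- unlist(al, use.names = FALSE)
  data.frame(
    snp_id = lib$records$snp_id[idx],
    allele = allele,
    is_risk = allele == lib$records$risk_allele[idx],
    region = paste0(lib$records$flank5[idx], allele, lib$records$flank3[idx]),
    stringsAsFactors = FALSE
  )
}

#' Read / write a library definition as TSV
#'
#' The on-disk format is a tab-separated table with header columns `snp_id`,
#' `locus`, `alleles` (comma-joined), `risk_allele`, `flank5`, `flank3`.
#' Loading re-validates every invariant and names the offending row on
#' failure; `load(write(lib))` is the identity.
#'
#' @param path File path.
#' @param fwd_primer,rev_primer Primers to attach on load (the TSV holds
#'   only the per-SNP fields).
#' @return `read_library()` returns a `reel_library`; `write_library()`
#'   returns `path` invisibly.
#' @export
read_library <- function(path, fwd_primer = default_fwd_primer(),
                         rev_primer = default_rev_primer()) {
  records <- utils::read.delim(path, colClasses = "character")
  reel_library(records, fwd_primer = fwd_primer, rev_primer = rev_primer)
}

#' @rdname read_library
#' @param lib A [reel_library()].
#' @export
write_library <- function(lib, path) {
  utils::write.table(lib$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export all allele constructs as FASTA
#'
#' Headers are `{snp_id}|{allele}|{risk|nonrisk}`.
#'
#' @param lib A [reel_library()].
#' @param path Output FASTA path.
#' @param full_construct If `TRUE` (default) write primer-flanked constructs,
#'   otherwise bare 31-mers.
#' @export
write_library_fasta <- function(lib, path, full_construct = TRUE) {
  reg <- library_regions(lib)
  seqs <- if (full_construct) {
    paste0(lib$fwd_primer, reg$region, lib$rev_primer)
  } else {
    reg$region
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- paste(reg$snp_id, reg$allele,
                    ifelse(reg$is_risk, "risk", "nonrisk"), sep = "|")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
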