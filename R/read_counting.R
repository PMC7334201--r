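# Exact-match amplicon counting: a read contributes iff its barcode matches
# a library barcode exactly and the 31-mer between the two constant primers
# equals a library variable region exactly. Everything else is discarded
# with a reason tally, so read conservation (assigned + discarded = total)
# holds per library.

DISCARD_REASONS <- c("bad_barcode", "primer_mismatch", "region_mismatch")

validate_barcode_map <- function(barcodes) {
  need <- c("barcode", "label", "cycle", "condition", "replicate")
  if (!all(need %in% names(barcodes))) {
    stop("barcode map lacks column(s): ",
         paste(setdiff(need, names(barcodes)), collapse = ", "))
  }
  if (nrow(barcodes) == 0) stop("empty barcode map")
  if (anyDuplicated(barcodes$barcode) || anyDuplicated(barcodes$label)) {
    stop("barcodes and labels must be unique")
  }
  bc <- barcodes$barcode
  for (i in seq_along(bc)) {
    pref <- startsWith(bc[-i], bc[i])
    if (any(pref)) {
      stop("barcode map is not prefix-free: '", bc[i], "' is a prefix of '",
           bc[-i][pref][1], "'")
    }
  }
  invisible(barcodes)
}

#' Read / write a barcode map as TSV
#'
#' Columns: `barcode`, `label`, `cycle`, `condition`, `replicate`.
#'
#' @param path TSV path.
#' @return `read_barcode_map()` returns the validated `data.frame`.
#' @export
read_barcode_map <- function(path) {
  bc <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(barcode = "character"))
  validate_barcode_map(bc)
}

#' @rdname read_barcode_map
#' @param barcodes Barcode map `data.frame` (see [make_barcode_map()]).
#' @export
write_barcode_map <- function(barcodes, path) {
  utils::write.table(barcodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Count barcoded reads against a library
#'
#' A read is assigned to a library iff one barcode matches its 5' end
#' exactly (the map must be prefix-free, so at most one can); the variable
#' region is then located by exact match of both constant primers and must
#' equal one of the library's 31-mers exactly. Reads failing any step are
#' tallied per library (or globally, for barcode failures) under the
#' reasons `bad_barcode`, `primer_mismatch`, `region_mismatch`.
#'
#' @param fastq Path(s) to single-end FASTQ files (plain or gzipped).
#' @param barcodes Barcode map (see [make_barcode_map()] /
#'   [read_barcode_map()]).
#' @param lib The [reel_library()] that defines primers and variable
#'   regions.
#' @param orient `"both"` (default) retries unassignable reads on their
#'   reverse complement; `"forward"` does not.
#' @return A [reel_counts()] whose `stats` carry per-library totals, matched
#'   counts and discard tallies; reads whose barcode matches nothing are
#'   reported on the attached `unassigned` attribute of `stats` via the
#'   `bad_barcode` column of an extra `<unassigned>` row.
#' @export
count_reads <- function(fastq, barcodes, lib, orient = c("both", "forward")) {
  orient <- match.arg(orient)
  validate_barcode_map(barcodes)
  reads <- unlist(lapply(fastq, function(f) {
    as.character(Biostrings::readDNAStringSet(f, format = "fastq",
                                              use.names = FALSE))
  }), use.names = FALSE)

  bc <- barcodes$barcode
  lib_of_read <- assign_barcodes(reads, bc)
  if (orient == "both" && anyNA(lib_of_read)) {
    flip <- which(is.na(lib_of_read))
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[flip])))
    rc_hit <- assign_barcodes(rc, bc)
    ok <- !is.na(rc_hit)
    reads[flip[ok]] <- rc[ok]
    lib_of_read[flip[ok]] <- rc_hit[ok]
  }

  reg <- library_regions(lib)
  n_seq <- nrow(reg)
  n_lib <- nrow(barcodes)
  counts <- matrix(0L, n_seq, n_lib)
  tally <- matrix(0L, n_lib, length(DISCARD_REASONS),
                  dimnames = list(barcodes$label, DISCARD_REASONS))
  n_bad_bc <- sum(is.na(lib_of_read))

  assigned <- which(!is.na(lib_of_read))
  if (length(assigned) > 0) {
    body <- substring(reads[assigned],
                      nchar(bc)[lib_of_read[assigned]] + 1L)
    vr <- locate_variable_region(body, lib$fwd_primer, lib$rev_primer)
    seq_i <- match(vr, reg$region)  # NA where no primer match or unknown 31-mer
    lib_i <- lib_of_read[assigned]
    good <- !is.na(seq_i)
    counts <- counts +
      unclass(table(factor(seq_i[good], levels = seq_len(n_seq)),
                    factor(lib_i[good], levels = seq_len(n_lib))))
    no_primer <- is.na(vr)
    tally[, "primer_mismatch"] <-
      tabulate(lib_i[no_primer], nbins = n_lib)
    tally[, "region_mismatch"] <-
      tabulate(lib_i[!no_primer & !good], nbins = n_lib)
  }

  labels <- barcodes[, c("label", "cycle", "condition", "replicate")]
  rownames(labels) <- NULL
  per_lib_total <- colSums(counts) + rowSums(tally)
  stats <- data.frame(
    label = labels$label,
    total_reads = per_lib_total,
    matched_reads = colSums(counts),
    as.data.frame(tally)
  )
  rownames(stats) <- NULL
  out <- reel_counts(counts, reg[, c("snp_id", "allele", "is_risk")],
                     labels, stats)
  attr(out$stats, "bad_barcode_reads") <- n_bad_bc
  attr(out$stats, "input_reads") <- length(reads)
  out
}

# index of the (prefix-free) barcode matching each read's 5' end, NA if none
assign_barcodes <- function(reads, bc) {
  hit <- rep(NA_integer_, length(reads))
  for (i in seq_along(bc)) {
    m <- is.na(hit) & startsWith(reads, bc[i])
    hit[m] <- i
  }
  hit
}

# extract the 31-mer bracketed by exact primer hits; NA where the primers
# are not found in that arrangement
locate_variable_region <- function(body, fwd, rev) {
  lf <- nchar(fwd)
  lr <- nchar(rev)
  if (lf > 0) {
    at <- regexpr(fwd, body, fixed = TRUE)
    start <- ifelse(at > 0, at + lf, NA_integer_)
  } else {
    start <- rep(1L, length(body))
  }
  vr <- substr(body, start, start + VARIABLE_REGION_LEN - 1L)
  if (lr > 0) {
    after <- substr(body, start + VARIABLE_REGION_LEN,
                    start + VARIABLE_REGION_LEN + lr - 1L)
    vr[is.na(start) | after != rev] <- NA_character_
  }
  vr[!is.na(vr) & nchar(vr) < VARIABLE_REGION_LEN] <- NA_character_
  vr
}

#' Perfect-match rate of a counted run
#'
#' @param x A [reel_counts()] from [count_reads()].
#' @return A list: `overall` (matched / total across all libraries,
#'   including reads whose barcode matched nothing) and `per_label`
#'   (`data.frame` of per-library rates).
#' @export
match_rate <- function(x) {
  bad_bc <- attr(x$stats, "bad_barcode_reads")
  if (is.null(bad_bc)) bad_bc <- 0
  total <- sum(x$stats$total_reads) + bad_bc
  if (total == 0) stop("match rate undefined: no reads")
  per <- data.frame(label = x$stats$label,
                    rate = ifelse(x$stats$total_reads > 0,
                                  x$stats$matched_reads / x$stats$total_reads,
                                  NA_real_))
  list(overall = sum(x$stats$matched_reads) / total, per_label = per)
}

#' Completeness quality control
#'
#' A SNP is retained iff every one of its alleles has at least `min_count`
#' reads in every library (all cycles, conditions and replicates), which
#' guarantees every downstream allele ratio is finite without pseudocounts.
#' Adding reads can never drop a retained SNP.
#'
#' @param x A [reel_counts()].
#' @param min_count Minimum count per (allele, library) cell (default 1).
#' @return A list: `counts` (the retained [reel_counts()]), `dropped`
#'   (`data.frame` of dropped `snp_id` with the first failing `allele` and
#'   `label`).
#' @export
qc_complete <- function(x, min_count = 1) {
  low <- x$counts < min_count
  bad_rows <- which(rowSums(low) > 0)
  bad_snps <- unique(x$seq_info$snp_id[bad_rows])
  dropped <- data.frame(snp_id = character(0), allele = character(0),
                        label = character(0))
  if (length(bad_snps) > 0) {
    first_bad <- vapply(bad_snps, function(id) {
      r <- intersect(which(x$seq_info$snp_id == id), bad_rows)[1]
      c(x$seq_info$allele[r], colnames(x$counts)[which(low[r, ])[1]])
    }, character(2))
    dropped <- data.frame(snp_id = bad_snps, allele = first_bad[1, ],
                          label = first_bad[2, ])
    rownames(dropped) <- NULL
  }
  keep <- !(x$seq_info$snp_id %in% bad_snps)
  kept <- reel_counts(x$counts[keep, , drop = FALSE],
                      x$seq_info[keep, , drop = FALSE],
                      x$labels, x$stats)
  list(counts = kept, dropped = dropped)
}

#' Write the per-library counting report
#'
#' @param x A [reel_counts()] from [count_reads()].
#' @param path TSV path.
#' @export
write_count_report <- function(x, path) {
  stats <- x$stats
  stats$match_rate <- ifelse(stats$total_reads > 0,
                             stats$matched_reads / stats$total_reads, NA)
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
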