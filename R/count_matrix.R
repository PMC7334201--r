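# The screen's central container: counts per (SNP, allele) sequence across
# the 40 sequenced libraries (cycle x condition x replicate).

#' Library labels for a screen layout
#'
#' @param cycles Sequenced cycles (default 1, 4, 7, 10).
#' @param conditions Condition names; `control` is buffer-only, `sample` is
#'   the nuclear-extract arm.
#' @param replicates Replicate indices per condition (default 1:5).
#' @return A `data.frame` with columns `label`, `cycle`, `condition`,
#'   `replicate`; with the defaults, 40 rows.
#' @export
count_labels <- function(cycles = c(1L, 4L, 7L, 10L),
                         conditions = c("control", "sample"),
                         replicates = 1:5) {
  g <- expand.grid(replicate = as.integer(replicates),
                   condition = conditions,
                   cycle = as.integer(cycles),
                   stringsAsFactors = FALSE)
  g <- g[, c("cycle", "condition", "replicate")]
  g$label <- sprintf("c%d_%s_r%d", g$cycle, g$condition, g$replicate)
  g[, c("label", "cycle", "condition", "replicate")]
}

#' Construct a count matrix
#'
#' @param counts Numeric matrix, one row per (SNP, allele) sequence and one
#'   column per library. Stochastic data are integer read counts; the
#'   simulator's deterministic (infinite-depth) mode stores expected counts,
#'   which need not be integers.
#' @param seq_info `data.frame` with columns `snp_id`, `allele`, `is_risk`,
#'   aligned with the rows of `counts`.
#' @param labels `data.frame` as from [count_labels()], aligned with the
#'   columns of `counts`.
#' @param stats Optional per-library read accounting (`label`, `total_reads`,
#'   `matched_reads`, and discard-reason tallies). When `NULL`, totals are
#'   taken as the column sums.
#' @return An object of class `reel_counts`.
#' @export
reel_counts <- function(counts, seq_info, labels, stats = NULL) {
  counts <- as.matrix(counts)
  if (nrow(seq_info) != nrow(counts)) {
    stop("seq_info rows must match count rows")
  }
  if (nrow(labels) != ncol(counts)) {
    stop("labels must match count columns")
  }
  if (anyDuplicated(labels$label)) stop("duplicate library labels")
  key <- paste(seq_info$snp_id, seq_info$allele, sep = "|")
  if (anyDuplicated(key)) stop("duplicate (snp_id, allele) rows")
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  rownames(counts) <- key
  colnames(counts) <- labels$label
  if (is.null(stats)) {
    stats <- data.frame(label = labels$label,
                        total_reads = colSums(counts),
                        matched_reads = colSums(counts))
  }
  if (any(stats$matched_reads > stats$total_reads)) {
    stop("matched_reads cannot exceed total_reads")
  }
  rownames(stats) <- NULL
  structure(list(counts = counts, seq_info = seq_info, labels = labels,
                 stats = stats),
            class = "reel_counts")
}

#' @export
print.reel_counts <- function(x, ...) {
  cat("reel_counts:", nrow(x$counts), "sequences x", ncol(x$counts),
      "libraries\n")
  cat("  cycles:", paste(sort(unique(x$labels$cycle)), collapse = ", "),
      " conditions:", paste(unique(x$labels$condition), collapse = ", "),
      " replicates:", max(x$labels$replicate), "\n")
  tot <- sum(x$stats$total_reads)
  cat("  reads: ", format(sum(x$stats$matched_reads), big.mark = ","),
      " matched of ", format(tot, big.mark = ","), " total\n", sep = "")
  invisible(x)
}

label_cols <- function(x, cycle, condition) {
  sel <- x$labels$cycle == cycle & x$labels$condition == condition
  x$labels$label[sel][order(x$labels$replicate[sel])]
}

seq_key <- function(snp_id, allele) paste(snp_id, allele, sep = "|")

#' Read / write a count matrix as long-format TSV
#'
#' Columns: `snp_id`, `allele`, `is_risk`, `cycle`, `condition`, `replicate`,
#' `count`. Per-library totals and discard tallies, if present, are written
#' alongside as `<path>.stats.tsv` and restored on read.
#'
#' @param x A `reel_counts`.
#' @param path TSV path.
#' @return `read_counts()` returns a `reel_counts`; `write_counts()` returns
#'   `path` invisibly.
#' @export
write_counts <- function(x, path) {
  long <- data.frame(
    snp_id = rep(x$seq_info$snp_id, times = ncol(x$counts)),
    allele = rep(x$seq_info$allele, times = ncol(x$counts)),
    is_risk = rep(x$seq_info$is_risk, times = ncol(x$counts)),
    cycle = rep(x$labels$cycle, each = nrow(x$counts)),
    condition = rep(x$labels$condition, each = nrow(x$counts)),
    replicate = rep(x$labels$replicate, each = nrow(x$counts)),
    count = as.vector(x$counts)
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$stats, paste0(path, ".stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "allele", "is_risk", "cycle", "condition", "replicate",
            "count")
  if (!all(need %in% names(long))) {
    stop("count TSV lacks column(s): ",
         paste(setdiff(need, names(long)), collapse = ", "))
  }
  lab <- sprintf("c%d_%s_r%d", long$cycle, long$condition, long$replicate)
  labels <- unique(data.frame(label = lab, cycle = long$cycle,
                              condition = long$condition,
                              replicate = long$replicate))
  rownames(labels) <- NULL
  key <- seq_key(long$snp_id, long$allele)
  seq_info <- unique(data.frame(snp_id = long$snp_id, allele = long$allele,
                                is_risk = long$is_risk))
  rownames(seq_info) <- NULL
  m <- matrix(0, nrow(seq_info), nrow(labels),
              dimnames = list(seq_key(seq_info$snp_id, seq_info$allele),
                              labels$label))
  m[cbind(match(key, rownames(m)), match(lab, labels$label))] <- long$count
  stats_path <- paste0(path, ".stats.tsv")
  stats <- if (file.exists(stats_path)) {
    utils::read.delim(stats_path, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  reel_counts(m, seq_info, labels, stats)
}
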