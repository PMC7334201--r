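# fSNP calling from a QC'd count matrix: per-replicate risk/non-risk ratios
# at the final cycle, two-sample Student's t test (control vs sample),
# normalized sample/control ratio trajectory over the sequenced cycles,
# least-squares slope, and the three-way candidate/putative/non-fSNP call.

#' Allele ratio
#'
#' Ratio of the risk-allele count to the non-risk-allele count. Orientation
#' is fixed (risk in the numerator): the sign of the downstream slope
#' depends on it.
#'
#' @param count_risk,count_nonrisk Non-negative counts (vectorized).
#' @return `count_risk / count_nonrisk`.
#' @export
allele_ratio <- function(count_risk, count_nonrisk) {
  if (any(count_nonrisk < 1)) {
    stop("non-risk allele count below 1; completeness QC should have ",
         "removed this SNP")
  }
  count_risk / count_nonrisk
}

#' Two-sample t test on final-cycle allele ratios
#'
#' Classic pooled-variance Student's t (two-tailed) comparing the
#' per-replicate allele ratios of the buffer controls with those of the
#' extract-treated samples; with five replicates each, df = 8. No
#' multiple-testing correction is applied. Degenerate inputs: if both
#' groups are constant, p is 1 when the constants agree and 0 (an underflow
#' sentinel for an infinite t) when they differ.
#'
#' @param control_ratios,sample_ratios Numeric vectors (length >= 2 each).
#' @param welch Use Welch's unequal-variance t instead (default `FALSE`).
#' @return Two-tailed p value.
#' @export
ttest_ratio <- function(control_ratios, sample_ratios, welch = FALSE) {
  if (length(control_ratios) < 2 || length(sample_ratios) < 2) {
    stop("each group needs at least 2 replicates")
  }
  if (stats::var(control_ratios) == 0 && stats::var(sample_ratios) == 0) {
    return(if (mean(control_ratios) == mean(sample_ratios)) 1 else 0)
  }
  stats::t.test(control_ratios, sample_ratios,
                var.equal = !welch)$p.value
}

#' Normalized sample/control ratio trajectory
#'
#' For each sequenced cycle: the mean of the five sample allele ratios
#' divided by the mean of the five control allele ratios. Equals 1 at every
#' cycle when nothing distinguishes the conditions, and follows
#' [expected_normalized_ratio()] in the noise-free limit.
#'
#' @param x A QC-passing [reel_counts()].
#' @param snp_id SNP to extract.
#' @param alleles Length-2 character vector `(risk, non-risk)`; by default
#'   the library's risk allele and the first non-risk allele.
#' @return Named numeric vector, one entry per sequenced cycle.
#' @export
normalized_trajectory <- function(x, snp_id, alleles = NULL) {
  rows <- which(x$seq_info$snp_id == snp_id)
  if (length(rows) == 0) stop("unknown snp_id: ", snp_id)
  if (is.null(alleles)) {
    alleles <- c(x$seq_info$allele[rows][x$seq_info$is_risk[rows]][1],
                 x$seq_info$allele[rows][!x$seq_info$is_risk[rows]][1])
  }
  r_risk <- rows[match(alleles[1], x$seq_info$allele[rows])]
  r_non <- rows[match(alleles[2], x$seq_info$allele[rows])]
  if (is.na(r_risk) || is.na(r_non)) {
    stop("alleles not found for ", snp_id)
  }
  cycles <- sort(unique(x$labels$cycle))
  out <- vapply(cycles, function(cyc) {
    ctrl <- label_cols(x, cyc, "control")
    samp <- label_cols(x, cyc, "sample")
    if (length(ctrl) == 0 || length(samp) == 0) {
      stop("incomplete data: cycle ", cyc, " lacks a condition")
    }
    mean(allele_ratio(x$counts[r_risk, samp], x$counts[r_non, samp])) /
      mean(allele_ratio(x$counts[r_risk, ctrl], x$counts[r_non, ctrl]))
  }, numeric(1))
  names(out) <- paste0("c", cycles)
  out
}

#' Least-squares slope of a normalized-ratio trajectory
#'
#' Ordinary least-squares slope of the normalized ratio against the cycle
#' number (x = 1, 4, 7, 10 by default, i.e. units of normalized ratio per
#' selection cycle). `slope_x = "rank"` regresses against the snapshot index
#' 1..4 instead.
#'
#' @param norm_ratio Finite positive trajectory values.
#' @param cycles Cycle numbers the values belong to.
#' @param slope_x `"cycle"` (default) or `"rank"`.
#' @return The fitted slope.
#' @export
fit_slope <- function(norm_ratio, cycles = c(1, 4, 7, 10),
                      slope_x = c("cycle", "rank")) {
  slope_x <- match.arg(slope_x)
  if (any(!is.finite(norm_ratio))) stop("non-finite trajectory value")
  x <- if (slope_x == "cycle") cycles else seq_along(cycles)
  unname(stats::coef(stats::lm(norm_ratio ~ x))[2])
}

# vectorized OLS slope for a matrix of trajectories (rows)
slope_matrix <- function(traj, x) {
  xc <- x - mean(x)
  as.vector((traj %*% xc) / sum(xc^2))
}

#' Classify a SNP from its p value and slope
#'
#' Empirical cutoffs: a candidate fSNP has p < `alpha` and |slope| >
#' `slope_cut`; a putative fSNP has p < `alpha` but |slope| <= `slope_cut`;
#' everything else (p >= `alpha`) is a non-fSNP. Inequalities are strict,
#' so p = alpha or |slope| = slope_cut falls in the weaker class.
#'
#' @param p_value,slope Numeric vectors (recycled).
#' @param alpha Significance cutoff (default 0.05, uncorrected).
#' @param slope_cut Absolute slope cutoff (default 0.05 per cycle).
#' @return Factor with levels `candidate`, `putative`, `non_fSNP`.
#' @export
classify_fsnp <- function(p_value, slope, alpha = 0.05, slope_cut = 0.05) {
  cls <- ifelse(p_value < alpha,
                ifelse(abs(slope) > slope_cut, "candidate", "putative"),
                "non_fSNP")
  factor(cls, levels = c("candidate", "putative", "non_fSNP"))
}

#' Replicate-correlation QC
#'
#' For each consecutive replicate pair (1/2, 2/3, ...), the squared Pearson
#' correlation of the per-SNP sample/control ratio-of-ratios at the given
#' cycle: for replicate i, each SNP contributes
#' (sample risk/non-risk ratio) / (control risk/non-risk ratio).
#'
#' @param x A QC-passing [reel_counts()].
#' @param cycle Cycle to evaluate (default 10).
#' @return Named numeric vector of R-squared values, one per consecutive
#'   pair.
#' @export
replicate_correlation <- function(x, cycle = 10) {
  if (!cycle %in% x$labels$cycle) stop("cycle ", cycle, " not present")
  pr <- snp_pairs(x$seq_info)
  pairs1 <- pr[!duplicated(pr$snp_id), ]  # one pair per SNP
  if (nrow(pairs1) < 2) stop("need at least 2 SNPs")
  ctrl <- label_cols(x, cycle, "control")
  samp <- label_cols(x, cycle, "sample")
  reps <- seq_along(ctrl)
  ratio_mat <- vapply(reps, function(i) {
    allele_ratio(x$counts[pairs1$risk_row, samp[i]],
                 x$counts[pairs1$non_row, samp[i]]) /
      allele_ratio(x$counts[pairs1$risk_row, ctrl[i]],
                   x$counts[pairs1$non_row, ctrl[i]])
  }, numeric(nrow(pairs1)))
  r2 <- vapply(seq_len(length(reps) - 1), function(i) {
    stats::cor(ratio_mat[, i], ratio_mat[, i + 1])^2
  }, numeric(1))
  names(r2) <- paste0("rep", seq_len(length(reps) - 1), "_",
                      seq_len(length(reps) - 1) + 1)
  r2
}

# all (risk allele, non-risk allele) row pairs; multi-allelic SNPs yield one
# pair per non-risk allele
snp_pairs <- function(seq_info) {
  risk_row <- which(seq_info$is_risk)
  names(risk_row) <- seq_info$snp_id[risk_row]
  non <- which(!seq_info$is_risk)
  data.frame(
    snp_id = seq_info$snp_id[non],
    risk_allele = unname(seq_info$allele[risk_row[seq_info$snp_id[non]]]),
    nonrisk_allele = seq_info$allele[non],
    risk_row = unname(risk_row[seq_info$snp_id[non]]),
    non_row = non,
    stringsAsFactors = FALSE
  )
}

#' Run the full fSNP screen analysis
#'
#' Applies completeness QC, then per SNP (risk allele against each non-risk
#' allele): five control and five sample allele ratios at the final
#' sequenced cycle, the two-tailed Student's t test, the normalized ratio
#' trajectory over all sequenced cycles, its least-squares slope, and the
#' candidate/putative/non-fSNP call. Multi-allelic SNPs get one result row
#' per allele pair and a SNP-level class equal to their strongest call.
#'
#' @param x A [reel_counts()].
#' @param alpha,slope_cut Classification cutoffs (see [classify_fsnp()]).
#' @param min_count Completeness-QC threshold (see [qc_complete()]).
#' @param slope_x Regressor for the slope fit (see [fit_slope()]).
#' @param test_cycle Cycle whose per-replicate ratios feed the t test
#'   (default: the last sequenced cycle).
#' @param welch Use Welch's t instead of pooled Student's t.
#' @param log_ratios Analyze log ratios instead of raw ratios (trajectory
#'   and t test); off by default.
#' @param adjust_p Add a Benjamini-Hochberg adjusted p column (the
#'   classification still uses the raw p, mirroring an uncorrected screen).
#' @return An object of class `reel_screen`: `results` (per allele pair),
#'   `snp_class` (per SNP), `class_counts`, `replicate_r2`, `dropped`,
#'   `params`.
#' @export
run_screen <- function(x, alpha = 0.05, slope_cut = 0.05, min_count = 1,
                       slope_x = c("cycle", "rank"), test_cycle = NULL,
                       welch = FALSE, log_ratios = FALSE, adjust_p = FALSE) {
  slope_x <- match.arg(slope_x)
  qc <- qc_complete(x, min_count = min_count)
  xq <- qc$counts
  cycles <- sort(unique(xq$labels$cycle))
  if (is.null(test_cycle)) test_cycle <- max(cycles)
  if (!test_cycle %in% cycles) {
    stop("test cycle ", test_cycle, " not present in the count matrix ",
         "(cycles: ", paste(cycles, collapse = ", "), ")")
  }
  empty <- nrow(xq$counts) == 0
  pairs <- if (empty) snp_pairs(xq$seq_info)[0, ] else snp_pairs(xq$seq_info)

  n_pair <- nrow(pairs)
  ctrl_cols <- lapply(cycles, function(cc) label_cols(xq, cc, "control"))
  samp_cols <- lapply(cycles, function(cc) label_cols(xq, cc, "sample"))
  names(ctrl_cols) <- names(samp_cols) <- as.character(cycles)

  ratio_of <- function(cols) {
    r <- xq$counts[pairs$risk_row, cols, drop = FALSE] /
      xq$counts[pairs$non_row, cols, drop = FALSE]
    if (log_ratios) log(r) else r
  }

  ctrl_test <- ratio_of(ctrl_cols[[as.character(test_cycle)]])
  samp_test <- ratio_of(samp_cols[[as.character(test_cycle)]])
  p_value <- vapply(seq_len(n_pair), function(i) {
    ttest_ratio(ctrl_test[i, ], samp_test[i, ], welch = welch)
  }, numeric(1))

  traj <- vapply(cycles, function(cc) {
    rowMeans(ratio_of(samp_cols[[as.character(cc)]])) /
      rowMeans(ratio_of(ctrl_cols[[as.character(cc)]]))
  }, numeric(n_pair))
  if (n_pair == 1) traj <- matrix(traj, nrow = 1)
  colnames(traj) <- paste0("norm_ratio_c", cycles)

  slope_xv <- if (slope_x == "cycle") cycles else seq_along(cycles)
  slope <- if (n_pair > 0) slope_matrix(traj, slope_xv) else numeric(0)
  cls <- classify_fsnp(p_value, slope, alpha = alpha, slope_cut = slope_cut)

  results <- data.frame(
    snp_id = pairs$snp_id,
    risk_allele = pairs$risk_allele,
    nonrisk_allele = pairs$nonrisk_allele,
    p_value = p_value,
    slope = slope,
    class = cls,
    stringsAsFactors = FALSE
  )
  if (adjust_p) {
    results$p_adj <- stats::p.adjust(p_value, method = "BH")
  }
  results <- cbind(results, as.data.frame(traj),
                   ratio_cols(ctrl_test, "control_ratio_r"),
                   ratio_cols(samp_test, "sample_ratio_r"))

  # SNP-level class: strongest call across allele pairs
  ord <- c(candidate = 1, putative = 2, non_fSNP = 3)
  snp_class <- if (n_pair > 0) {
    best <- tapply(ord[as.character(cls)], results$snp_id, min)
    data.frame(snp_id = names(best),
               class = factor(names(ord)[best], levels = names(ord)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(snp_id = character(0),
               class = factor(character(0), levels = names(ord)))
  }
  rownames(snp_class) <- NULL

  rep_r2 <- if (nrow(xq$counts) >= 4) {
    replicate_correlation(xq, cycle = test_cycle)
  } else {
    numeric(0)
  }

  structure(list(
    results = results,
    snp_class = snp_class,
    class_counts = table(snp_class$class),
    replicate_r2 = rep_r2,
    dropped = qc$dropped,
    params = list(alpha = alpha, slope_cut = slope_cut,
                  min_count = min_count, slope_x = slope_x,
                  test_cycle = test_cycle, welch = welch,
                  log_ratios = log_ratios, cycles = cycles)
  ), class = "reel_screen")
}

ratio_cols <- function(m, prefix) {
  d <- as.data.frame(m)
  names(d) <- paste0(prefix, seq_len(ncol(m)))
  rownames(d) <- NULL
  d
}

#' @export
print.reel_screen <- function(x, ...) {
  cat("reel_screen:", nrow(x$snp_class), "SNPs analyzed (",
      nrow(x$dropped), "dropped by completeness QC )\n")
  cc <- x$class_counts
  cat(sprintf("  significant (p < %s): %d | candidate: %d  putative: %d  non-fSNP: %d\n",
              format(x$params$alpha),
              sum(cc[c("candidate", "putative")]),
              cc["candidate"], cc["putative"], cc["non_fSNP"]))
  if (length(x$replicate_r2) > 0) {
    cat("  replicate R2:",
        paste(sprintf("%s=%.2f", names(x$replicate_r2), x$replicate_r2),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Write screen results and summary
#'
#' @param screen A `reel_screen` from [run_screen()].
#' @param results_path TSV path for the per-allele-pair result table.
#' @param summary_path Optional JSON path for class counts, replicate R2
#'   and parameters.
#' @export
write_screen <- function(screen, results_path, summary_path = NULL) {
  utils::write.table(screen$results, results_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(summary_path)) {
    jsonlite::write_json(list(
      n_snps = nrow(screen$snp_class),
      n_dropped = nrow(screen$dropped),
      class_counts = as.list(screen$class_counts),
      replicate_r2 = as.list(screen$replicate_r2),
      params = screen$params
    ), summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(results_path)
}
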