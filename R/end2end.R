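# One-call pipeline: simulate a screen, emit FASTQ, count it back, verify
# the round trip, analyze, and write all artifacts with a provenance block.

#' Run the simulated screen end to end
#'
#' Chains [simulate_screen()] -> [emit_fastq()] -> [count_reads()] ->
#' [run_screen()], verifies that counting the emitted error-free FASTQ
#' reproduces the simulated count matrix exactly, and writes every artifact
#' (library, truth, barcodes, FASTQ, counts, counting report, results,
#' summary) plus a `provenance.json` echoing the configuration and seed to
#' `outdir`. Reruns with the same configuration and seed are byte-identical.
#'
#' @param outdir Output directory (created if needed).
#' @param n_snps,depth,seed,... Simulation settings passed to
#'   [simulation_config()].
#' @param lib Optional [reel_library()]; by default a random library of
#'   `n_snps` SNPs is generated from the seed.
#' @param error_rate Per-base FASTQ error rate. The exact round-trip check
#'   is only asserted at 0.
#' @param alpha,slope_cut Classification cutoffs for [run_screen()].
#' @param gzip_fastq Write the FASTQ gzipped.
#' @return Invisibly, a list with the `reel_screen` report, the simulation
#'   truth, and the paths written.
#' @export
run_end2end <- function(outdir, n_snps = 200L, depth = 5e4, seed = 1L,
                        lib = NULL, error_rate = 0, alpha = 0.05,
                        slope_cut = 0.05, gzip_fastq = TRUE, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  config <- simulation_config(n_snps = n_snps, depth = depth, seed = seed,
                              ...)
  if (is.null(lib)) lib <- random_library(n_snps, seed = seed)
  sim <- simulate_screen(lib, config)
  barcodes <- make_barcode_map(sim$counts$labels, seed = seed)

  paths <- list(
    library = file.path(outdir, "library.tsv"),
    truth = file.path(outdir, "truth.tsv"),
    barcodes = file.path(outdir, "barcodes.tsv"),
    fastq = file.path(outdir,
                      if (gzip_fastq) "reads.fastq.gz" else "reads.fastq"),
    counts = file.path(outdir, "counts.tsv"),
    count_report = file.path(outdir, "count_report.tsv"),
    results = file.path(outdir, "results.tsv"),
    summary = file.path(outdir, "summary.json"),
    provenance = file.path(outdir, "provenance.json")
  )
  write_library(lib, paths$library)
  truth_tab <- merge(sim$truth$model, sim$truth$snp, by = "snp_id",
                     sort = FALSE)
  utils::write.table(truth_tab, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_barcode_map(barcodes, paths$barcodes)
  emit_fastq(sim$counts, lib, barcodes, paths$fastq,
             error_rate = error_rate, seed = seed)
  counted <- count_reads(paths$fastq, barcodes, lib)
  if (error_rate == 0 &&
      !identical(unname(counted$counts[rownames(sim$counts$counts),
                                       colnames(sim$counts$counts)]) * 1,
                 unname(sim$counts$counts) * 1)) {
    stop("round-trip failure: counted FASTQ does not reproduce the ",
         "simulated count matrix")
  }
  write_counts(counted, paths$counts)
  write_count_report(counted, paths$count_report)
  screen <- run_screen(counted, alpha = alpha, slope_cut = slope_cut)
  write_screen(screen, paths$results, paths$summary)
  jsonlite::write_json(list(
    package = "reelscreen",
    version = as.character(utils::packageVersion("reelscreen")),
    seed = seed,
    error_rate = error_rate,
    config = unclass(config),
    alpha = alpha,
    slope_cut = slope_cut
  ), paths$provenance, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(screen = screen, truth = sim$truth, paths = paths))
}

#' Compare screen calls with simulation truth
#'
#' Sensitivity and specificity of the candidate/putative calls against the
#' simulator's ground-truth fSNP labels, plus slope-sign agreement for
#' correctly recovered fSNPs. SNPs removed by completeness QC are reported
#' separately: they receive no classification.
#'
#' @param screen A `reel_screen` from [run_screen()].
#' @param truth A `sim_truth` from [simulate_screen()] / [shift_model()].
#' @return A list: `n_true_fsnp`, `n_true_fsnp_analyzed`, `sensitivity`
#'   (called candidate or putative among analyzed true fSNPs),
#'   `sensitivity_overall` (denominator all true fSNPs, QC-dropped counted
#'   as misses), `specificity` (non-fSNP rate among analyzed null SNPs),
#'   `slope_sign_agreement` (fraction of recovered fSNPs whose fitted slope
#'   sign matches the expected sign).
#' @export
score_recovery <- function(screen, truth) {
  tr <- truth$snp
  called <- merge(screen$snp_class, tr, by = "snp_id")
  pos <- called$is_functional
  hit <- called$class %in% c("candidate", "putative")
  n_true <- sum(tr$is_functional)
  sens_analyzed <- if (any(pos)) mean(hit[pos]) else NA_real_
  spec <- if (any(!pos)) mean(called$class[!pos] == "non_fSNP") else NA_real_
  # slope sign check on recovered fSNPs, first allele pair per SNP
  res1 <- screen$results[!duplicated(screen$results$snp_id), ]
  rec <- merge(res1[res1$snp_id %in% called$snp_id[pos & hit], ],
               tr, by = "snp_id")
  sign_ok <- if (nrow(rec) > 0) {
    mean(sign(rec$slope) == rec$expected_slope_sign)
  } else {
    NA_real_
  }
  list(
    n_true_fsnp = n_true,
    n_true_fsnp_analyzed = sum(pos),
    sensitivity = sens_analyzed,
    sensitivity_overall = if (n_true > 0) sum(hit & pos) / n_true
                          else NA_real_,
    specificity = spec,
    slope_sign_agreement = sign_ok
  )
}
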