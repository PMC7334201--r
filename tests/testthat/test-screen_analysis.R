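test_that("allele ratio is risk over non-risk and guards its denominator", {
  expect_equal(allele_ratio(50, 25), 2)
  expect_equal(allele_ratio(7, 7), 1)
  expect_equal(allele_ratio(c(2, 3), c(4, 3)), c(0.5, 1))
  expect_error(allele_ratio(3, 0), "QC")
})

test_that("the ratio t test matches the pooled-variance Student's t", {
  ctrl <- c(1.0, 1.1, 0.9, 1.0, 1.0)
  samp <- c(2.0, 2.1, 1.9, 2.0, 2.0)
  # frozen from an independent reference implementation of the two-sample
  # pooled t (t = -22.3607, df = 8)
  expect_equal(ttest_ratio(ctrl, samp), 1.6924559265112e-08,
               tolerance = 1e-10)
  expect_equal(ttest_ratio(samp, ctrl), ttest_ratio(ctrl, samp))
  expect_equal(ttest_ratio(ctrl, ctrl), 1)
  # textbook pooled formula on random fixtures
  set.seed(51)
  for (i in 1:10) {
    a <- rnorm(5); b <- rnorm(5, 0.5)
    sp2 <- (4 * var(a) + 4 * var(b)) / 8
    t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
    expect_equal(ttest_ratio(a, b), 2 * pt(-abs(t_stat), df = 8))
  }
  # invariant under common rescaling of both groups
  expect_equal(ttest_ratio(ctrl * 3.7, samp * 3.7), ttest_ratio(ctrl, samp))
  # degenerate cases: constant groups
  expect_equal(ttest_ratio(rep(1, 5), rep(1, 5)), 1)
  expect_equal(ttest_ratio(rep(1, 5), rep(2, 5)), 0)
  expect_error(ttest_ratio(1, c(1, 2)), "at least 2")
})

test_that("normalized trajectories divide sample means by control means", {
  x <- flat_counts(fill = 8)
  expect_equal(unname(normalized_trajectory(x, "rs1")), rep(1, 4))
  # hand-built means: sample ratios constant 2, control ratios 1, 2, 4, 8
  x2 <- flat_counts(fill = 1)
  for (cyc in c(1, 4, 7, 10)) {
    ctrl_fill <- c(`1` = 1, `4` = 2, `7` = 4, `10` = 8)[as.character(cyc)]
    for (r in 1:5) {
      x2$counts["rs1|A", sprintf("c%d_control_r%d", cyc, r)] <- ctrl_fill
      x2$counts["rs1|A", sprintf("c%d_sample_r%d", cyc, r)] <- 2
    }
  }
  expect_equal(unname(normalized_trajectory(x2, "rs1")), c(2, 1, 0.5, 0.25))
  expect_error(normalized_trajectory(x2, "nope"), "unknown snp_id")
})

test_that("slope fitting is exact on linear input and antisymmetric", {
  expect_equal(fit_slope(c(1.0, 1.3, 1.6, 1.9)), 0.1)
  expect_equal(fit_slope(rep(1.4, 4)), 0)
  expect_equal(fit_slope(c(1.9, 1.6, 1.3, 1.0)), -0.1)
  expect_error(fit_slope(c(1, NA, 2, 3)), "non-finite")
  # rank regressor differs by the cycle spacing factor 3
  expect_equal(fit_slope(c(1.0, 1.3, 1.6, 1.9), slope_x = "rank"), 0.3)
  # vectorized slope agrees with lm() on random trajectories
  set.seed(52)
  traj <- matrix(rexp(40), 10, 4)
  vs <- reelscreen:::slope_matrix(traj, c(1, 4, 7, 10))
  for (i in 1:10) {
    expect_equal(vs[i], unname(coef(lm(traj[i, ] ~ c(1, 4, 7, 10)))[2]))
  }
})

test_that("classification partitions the (p, slope) plane with strict cutoffs", {
  expect_equal(as.character(classify_fsnp(0.01, 0.10)), "candidate")
  expect_equal(as.character(classify_fsnp(0.01, -0.10)), "candidate")
  expect_equal(as.character(classify_fsnp(0.01, 0.02)), "putative")
  expect_equal(as.character(classify_fsnp(0.20, 0.30)), "non_fSNP")
  # boundaries fall in the weaker class
  expect_equal(as.character(classify_fsnp(0.05, 0.10)), "non_fSNP")
  expect_equal(as.character(classify_fsnp(0.01, 0.05)), "putative")
  expect_equal(as.character(classify_fsnp(0.01, -0.05)), "putative")
  # every grid point gets exactly one class
  grid <- expand.grid(p = c(0, 0.01, 0.049, 0.05, 0.051, 0.2, 1),
                      s = c(-0.3, -0.05, -0.02, 0, 0.02, 0.05, 0.3))
  cls <- classify_fsnp(grid$p, grid$s)
  expect_false(anyNA(cls))
  expect_equal(length(cls), nrow(grid))
  # custom thresholds
  expect_equal(as.character(classify_fsnp(0.08, 0.2, alpha = 0.1)),
               "candidate")
})

test_that("replicate correlation is 1 for duplicated data and ~0 for noise", {
  x <- flat_counts(fill = 4)
  set.seed(53)
  # shared signal: same ratios in every replicate -> R2 = 1
  sig <- sample(1:20, 3)
  for (r in 1:5) {
    for (cond in c("control", "sample")) {
      x$counts[c("rs1|A", "rs2|T", "rs3|G"),
               sprintf("c10_%s_r%d", cond, r)] <-
        if (cond == "sample") sig * 4 else 4
    }
  }
  expect_equal(unname(replicate_correlation(x)), rep(1, 4))
  # independent noise across replicates on many SNPs -> R2 near 0
  lib <- random_library(300, seed = 54)
  xn <- flat_counts(lib, fill = 50, cycles = 10)
  risk <- xn$seq_info$is_risk
  xn$counts[risk, ] <- matrix(rpois(sum(risk) * ncol(xn$counts), 50),
                              ncol = ncol(xn$counts))
  r2 <- replicate_correlation(xn, cycle = 10)
  expect_true(all(r2 < 0.1))
})

test_that("run_screen returns an empty report on an empty matrix", {
  lib <- tiny_library()
  x <- flat_counts(lib, fill = 0)
  scr <- run_screen(x)  # QC drops everything
  expect_equal(nrow(scr$results), 0)
  expect_equal(nrow(scr$snp_class), 0)
  expect_equal(sum(scr$class_counts), 0)
  expect_equal(nrow(scr$dropped), 3)
})

test_that("run_screen errors cleanly when the test cycle is absent", {
  x <- flat_counts(fill = 5, cycles = c(1, 4, 7))
  expect_error(run_screen(x, test_cycle = 10), "cycle 10")
})

test_that("multi-allelic SNPs yield one result per pair, strongest call wins", {
  lib <- reel_library(rbind(
    snp_record("rsM", c("A", "C", "G"), "A", strrep("C", 15), strrep("T", 15)),
    snp_record("rsB", c("A", "G"), "G", strrep("G", 15), strrep("A", 15))
  ))
  x <- flat_counts(lib, fill = 20)
  # depress the A (risk) allele of rsM in samples, strongly at late cycles
  set.seed(55)
  for (cyc in c(1, 4, 7, 10)) {
    for (r in 1:5) {
      x$counts["rsM|A", sprintf("c%d_sample_r%d", cyc, r)] <-
        round(20 * 0.5^cyc * (1 + 0.05 * r)) + 1
    }
  }
  scr <- run_screen(x)
  expect_equal(sum(scr$results$snp_id == "rsM"), 2)
  expect_equal(sum(scr$results$snp_id == "rsB"), 1)
  m <- scr$results[scr$results$snp_id == "rsM", ]
  expect_setequal(m$nonrisk_allele, c("C", "G"))
  expect_equal(nrow(scr$snp_class), 2)
  best <- min(c(candidate = 1, putative = 2, non_fSNP = 3)[as.character(m$class)])
  expect_equal(as.character(scr$snp_class$class[scr$snp_class$snp_id == "rsM"]),
               names(which(c(candidate = 1, putative = 2, non_fSNP = 3) == best))[1])
  # class counts partition the analyzed SNPs
  expect_equal(sum(scr$class_counts), nrow(scr$snp_class))
})

test_that("screen results survive a TSV round trip of the counts", {
  lib <- random_library(40, seed = 56)
  cfg <- simulation_config(n_snps = 40, depth = 5000, seed = 57)
  sim <- simulate_screen(lib, cfg)
  direct <- run_screen(sim$counts)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(sim$counts, path)
  reread <- run_screen(read_counts(path))
  expect_equal(reread$results[order(reread$results$snp_id), ],
               direct$results[order(direct$results$snp_id), ],
               ignore_attr = TRUE)
})
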