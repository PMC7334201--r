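# Forward simulator of the cyclic gel-shift selection. Each library is a
# vector of relative sequence frequencies; one cycle removes a per-sequence
# fraction p_shift into the shifted band, and PCR regeneration of the
# recovered unshifted band is modelled as renormalization. Sequencing is a
# multinomial snapshot at fixed depth.

#' Generate a random SNP library
#'
#' Convenience generator for simulation studies: random 15-nt flanks
#' (resampled until all variable regions are unique) and random allele sets.
#'
#' @param n_snps Number of SNPs.
#' @param n_tri,n_quad How many of them carry three / four alleles; the rest
#'   are biallelic.
#' @param seed Optional integer seed.
#' @return A [reel_library()].
#' @export
random_library <- function(n_snps, n_tri = 0, n_quad = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_tri + n_quad > n_snps) stop("n_tri + n_quad exceeds n_snps")
  nt <- c("A", "C", "G", "T")
  rand_flank <- function(n) {
    vapply(seq_len(n), function(i) {
      paste(sample(nt, FLANK_LEN, replace = TRUE), collapse = "")
    }, character(1))
  }
  n_alleles <- c(rep(2L, n_snps - n_tri - n_quad), rep(3L, n_tri),
                 rep(4L, n_quad))
  alleles <- vapply(n_alleles, function(k) {
    paste(sample(nt, k), collapse = ",")
  }, character(1))
  records <- data.frame(
    snp_id = sprintf("rs%06d", seq_len(n_snps)),
    locus = sprintf("locus%03d", (seq_len(n_snps) - 1L) %% 100L + 1L),
    alleles = alleles,
    risk_allele = vapply(strsplit(alleles, ","), `[`, character(1), 1L),
    flank5 = rand_flank(n_snps),
    flank3 = rand_flank(n_snps),
    stringsAsFactors = FALSE
  )
  # flanks alone make regions unique with overwhelming probability; retry on
  # the rare collision
  for (attempt in 1:20) {
    lib <- try(reel_library(records), silent = TRUE)
    if (!inherits(lib, "try-error")) return(lib)
    records$flank5 <- rand_flank(n_snps)
  }
  stop("could not generate a collision-free library")
}

#' Simulation configuration
#'
#' Defaults mirror the screen layout of a ten-cycle run: five buffer-treated
#' control and five nuclear-extract-treated sample libraries carried as
#' independent lineages through 10 cycles, sequenced after cycles 1, 4, 7
#' and 10.
#'
#' @param n_snps Number of SNPs in the simulated library.
#' @param fraction_functional Fraction of SNPs whose alleles differ in shift
#'   probability (true fSNPs).
#' @param delta_p Shift-probability difference between the preferentially
#'   bound allele and the baseline, for fSNPs.
#' @param baseline_p Shift probability of every non-preferred sequence in
#'   the sample (nuclear extract) condition; models uniform nonspecific
#'   binding.
#' @param p_control Allele-independent loss per cycle in the buffer-only
#'   controls (default 0: nothing shifts without extract).
#' @param replicates Replicate libraries per condition.
#' @param cycles Total selection cycles run.
#' @param cycles_sequenced Cycles at which libraries are sequenced (a subset
#'   of `1:cycles`); the snapshot is taken after that cycle's selection.
#' @param depth Reads sequenced per library.
#' @param pcr_noise_sd Standard deviation (log scale) of an i.i.d. lognormal
#'   per-sequence amplification jitter applied each cycle; 0 disables it.
#' @param mode `"stochastic"` draws multinomial read counts (and applies PCR
#'   jitter if requested); `"deterministic"` records the noise-free expected
#'   counts `frequency * depth` (infinite-depth limit) and applies no jitter.
#' @param seed Integer seed fixing all randomness (truth assignment, lineage
#'   jitter, sequencing draws, in that order).
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_snps = 500L, fraction_functional = 0.1,
                              delta_p = 0.3, baseline_p = 0.1, p_control = 0,
                              replicates = 5L, cycles = 10L,
                              cycles_sequenced = c(1L, 4L, 7L, 10L),
                              depth = 5e4, pcr_noise_sd = 0,
                              mode = c("stochastic", "deterministic"),
                              seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_snps >= 1, fraction_functional >= 0, fraction_functional <= 1,
            delta_p >= 0, baseline_p >= 0, baseline_p + delta_p < 1,
            p_control >= 0, p_control < 1, replicates >= 1, cycles >= 1,
            depth > 0, pcr_noise_sd >= 0)
  cycles_sequenced <- sort(unique(as.integer(cycles_sequenced)))
  if (!all(cycles_sequenced %in% seq_len(cycles))) {
    stop("cycles_sequenced must lie in 1..cycles")
  }
  structure(list(
    n_snps = as.integer(n_snps), fraction_functional = fraction_functional,
    delta_p = delta_p, baseline_p = baseline_p, p_control = p_control,
    replicates = as.integer(replicates), cycles = as.integer(cycles),
    cycles_sequenced = cycles_sequenced, depth = depth,
    pcr_noise_sd = pcr_noise_sd, mode = mode, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Build an allele shift model with ground truth
#'
#' For each SNP drawn as functional, one allele (the risk allele with
#' probability 1/2, otherwise a random non-risk allele) receives shift
#' probability `baseline_p + delta_p` in the sample condition; every other
#' sequence sits at `baseline_p`. Controls lose the allele-independent
#' `p_control` per cycle. Uses the current RNG state.
#'
#' @param lib A [reel_library()].
#' @param config A [simulation_config()].
#' @return A list of class `sim_truth`: `model` (per-sequence `p_sample`,
#'   `p_control`), `snp` (per-SNP `is_functional` and `expected_slope_sign`,
#'   the sign of `p_nonrisk - p_risk`).
#' @export
shift_model <- function(lib, config) {
  reg <- library_regions(lib)
  n_snps <- nrow(lib$records)
  n_fun <- round(config$fraction_functional * n_snps)
  functional <- sort(sample.int(n_snps, n_fun))
  is_fun <- seq_len(n_snps) %in% functional
  p_sample <- rep(config$baseline_p, nrow(reg))
  for (i in functional) {
    id <- lib$records$snp_id[i]
    rows <- which(reg$snp_id == id)
    boosted <- if (stats::runif(1) < 0.5) {
      rows[reg$is_risk[rows]]
    } else {
      r <- rows[!reg$is_risk[rows]]
      if (length(r) > 1) sample(r, 1) else r
    }
    p_sample[boosted] <- config$baseline_p + config$delta_p
  }
  snp <- data.frame(snp_id = lib$records$snp_id, is_functional = is_fun)
  # slope sign of the risk/non-risk trajectory: negative when the risk allele
  # is preferentially shifted (spec'd against the first non-risk allele)
  risk_rows <- match(seq_key(snp$snp_id, lib$records$risk_allele),
                     seq_key(reg$snp_id, reg$allele))
  first_nonrisk <- vapply(snp$snp_id, function(id) {
    which(reg$snp_id == id & !reg$is_risk)[1]
  }, integer(1))
  snp$expected_slope_sign <- sign(p_sample[first_nonrisk] -
                                    p_sample[risk_rows])
  structure(list(
    model = data.frame(snp_id = reg$snp_id, allele = reg$allele,
                       is_risk = reg$is_risk, p_sample = p_sample,
                       p_control = config$p_control),
    snp = snp
  ), class = "sim_truth")
}

#' Apply one selection + regeneration cycle to a library
#'
#' Each sequence retains fraction `1 - p_shift` in the unshifted band; PCR
#' regeneration restores total material, i.e. frequencies are renormalized.
#' With `pcr_noise_sd > 0` each retained term is additionally multiplied by
#' an i.i.d. lognormal factor before renormalization (drawn from the current
#' RNG state).
#'
#' @param freq Relative frequencies summing to 1.
#' @param p_shift Per-sequence shift probabilities in `[0, 1]`.
#' @param pcr_noise_sd Log-scale SD of the amplification jitter.
#' @return Updated frequencies summing to 1.
#' @export
apply_cycle <- function(freq, p_shift, pcr_noise_sd = 0) {
  if (abs(sum(freq) - 1) > 1e-6) stop("frequencies must sum to 1")
  if (any(p_shift < 0 | p_shift > 1)) stop("p_shift must lie in [0, 1]")
  w <- freq * (1 - p_shift)
  if (pcr_noise_sd > 0) {
    w <- w * stats::rlnorm(length(w), meanlog = 0, sdlog = pcr_noise_sd)
  }
  tot <- sum(w)
  if (tot <= 0) stop("degenerate library: no sequence survived the cycle")
  w / tot
}

#' Closed-form normalized-ratio trajectory
#'
#' In the noise-free model the risk/non-risk ratio in a sample library after
#' `cycle` selections is multiplied by `((1 - p_r) / (1 - p_n))^cycle`, while
#' an allele-independent control loss cancels in the control ratio; the
#' sample/control normalized ratio is therefore
#' `((1 - p_r) / (1 - p_n))^cycle`. This is the oracle the stochastic
#' simulator converges to with depth.
#'
#' @param p_r,p_n Shift probabilities of the risk and non-risk allele in the
#'   sample condition, in `[0, 1)`.
#' @param cycle Cycle number(s).
#' @param p_control Allele-independent control loss (cancels; accepted for
#'   interface symmetry).
#' @return Numeric vector, one value per `cycle`.
#' @export
expected_normalized_ratio <- function(p_r, p_n, cycle, p_control = 0) {
  stopifnot(p_r >= 0, p_r < 1, p_n >= 0, p_n < 1,
            p_control >= 0, p_control < 1)
  ((1 - p_r) / (1 - p_n))^cycle
}

#' Multinomial sequencing of a library
#'
#' @param freq Relative frequencies summing to 1.
#' @param depth Total reads to draw.
#' @return Integer counts summing exactly to `depth` (uses the current RNG
#'   state).
#' @export
sequence_library <- function(freq, depth) {
  if (abs(sum(freq) - 1) > 1e-6) stop("frequencies must sum to 1")
  if (depth <= 0) stop("depth must be positive")
  as.vector(stats::rmultinom(1, size = depth, prob = freq))
}

#' Forward-simulate a full screen
#'
#' Every replicate library of each condition evolves as an independent
#' lineage from the uniform initial library; after the selection step of
#' each sequenced cycle the library is sequenced at the configured depth
#' (multinomially in stochastic mode, at infinite depth in deterministic
#' mode).
#'
#' @param lib A [reel_library()].
#' @param config A [simulation_config()].
#' @param truth Optional pre-built [shift_model()] result; by default one is
#'   drawn from the config.
#' @return A list with elements `counts` (a [reel_counts()]) and `truth`
#'   (a `sim_truth`).
#' @export
simulate_screen <- function(lib, config, truth = NULL) {
  set.seed(config$seed)
  if (is.null(truth)) truth <- shift_model(lib, config)
  reg <- truth$model
  n_seq <- nrow(reg)
  labels <- count_labels(cycles = config$cycles_sequenced,
                         replicates = seq_len(config$replicates))
  counts <- matrix(0, n_seq, nrow(labels),
                   dimnames = list(seq_key(reg$snp_id, reg$allele),
                                   labels$label))
  deterministic <- config$mode == "deterministic"
  noise_sd <- if (deterministic) 0 else config$pcr_noise_sd
  for (condition in c("control", "sample")) {
    p_shift <- if (condition == "control") {
      rep(config$p_control, n_seq)
    } else {
      reg$p_sample
    }
    for (rep_i in seq_len(config$replicates)) {
      freq <- rep(1 / n_seq, n_seq)
      for (cyc in seq_len(config$cycles)) {
        freq <- apply_cycle(freq, p_shift, pcr_noise_sd = noise_sd)
        if (cyc %in% config$cycles_sequenced) {
          col <- sprintf("c%d_%s_r%d", cyc, condition, rep_i)
          counts[, col] <- if (deterministic) {
            freq * config$depth
          } else {
            sequence_library(freq, config$depth)
          }
        }
      }
    }
  }
  seq_info <- reg[, c("snp_id", "allele", "is_risk")]
  list(counts = reel_counts(counts, seq_info, labels), truth = truth)
}

#' Random barcode map for a screen layout
#'
#' Equal-length barcodes are prefix-free by construction.
#'
#' @param labels A `data.frame` from [count_labels()].
#' @param barcode_length Barcode length in nt.
#' @param seed Optional integer seed.
#' @return `labels` with a `barcode` column prepended.
#' @export
make_barcode_map <- function(labels, barcode_length = 8L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(labels)
  if (4^barcode_length < 2 * n) stop("barcode_length too short for layout")
  repeat {
    bc <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), barcode_length, replace = TRUE),
            collapse = "")
    }, character(1))
    if (!anyDuplicated(bc)) break
  }
  cbind(data.frame(barcode = bc, stringsAsFactors = FALSE), labels)
}

#' Emit simulated reads as FASTQ
#'
#' Each read is `barcode + fwd_primer + variable region + rev_primer` with
#' uniform quality; the read multiset per library reproduces the count
#' matrix exactly. An optional per-base substitution error rate corrupts
#' reads independently at each position.
#'
#' @param x A [reel_counts()] with integer counts.
#' @param lib The [reel_library()] the counts refer to.
#' @param barcodes Barcode map from [make_barcode_map()] covering every
#'   library column of `x`.
#' @param path Output FASTQ path (gzipped if it ends in `.gz`).
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Optional integer seed for the error process.
#' @return `path`, invisibly.
#' @export
emit_fastq <- function(x, lib, barcodes, path, error_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(x$counts != round(x$counts))) {
    stop("emit_fastq needs integer counts (stochastic-mode output)")
  }
  missing_bc <- setdiff(x$labels$label, barcodes$label)
  if (length(missing_bc) > 0) {
    stop("no barcode for library column(s): ",
         paste(missing_bc, collapse = ", "))
  }
  reg <- library_regions(lib)
  construct <- paste0(lib$fwd_primer, reg$region, lib$rev_primer)
  key <- seq_key(reg$snp_id, reg$allele)
  seq_of_row <- construct[match(rownames(x$counts), key)]
  if (anyNA(seq_of_row)) stop("count rows not present in the library")
  bc_of_col <- barcodes$barcode[match(x$labels$label, barcodes$label)]

  n_per_cell <- as.vector(x$counts)
  row_idx <- rep(rep(seq_len(nrow(x$counts)), ncol(x$counts)), n_per_cell)
  col_idx <- rep(rep(seq_len(ncol(x$counts)), each = nrow(x$counts)),
                 n_per_cell)
  reads <- paste0(bc_of_col[col_idx], seq_of_row[row_idx])
  if (error_rate > 0) reads <- corrupt_reads(reads, error_rate)
  dss <- Biostrings::DNAStringSet(reads)
  names(dss) <- paste0(x$labels$label[col_idx], ":", seq_along(reads))
  Biostrings::writeXStringSet(dss, path, format = "fastq",
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

# i.i.d. per-base substitution: a Binomial total with uniformly sampled
# distinct positions is exactly the Bernoulli error mask; multiple hits in
# one read are applied in successive vectorized passes
corrupt_reads <- function(reads, error_rate) {
  widths <- nchar(reads)
  total <- sum(widths)
  n_err <- stats::rbinom(1, total, error_rate)
  if (n_err == 0) return(reads)
  flat <- sort(sample(total, n_err))
  ends <- cumsum(widths)
  read_i <- findInterval(flat - 1, ends) + 1L
  pos <- flat - c(0, ends)[read_i]
  nt <- c("A", "C", "G", "T")
  pass <- stats::ave(seq_along(read_i), read_i, FUN = seq_along)
  for (k in seq_len(max(pass))) {
    sel <- pass == k
    i <- read_i[sel]
    p <- pos[sel]
    cur <- substr(reads[i], p, p)
    shift <- sample.int(3, length(i), replace = TRUE)
    new <- nt[(match(cur, nt) - 1L + shift) %% 4L + 1L]
    substr(reads[i], p, p) <- new
  }
  reads
}
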