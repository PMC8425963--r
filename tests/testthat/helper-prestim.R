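# Shared fixtures and small oracles, all built in code.

tiny_design <- function(...) {
  study_design(n_blocks = 1L, test_per_block_per_direction = 2L,
               control_per_block_per_direction = 1L, ...)
}

# Hilbert-transform instantaneous phase (FFT analytic signal), used as an
# independent oracle for wavelet phase estimates on noiseless signals.
hilbert_phase <- function(x) {
  n <- length(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Arg(fft(fft(x) * h, inverse = TRUE) / n)
}

# Standard-normal quantile by numeric inversion of pnorm, independent of
# qnorm, for criterion cross-checks.
z_oracle <- function(p) {
  vapply(p, function(pp)
    uniroot(function(q) pnorm(q) - pp, c(-10, 10), tol = 1e-12)$root, 0)
}

# Scaled-down cohort used by the simulation-based acceptance checks:
# 13 subjects, an 8 x 8 sensor grid and the -600..-200 ms prestimulus
# window at 333 Hz (the study geometry), with one session block and a
# single 10 Hz alpha centre frequency to keep runtimes practical.
acc_design <- function() {
  study_design(n_blocks = 1L, test_per_block_per_direction = 25L,
               control_per_block_per_direction = 1L,
               epoch_window = c(-0.8, 0.2))
}

acc_layout <- function() grid_layout(8L, 8L)

# One cohort through the POS and/or correlation arms with the reduced
# permutation counts (200 subject-level, 1000 group-level, 200 cluster
# repetitions). Subjects with an empty report-by-direction cell are
# dropped, mirroring run_pipeline(). Returns the cluster tests plus the
# effect-sensor indices.
analyze_cohort_arms <- function(seed, phase_coupling = 0,
                                power_bias_coupling = 0,
                                arms = c("pos", "corr"),
                                design = acc_design()) {
  layout <- acc_layout()
  cohort <- simulate_cohort(13L, design, layout, seed = seed,
                            phase_coupling = phase_coupling,
                            power_bias_coupling = power_bias_coupling)
  preps <- list()
  rates <- numeric(0)
  for (s in cohort) {
    tr <- filter_rts(s$trials)
    tt <- tr[tr$label %in% c("ILL", "no-ILL"), , drop = FALSE]
    p <- tryCatch({
      for (dir in c("inward", "outward")) for (lb in c("ILL", "no-ILL"))
        if (!any(tt$label == lb & tt$direction == dir))
          stop("empty cell")
      te <- equalize_trials(tt, seed = seed + 1L)
      ep <- subset_epochs(s$epochs, match(te$trial, s$epochs$trial_ids))
      tf <- morlet_transform(ep, 10, window = c(-0.6, -0.2))
      list(ph = tf_phasors(tf), pw = band_average(tf, "alpha"),
           lab = te$label)
    }, error = function(e) NULL)
    if (!is.null(p)) {
      preps[[length(preps) + 1L]] <- p
      rates <- c(rates, mean(tt$label == "ILL"))
    }
  }
  n <- length(preps)
  out <- list(n_used = n, effect_sensors = cohort[[1]]$epochs$effect_sensors)
  if ("pos" %in% arms) {
    obs <- Reduce(`+`, lapply(preps, function(p)
      pos_observed(p$ph, p$lab))) / n
    snulls <- lapply(seq_len(n), function(i)
      subject_null(preps[[i]]$ph, preps[[i]]$lab, n_perm = 200L,
                   seed = seed + 10L + i))
    gnull <- group_null(snulls, n_draws = 1000L, seed = seed + 50L)
    out$pos <- cluster_permutation_pos(
      obs, gnull, layout,
      cluster_config(forming_alpha = 0.05, min_neighbors = 0L,
                     min_cluster_size = 10L, n_permutations = 200L),
      seed = seed + 60L)
  }
  if ("corr" %in% arms) {
    ntm <- dim(preps[[1]]$pw)[3]
    brain <- array(0, c(n, 64L, ntm))
    for (i in seq_len(n)) {
      p <- preps[[i]]
      cm <- function(sel)
        colMeans(matrix(p$pw[sel, , , drop = FALSE], nrow = sum(sel)))
      brain[i, , ] <- cm(p$lab == "ILL") - cm(p$lab == "no-ILL")
    }
    out$corr <- cluster_permutation_correlation(
      brain, rates, layout, cluster_config(n_permutations = 200L),
      seed = seed + 70L)
  }
  out
}

cluster_sensors <- function(test_obj) {
  unique(unlist(lapply(significant_clusters(test_obj), `[[`, "sensors")))
}
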