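#' Analysis configuration for the end-to-end pipeline
#'
#' Bundles every tunable of the analysis chain. Defaults are the study
#' settings: alpha band 8-12 Hz decomposed at 1 Hz steps with 3 Hz-bandwidth
#' Morlet wavelets, prestimulus window -600..-200 ms, RT rejection bounds
#' 0.2-4 s, 1000 subject-level and 10000 group-level POS permutations, 4000
#' permutations for the correlation/conjunction cluster tests (forming
#' threshold 0.01 two-sided, minimum 2 neighbours), POS clustering at the
#' 2.5/97.5 null percentiles with minimal cluster size 10, and 2000
#' bootstrap repetitions. Reduce the permutation counts for exploratory
#' runs.
#'
#' @param band band name or [band_definition()].
#' @param freq_step spacing (Hz) of wavelet centre frequencies in the band.
#' @param bandwidth Morlet spectral bandwidth (Hz).
#' @param prestim_window `[start, end]` seconds.
#' @param rt_bounds RT rejection bounds (s).
#' @param amplitude_threshold peak-amplitude epoch rejection threshold.
#' @param n_subject_perm,n_group_perm POS null sizes.
#' @param n_cluster_perm group-null draws clustered for the POS correction.
#' @param n_boot bootstrap repetitions for cluster-averaged correlations.
#' @param corr_config,pos_config,contrast_config,conj_config per-test
#'   [cluster_config()]s.
#' @param seed master seed; all stage seeds derive from it.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(band = "alpha", freq_step = 1, bandwidth = 3,
                            prestim_window = c(-0.6, -0.2),
                            rt_bounds = c(0.2, 4),
                            amplitude_threshold = Inf,
                            n_subject_perm = 1000L,
                            n_group_perm = 10000L,
                            n_cluster_perm = 1000L,
                            n_boot = 2000L,
                            corr_config = cluster_config(),
                            pos_config = cluster_config(
                              forming_alpha = 0.05, min_neighbors = 0L,
                              min_cluster_size = 10L,
                              n_permutations = n_cluster_perm),
                            contrast_config = cluster_config(
                              min_neighbors = 0L, n_permutations = 1000L),
                            conj_config = cluster_config(
                              forming_alpha = 0.01, min_neighbors = 0L,
                              n_permutations = corr_config$n_permutations,
                              cluster_stat = "max"),
                            seed = 1L) {
  if (is.character(band)) band <- band_definition(band)
  stopifnot(n_subject_perm >= 1L, n_group_perm >= 1L, n_boot >= 1L)
  structure(list(band = band, freq_step = freq_step, bandwidth = bandwidth,
                 prestim_window = prestim_window, rt_bounds = rt_bounds,
                 amplitude_threshold = amplitude_threshold,
                 n_subject_perm = as.integer(n_subject_perm),
                 n_group_perm = as.integer(n_group_perm),
                 n_cluster_perm = as.integer(n_cluster_perm),
                 n_boot = as.integer(n_boot),
                 corr_config = corr_config, pos_config = pos_config,
                 contrast_config = contrast_config,
                 conj_config = conj_config, seed = as.integer(seed)),
            class = "analysis_config")
}

band_freqs <- function(config) {
  seq(config$band$range[1], config$band$range[2], by = config$freq_step)
}

#' Per-subject spectral preparation
#'
#' Runs the single-subject preprocessing chain: RT filtering, trial
#' labelling, peak-amplitude epoch rejection, equalisation of trial counts
#' across report-by-direction cells, Morlet decomposition of the band,
#' restriction to the prestimulus window, and band-averaged power and unit
#' phasors. On planar layouts the band power is combined across each site's
#' channel pair with the Euclidean norm (POS is combined later, after the
#' per-channel POS maps are formed).
#'
#' @param subject one element of a [simulate_cohort()] (list with `trials`
#'   and `epochs`), or any list with those fields.
#' @param config an [analysis_config()].
#' @param seed seed for the equalisation subsampling.
#' @return List: `phasors` (trials x channels x freqs x time), `power`
#'   (trials x sensors x time, band-averaged, planar-combined), `labels`,
#'   `direction`, `times`, `site` (site index per power sensor).
#' @export
prepare_subject <- function(subject, config = analysis_config(), seed = 1L) {
  trials <- subject$trials
  if (!"label" %in% names(trials)) trials <- classify_trials(trials)
  trials <- filter_rts(trials, config$rt_bounds[1], config$rt_bounds[2])
  tt <- trials[trials$label %in% c("ILL", "no-ILL"), , drop = FALSE]
  epochs <- subject$epochs
  if (is.finite(config$amplitude_threshold)) {
    epochs <- reject_epochs(epochs, config$amplitude_threshold)
    tt <- tt[tt$trial %in% epochs$trial_ids, , drop = FALSE]
  }
  need <- expand.grid(label = c("ILL", "no-ILL"),
                      direction = unique(trials$direction),
                      stringsAsFactors = FALSE)
  for (k in seq_len(nrow(need))) {
    if (!any(tt$label == need$label[k] & tt$direction == need$direction[k]))
      stop("empty cell: no ", need$label[k], " trials for direction ",
           need$direction[k])
  }
  tt <- equalize_trials(tt, keys = c("label", "direction"), seed = seed)
  idx <- match(tt$trial, epochs$trial_ids)
  if (anyNA(idx)) stop("trial table and epochs are out of register")
  epochs <- subset_epochs(epochs, idx)
  tf <- morlet_transform(epochs, band_freqs(config), config$bandwidth,
                         window = config$prestim_window)
  phasors <- tf_phasors(tf)
  power <- band_average(tf, config$band)          # trials x channels x time
  layout <- epochs$layout
  site <- seq_len(dim(power)[2])
  if (layout$channel_kind == "planar_pair") {
    power <- combine_planar(power, site = layout$site, dim = 2L)
    site <- unique(layout$site)
  }
  list(phasors = phasors, power = power, labels = tt$label,
       direction = tt$direction, times = tf$times, site = site,
       layout = layout)
}

#' Paired power contrast with sign-flip cluster permutation
#'
#' Tests a per-subject paired difference map (for example ILL minus no-ILL
#' prestimulus band power) against zero with a one-sample t statistic at
#' every sensor and time point, clusters the supra-threshold t values
#' two-sidedly, and corrects family-wise against the maximum absolute
#' cluster sum under random per-subject sign flips of the difference.
#'
#' @param ill_power,noill_power numeric arrays subjects x sensors x time
#'   with identical dimensions (equalised trial counts upstream).
#' @param layout a `sensor_layout`.
#' @param config a [cluster_config()].
#' @param seed integer seed.
#' @return A `cluster_test`; element `t_map` holds the observed t map.
#' @export
power_contrast <- function(ill_power, noill_power, layout,
                           config = cluster_config(min_neighbors = 0L,
                                                   n_permutations = 1000L),
                           seed = 1L) {
  if (!identical(dim(ill_power), dim(noill_power)))
    stop("unbalanced inputs: dimensions differ")
  d <- dim(ill_power)
  n <- d[1]
  if (n < 4L) stop("need at least 4 subjects")
  D <- matrix(ill_power - noill_power, nrow = n)
  ss <- colSums(D^2)
  tmap_of <- function(m) {
    v <- pmax(ss - n * m^2, 0) / (n - 1)
    tv <- m / sqrt(v / n)
    tv[!is.finite(tv)] <- 0
    tv
  }
  thr <- stats::qt(1 - config$forming_alpha / 2, df = n - 1)
  t_obs <- matrix(tmap_of(colMeans(D)), nrow = d[2])
  obs <- clusters_from_map(t_obs, -thr, thr, layout,
                           config$min_neighbors, config$min_cluster_size)
  rng <- local_rng(seed)
  flips <- matrix(sample(c(-1, 1), config$n_permutations * n,
                         replace = TRUE),
                  nrow = config$n_permutations)
  rng$restore()
  M <- (flips %*% D) / n
  null_max <- numeric(config$n_permutations)
  for (k in seq_len(config$n_permutations)) {
    tm <- matrix(tmap_of(M[k, ]), nrow = d[2])
    cls <- clusters_from_map(tm, -thr, thr, layout,
                             config$min_neighbors, config$min_cluster_size)
    null_max[k] <- max_cluster_stat(cls, config$cluster_stat)
  }
  res <- new_cluster_test(obs, null_max, config, d[2:3], "power-contrast")
  res$t_map <- t_obs
  res
}

condition_mean_power <- function(prep, label, direction = NULL) {
  sel <- prep$labels == label
  if (!is.null(direction)) sel <- sel & prep$direction == direction
  pw <- prep$power[sel, , , drop = FALSE]
  matrix(colMeans(matrix(pw, nrow = dim(pw)[1])), nrow = dim(pw)[2])
}

#' Run the full prestimulus analysis chain on a cohort
#'
#' Executes, per subject: labelling, RT filtering, epoch rejection, trial
#' equalisation, Morlet decomposition, prestimulus restriction; then at the
#' group level: (i) the POS test (pooled directions) with its two-level
#' permutation null and spatiotemporal clustering, (ii) the paired ILL vs
#' no-ILL power contrast (pooled directions), (iii) per-direction cluster
#' tests of the between-subject correlation between the ILL minus no-ILL
#' power difference and the direction-specific illusion rate and criterion,
#' and (iv) a conjunction test across directions per behavioural measure,
#' with percentile-bootstrap CIs of the cluster-averaged correlations.
#'
#' Subjects with an empty report-by-direction cell (no usable trials of some
#' type) are dropped with a warning and recorded in the report.
#'
#' @param cohort a `prestim_cohort` (or list of subjects with `trials` and
#'   `epochs`).
#' @param config an [analysis_config()].
#' @return Object of class `prestim_report`.
#' @export
run_pipeline <- function(cohort, config = analysis_config()) {
  layout <- attr(cohort, "layout") %||% cohort[[1]]$epochs$layout
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  behavior <- stage("behavior", lapply(cohort, function(s) {
    tr <- classify_trials(s$trials)
    tr <- filter_rts(tr, config$rt_bounds[1], config$rt_bounds[2])
    summarize_behavior(tr)
  }))

  preps <- vector("list", length(cohort))
  dropped <- character(0)
  for (i in seq_along(cohort)) {
    preps[[i]] <- tryCatch(
      prepare_subject(cohort[[i]], config, seed = derive_seed(seed, 100 + i)),
      error = function(e) e)
    if (inherits(preps[[i]], "error")) {
      id <- cohort[[i]]$profile$subject_id %||% as.character(i)
      warning("dropping subject ", id, ": ",
              conditionMessage(preps[[i]]), call. = FALSE)
      dropped <- c(dropped, id)
      preps[[i]] <- NULL
    }
  }
  preps <- Filter(Negate(is.null), preps)
  keep_beh <- !(vapply(cohort, function(s)
    s$profile$subject_id %||% "", "") %in% dropped)
  behavior <- behavior[keep_beh]
  if (length(preps) < 4L) stop("fewer than 4 usable subjects")
  n_sub <- length(preps)

  # --- POS arm (pooled directions), per channel then planar-combined
  pos_res <- stage("pos", {
    obs_maps <- lapply(preps, function(p)
      pos_observed(p$phasors, p$labels))
    snulls <- lapply(seq_len(n_sub), function(i)
      subject_null(preps[[i]]$phasors, preps[[i]]$labels,
                   n_perm = config$n_subject_perm,
                   seed = derive_seed(seed, 200 + i)))
    if (layout$channel_kind == "planar_pair") {
      obs_maps <- lapply(obs_maps, combine_planar,
                         site = layout$site, dim = 1L)
      for (i in seq_along(snulls)) {
        sm <- snulls[[i]]$samples                # points x draws
        a <- array(sm, c(snulls[[i]]$map_dim, ncol(sm)))
        a <- combine_planar(a, site = layout$site, dim = 1L)
        snulls[[i]]$samples <- matrix(a, ncol = ncol(sm))
        snulls[[i]]$map_dim <- dim(a)[1:2]
      }
      pos_layout <- grid_layout(
        n_rows = max(layout$positions[, 2]),
        n_cols = max(layout$positions[, 1]))
    } else pos_layout <- layout
    gnull <- group_null(snulls, n_draws = config$n_group_perm,
                        seed = derive_seed(seed, 300))
    g_obs <- Reduce(`+`, obs_maps) / n_sub
    test <- cluster_permutation_pos(g_obs, gnull, pos_layout,
                                    config$pos_config,
                                    seed = derive_seed(seed, 301))
    list(test = test, observed = g_obs, z = zscore_pos(g_obs, gnull))
  })

  # --- pooled ILL vs no-ILL power contrast
  site_layout <- if (layout$channel_kind == "planar_pair")
    grid_layout(n_rows = max(layout$positions[, 2]),
                n_cols = max(layout$positions[, 1])) else layout
  contrast <- stage("power-contrast", {
    ill <- stack_first(lapply(preps, condition_mean_power, label = "ILL"))
    nil <- stack_first(lapply(preps, condition_mean_power, label = "no-ILL"))
    power_contrast(ill, nil, site_layout, config$contrast_config,
                   seed = derive_seed(seed, 400))
  })

  # --- per-direction brain-behaviour correlations
  directions <- sort(unique(preps[[1]]$direction))
  measures <- c("illusion_rate", "criterion")
  correlations <- list()
  maps <- list()
  for (dir in directions) {
    brain <- stage("power-diff", stack_first(lapply(preps, function(p)
      condition_mean_power(p, "ILL", dir) -
        condition_mean_power(p, "no-ILL", dir))))
    for (ms in measures) {
      beh <- vapply(behavior, function(b)
        if (ms == "illusion_rate") b[[dir]]$illusion_rate else b[[dir]]$c, 0)
      key <- paste(dir, ms, sep = ".")
      correlations[[key]] <- stage(
        paste0("correlation-", key),
        cluster_permutation_correlation(
          brain, beh, site_layout, config$corr_config,
          seed = derive_seed(seed, 500 + length(correlations))))
      maps[[key]] <- correlations[[key]]$map
      sig <- significant_clusters(correlations[[key]])
      correlations[[key]]$cluster_ci <- lapply(sig, function(cl) {
        avg <- matrix(brain, nrow = n_sub)[, cl$points, drop = FALSE]
        bootstrap_ci(rowMeans(avg), beh, n_boot = config$n_boot,
                     seed = derive_seed(seed, 600 + length(correlations)))
      })
    }
  }

  conjunctions <- list()
  if (length(directions) == 2L) {
    for (ms in measures) {
      a <- maps[[paste(directions[1], ms, sep = ".")]]
      b <- maps[[paste(directions[2], ms, sep = ".")]]
      conjunctions[[ms]] <- stage(
        paste0("conjunction-", ms),
        conjunction_test(a, b, site_layout, config$conj_config,
                         seed = derive_seed(seed, 700 + length(conjunctions))))
    }
  }

  structure(list(behavior = behavior, pos = pos_res, contrast = contrast,
                 correlations = correlations, conjunctions = conjunctions,
                 dropped_subjects = dropped, n_subjects = n_sub,
                 config = config, times = preps[[1]]$times),
            class = "prestim_report")
}

#' @export
print.prestim_report <- function(x, ...) {
  cat("Prestimulus oscillation analysis report\n")
  cat(sprintf("  %d subjects analysed%s\n", x$n_subjects,
              if (length(x$dropped_subjects))
                paste0(" (dropped: ",
                       paste(x$dropped_subjects, collapse = ", "), ")")
              else ""))
  rates <- vapply(x$behavior, function(b) b$pooled$illusion_rate, 0)
  crits <- vapply(x$behavior, function(b) b$pooled$c, 0)
  cat(sprintf("  illusion rate %.0f%% (range %.0f-%.0f%%), median c %+.2f\n",
              100 * mean(rates), 100 * min(rates), 100 * max(rates),
              stats::median(crits)))
  summ <- function(label, ct) {
    sig <- significant_clusters(ct)
    cat(sprintf("  %-28s %d cluster(s), %d significant", label,
                length(ct$clusters), length(sig)))
    if (length(sig))
      cat(sprintf("; best p = %.4f", min(vapply(sig, `[[`, 0, "p"))))
    cat("\n")
  }
  summ("POS (pooled)", x$pos$test)
  summ("power contrast (pooled)", x$contrast)
  for (nm in names(x$correlations)) summ(paste0("corr ", nm),
                                         x$correlations[[nm]])
  for (nm in names(x$conjunctions)) summ(paste0("conjunction ", nm),
                                         x$conjunctions[[nm]])
  invisible(x)
}
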