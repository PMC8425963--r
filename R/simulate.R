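#' Simulate multi-sensor epochs with an injectable prestimulus alpha effect
#'
#' Generates one epoch per trial on every channel of `layout`: spectrally
#' shaped 1/f^a Gaussian background noise (unit variance), a sustained
#' alpha-band oscillation with trial-varying amplitude and phase, and a small
#' evoked-like transient after each flash onset. On the designated *effect
#' sensors* all channels share a single per-trial alpha phase and amplitude;
#' these latent values are returned so [simulate_responses()] can couple the
#' behavioural report to them. All other channels receive alpha with
#' independent random phase per trial, so no phase-opposition or power effect
#' can arise there.
#'
#' The latent phase is parameterised at a fixed reference time `phase_ref`
#' (default -0.4 s, the centre of the usual prestimulus window): the injected
#' oscillation is `a * cos(2*pi*f*(t - phase_ref) + phi)`, so the
#' instantaneous phase at `phase_ref` equals the latent `phi` exactly.
#'
#' @param trials trial table from [generate_design()].
#' @param profile a [subject_profile()].
#' @param layout a [grid_layout()] sensor layout.
#' @param design the [study_design()] that produced `trials`.
#' @param seed integer seed.
#' @param effect_sensors integer channel indices carrying the coupled alpha;
#'   default: all channels of the 4 sites closest to the layout centre.
#' @param alpha_freq alpha frequency in Hz (default 10).
#' @param phase_ref time (s) at which the latent phase is defined.
#' @param amp_sdlog log-scale SD of the trial-to-trial alpha amplitude.
#' @param evoked_amp amplitude of the post-flash evoked transient.
#' @param noise_sd standard deviation of the background noise (0 disables
#'   it, useful for oracle checks).
#' @return A list of class `epoch_set`: `data` (trials x sensors x time
#'   array), `times`, `sampling_rate`, `trial_ids`, `subject_id`, `layout`,
#'   `effect_sensors`, and `latent` (data.frame with per-trial `alpha_phase`,
#'   `alpha_amp`, `alpha_power`).
#' @export
simulate_epochs <- function(trials, profile, layout, design, seed = 1L,
                            effect_sensors = NULL, alpha_freq = 10,
                            phase_ref = -0.4, amp_sdlog = 0.4,
                            evoked_amp = 1.5, noise_sd = 1) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(layout, "sensor_layout"),
            inherits(design, "study_design"))
  win <- design$epoch_window
  if (diff(win) < 1 / alpha_freq)
    stop("epoch window shorter than one alpha cycle")
  fs <- design$sampling_rate
  nt <- nrow(trials)
  ns <- length(layout$sensor_ids)
  ntime <- round(diff(win) * fs) + 1L
  times <- win[1] + (seq_len(ntime) - 1L) / fs
  if (is.null(effect_sensors))
    effect_sensors <- default_effect_sensors(layout)
  effect_sensors <- sort(unique(as.integer(effect_sensors)))
  if (any(effect_sensors < 1L | effect_sensors > ns))
    stop("effect_sensors out of range")

  rng <- local_rng(seed)
  # 1/f^a coloured noise, fft-shaped at a composite length, unit variance
  ncol_all <- nt * ns
  nfft <- stats::nextn(ntime)
  w <- matrix(stats::rnorm(nfft * ncol_all), nrow = nfft)
  fgrid <- c(0, seq_len(nfft - 1)) * fs / nfft
  fgrid <- pmin(fgrid, fs - fgrid)            # two-sided spectrum
  gain <- c(0, fgrid[-1]^(-profile$noise_exponent / 2))
  gain <- gain / sqrt(mean(gain^2))
  noise <- Re(stats::mvfft(stats::mvfft(w) * gain, inverse = TRUE)) / nfft
  data <- aperm(array(noise_sd * noise[seq_len(ntime), , drop = FALSE],
                      dim = c(ntime, nt, ns)), c(2L, 3L, 1L))

  # sustained alpha: shared latent phase/amplitude on effect sensors,
  # independent phase/amplitude elsewhere
  carrier <- exp(1i * 2 * pi * alpha_freq * (times - phase_ref))
  amp <- profile$alpha_amplitude * exp(stats::rnorm(nt, 0, amp_sdlog))
  phi <- stats::runif(nt, -pi, pi)
  shared <- Re(outer(amp * exp(1i * phi), carrier))
  for (s in effect_sensors) data[, s, ] <- data[, s, ] + shared
  other <- setdiff(seq_len(ns), effect_sensors)
  if (length(other) > 0L) {
    amp_o <- profile$alpha_amplitude *
      exp(stats::rnorm(nt * length(other), 0, amp_sdlog))
    phi_o <- stats::runif(nt * length(other), -pi, pi)
    bg <- Re(outer(amp_o * exp(1i * phi_o), carrier))
    data[, other, ] <- data[, other, , drop = FALSE] +
      array(bg, dim = c(nt, length(other), ntime))
  }

  # evoked-like transients ~100 ms after each flash onset, all sensors
  if (evoked_amp != 0) {
    for (dir in unique(trials$direction)) {
      onsets <- (0:2) * design$soa[[dir]]
      ev <- rowSums(vapply(onsets, function(on)
        evoked_amp * exp(-(times - on - 0.1)^2 / (2 * 0.03^2)),
        numeric(ntime)))
      idx <- which(trials$direction == dir)
      data[idx, , ] <- data[idx, , , drop = FALSE] +
        rep(ev, each = length(idx) * ns)
    }
  }
  rng$restore()

  latent <- data.frame(trial = trials$trial, alpha_phase = phi,
                       alpha_amp = amp, alpha_power = amp^2)
  structure(list(
    data = data, times = times, sampling_rate = fs,
    trial_ids = trials$trial, subject_id = profile$subject_id,
    layout = layout, effect_sensors = effect_sensors,
    alpha_freq = alpha_freq, phase_ref = phase_ref, latent = latent
  ), class = "epoch_set")
}

default_effect_sensors <- function(layout, n_sites = 4L) {
  pos <- layout$positions
  sites <- layout$site
  upos <- pos[!duplicated(sites), , drop = FALSE]
  usite <- sites[!duplicated(sites)]
  ctr <- colMeans(upos)
  d <- sqrt((upos[, 1] - ctr[1])^2 + (upos[, 2] - ctr[2])^2)
  keep <- usite[order(d)][seq_len(min(n_sites, length(usite)))]
  which(sites %in% keep)
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Epoch set '%s': %d trials x %d sensors x %d samples @ %g Hz\n",
              x$subject_id, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$sampling_rate))
  cat(sprintf("  time %.3f..%.3f s; %d effect sensors\n",
              x$times[1], x$times[length(x$times)], length(x$effect_sensors)))
  invisible(x)
}

#' Simulate behavioural responses coupled to latent oscillatory state
#'
#' Fills in `response` and `rt` for every trial. On test trials the
#' probability of reporting the illusory (intermediate) percept is
#' `plogis(qlogis(base) + power_bias_coupling * (2*base - 1) * z_power
#' + phase_coupling * cos(phase - preferred_phase))`, where `z_power` is the
#' latent single-trial alpha power standardised within subject and `phase` is
#' the latent prestimulus alpha phase. The graded bias weight `2*base - 1`
#' (the subject's bias away from indifference, in [-1, 1]) makes the
#' power effect push perception toward the subject's own prior, with a
#' strength growing with how pronounced that prior is; across subjects this
#' yields a monotone relation between the power difference and the illusion
#' rate. Control trials are answered correctly
#' (response `"intermediate"`, since the control sequence really is
#' intermediate) with fixed probability `control_accuracy`. Response times are
#' log-normal with a faster location for control trials.
#'
#' @param trials trial table from [generate_design()].
#' @param profile a [subject_profile()].
#' @param latent per-trial latent data.frame (from [simulate_epochs()]),
#'   aligned to `trials$trial`.
#' @param seed integer seed.
#' @param control_accuracy probability a control trial is answered correctly.
#' @param rt_meanlog named log-scale RT locations for test/control trials (s).
#' @param rt_sdlog log-scale RT spread.
#' @return `trials` with `response` (`"intermediate"`/`"not-intermediate"`)
#'   and `rt` filled in.
#' @export
simulate_responses <- function(trials, profile, latent, seed = 1L,
                               control_accuracy = 0.81,
                               rt_meanlog = c(test = log(0.75),
                                              control = log(0.6)),
                               rt_sdlog = 0.6) {
  stopifnot(inherits(profile, "subject_profile"))
  if (is.null(latent) || !all(c("alpha_phase", "alpha_power") %in%
                              names(latent)))
    stop("missing latent values: need alpha_phase and alpha_power per trial")
  ord <- match(trials$trial, latent$trial)
  if (anyNA(ord)) stop("missing latent values for some trials")
  phase <- latent$alpha_phase[ord]
  pw <- latent$alpha_power[ord]
  z_power <- as.numeric(scale(pw))
  if (all(!is.finite(z_power))) z_power <- rep(0, length(pw))

  rng <- local_rng(seed)
  bias <- 2 * profile$base_illusion_rate - 1
  eta <- stats::qlogis(profile$base_illusion_rate) +
    profile$power_bias_coupling * bias * z_power +
    profile$phase_coupling * cos(phase - profile$preferred_phase)
  p_ill <- stats::plogis(eta)
  is_test <- trials$condition == "test"
  u <- stats::runif(nrow(trials))
  resp <- character(nrow(trials))
  resp[is_test] <- ifelse(u[is_test] < p_ill[is_test],
                          "intermediate", "not-intermediate")
  resp[!is_test] <- ifelse(u[!is_test] < control_accuracy,
                           "intermediate", "not-intermediate")
  ml <- ifelse(is_test, rt_meanlog[["test"]], rt_meanlog[["control"]])
  rt <- stats::rlnorm(nrow(trials), meanlog = ml, sdlog = rt_sdlog)
  rng$restore()

  trials$response <- resp
  trials$rt <- rt
  trials
}

#' Simulate a cohort of subjects
#'
#' Draws one subject profile per subject (baseline illusion rates uniform over
#' `base_rate_range`, preferred phases uniform on the circle, shared coupling
#' weights), then simulates the session design, epochs and responses for each.
#' With both couplings at 0 the cohort is an exact null for every downstream
#' phase or power test.
#'
#' @param n_subjects number of subjects.
#' @param design a [study_design()].
#' @param layout a [grid_layout()].
#' @param seed master integer seed; per-subject seeds are derived from it.
#' @param base_rate_range range of baseline illusion rates across subjects.
#' @param power_bias_coupling,phase_coupling coupling weights shared by all
#'   subjects (see [subject_profile()]).
#' @param alpha_amplitude,noise_exponent passed to every profile.
#' @param ... further arguments passed to [simulate_epochs()].
#' @return List of class `prestim_cohort`; each element has `profile`,
#'   `trials` (with responses and labels), `epochs`, `latent`.
#' @export
simulate_cohort <- function(n_subjects = 13L, design = study_design(),
                            layout = grid_layout(), seed = 1L,
                            base_rate_range = c(0.12, 0.95),
                            power_bias_coupling = 0, phase_coupling = 0,
                            alpha_amplitude = 1, noise_exponent = 1, ...) {
  rng <- local_rng(derive_seed(seed, 1L))
  rates <- stats::runif(n_subjects, base_rate_range[1], base_rate_range[2])
  prefs <- stats::runif(n_subjects, -pi, pi)
  rng$restore()
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    profile <- subject_profile(
      subject_id = sprintf("s%02d", i),
      base_illusion_rate = rates[i],
      power_bias_coupling = power_bias_coupling,
      phase_coupling = phase_coupling,
      preferred_phase = prefs[i],
      alpha_amplitude = alpha_amplitude,
      noise_exponent = noise_exponent)
    trials <- generate_design(design, seed = derive_seed(seed, 10L + 3L * i))
    epochs <- simulate_epochs(trials, profile, layout, design,
                              seed = derive_seed(seed, 11L + 3L * i), ...)
    trials <- simulate_responses(trials, profile, epochs$latent,
                                 seed = derive_seed(seed, 12L + 3L * i))
    trials <- classify_trials(trials)
    subjects[[i]] <- list(profile = profile, trials = trials,
                          epochs = epochs, latent = epochs$latent)
  }
  structure(subjects, class = "prestim_cohort",
            layout = layout, design = design, seed = seed)
}

#' @export
print.prestim_cohort <- function(x, ...) {
  rates <- vapply(x, function(s) {
    tt <- s$trials[s$trials$condition == "test", ]
    mean(tt$label == "ILL", na.rm = TRUE)
  }, 0)
  cat(sprintf("Simulated cohort: %d subjects, %d trials each\n",
              length(x), nrow(x[[1]]$trials)))
  cat(sprintf("  empirical illusion label fraction %.2f..%.2f\n",
              min(rates), max(rates)))
  invisible(x)
}
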