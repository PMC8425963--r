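#' Study design for a three-flash apparent-motion session
#'
#' Describes one recording session: how many blocks are run, how many test
#' (illusion-inducing) and control (veridical) trials of each motion direction
#' each block contains, the flash stimulus-onset asynchrony per direction, the
#' inter-trial interval range, and the epoching parameters used when cutting
#' continuous data around the first flash.
#'
#' Defaults reproduce the session structure of the study the package models:
#' 5 blocks, 60 test and 30 control trials per direction per block (900 trials
#' in total), SOA 188 ms for inward and 272 ms for outward sequences, ITI
#' uniform on 0.8--1.3 s, and 2 s epochs from -0.8 to +1.2 s around the first
#' flash sampled at 333 Hz.
#'
#' @param n_blocks number of blocks.
#' @param test_per_block_per_direction test trials per direction in each block.
#' @param control_per_block_per_direction control trials per direction in each
#'   block.
#' @param soa named numeric, stimulus-onset asynchrony (s) per direction.
#' @param iti_range length-2 numeric, uniform inter-trial interval bounds (s).
#' @param epoch_window length-2 numeric, epoch start/end (s) relative to the
#'   first flash; must straddle 0.
#' @param sampling_rate sampling rate of generated epochs (Hz).
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_blocks = 5L,
                         test_per_block_per_direction = 60L,
                         control_per_block_per_direction = 30L,
                         soa = c(inward = 0.188, outward = 0.272),
                         iti_range = c(0.8, 1.3),
                         epoch_window = c(-0.8, 1.2),
                         sampling_rate = 333) {
  n_blocks <- as.integer(n_blocks)
  ntest <- as.integer(test_per_block_per_direction)
  nctrl <- as.integer(control_per_block_per_direction)
  if (n_blocks < 1L || ntest < 1L || nctrl < 1L)
    stop("invalid design: all counts must be positive")
  if (length(iti_range) != 2L || iti_range[1] >= iti_range[2])
    stop("invalid design: iti_range must be increasing [low, high]")
  if (length(epoch_window) != 2L ||
      !(epoch_window[1] < 0 && epoch_window[2] > 0))
    stop("invalid design: epoch_window must satisfy start < 0 < end")
  if (sampling_rate <= 0) stop("invalid design: sampling_rate must be > 0")
  if (is.null(names(soa)) || !setequal(names(soa), c("inward", "outward")))
    stop("invalid design: soa must be named for both directions")
  structure(list(
    n_blocks = n_blocks,
    test_per_block_per_direction = ntest,
    control_per_block_per_direction = nctrl,
    directions = c("inward", "outward"),
    soa = soa[c("inward", "outward")],
    iti_range = as.numeric(iti_range),
    epoch_window = as.numeric(epoch_window),
    sampling_rate = as.numeric(sampling_rate)
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  per_block <- 2L * (x$test_per_block_per_direction +
                       x$control_per_block_per_direction)
  cat("Study design:", x$n_blocks, "blocks x", per_block, "trials",
      sprintf("(%d total)\n", x$n_blocks * per_block))
  cat(sprintf("  test %d / control %d per direction per block\n",
              x$test_per_block_per_direction,
              x$control_per_block_per_direction))
  cat(sprintf("  SOA inward %.0f ms, outward %.0f ms; ITI %.2f-%.2f s\n",
              1000 * x$soa[["inward"]], 1000 * x$soa[["outward"]],
              x$iti_range[1], x$iti_range[2]))
  cat(sprintf("  epochs %.2f..%.2f s @ %g Hz\n",
              x$epoch_window[1], x$epoch_window[2], x$sampling_rate))
  invisible(x)
}

#' Subject profile controlling simulated behaviour and oscillations
#'
#' A subject is characterised by a baseline propensity to report the illusion,
#' and by how strongly the single-trial prestimulus alpha oscillation is
#' coupled to that report. `power_bias_coupling` scales a power-by-bias term
#' (high alpha power pushes the report toward the subject's own bias, i.e.
#' toward the illusion for high-rate subjects and away from it for low-rate
#' subjects); `phase_coupling` scales a cosine tuning of the report to the
#' prestimulus alpha phase around `preferred_phase`. Both default to 0, which
#' makes the subject a true null for every downstream test.
#'
#' @param subject_id identifier.
#' @param base_illusion_rate baseline probability of reporting the illusion on
#'   a test trial, in (0, 1).
#' @param power_bias_coupling dimensionless logistic weight of the
#'   power-by-bias effect.
#' @param phase_coupling dimensionless logistic weight of the phase effect.
#' @param preferred_phase phase angle (rad) at which illusion reports peak.
#' @param alpha_amplitude amplitude of the injected alpha oscillation
#'   (signal units; noise has unit standard deviation).
#' @param noise_exponent spectral exponent of the 1/f^a background noise.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id = "s01",
                            base_illusion_rate = 0.5,
                            power_bias_coupling = 0,
                            phase_coupling = 0,
                            preferred_phase = 0,
                            alpha_amplitude = 1,
                            noise_exponent = 1) {
  if (!(base_illusion_rate > 0 && base_illusion_rate < 1))
    stop("base_illusion_rate must lie in (0, 1)")
  if (alpha_amplitude < 0) stop("alpha_amplitude must be >= 0")
  structure(list(
    subject_id = as.character(subject_id),
    base_illusion_rate = base_illusion_rate,
    power_bias_coupling = power_bias_coupling,
    phase_coupling = phase_coupling,
    preferred_phase = preferred_phase,
    alpha_amplitude = alpha_amplitude,
    noise_exponent = noise_exponent
  ), class = "subject_profile")
}

#' Rectangular sensor layout with rook adjacency
#'
#' Builds a simple grid of sensors with 4-neighbour (rook) spatial adjacency,
#' the smallest structure that exercises spatiotemporal clustering. In
#' `planar_pair` mode each grid site carries two orthogonal channels (as on
#' planar gradiometer arrays); the two channels of a site are mutual
#' neighbours and inherit the site adjacency.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param channel_kind `"single"` (one channel per site) or `"planar_pair"`.
#' @return An object of class `sensor_layout` with elements `sensor_ids`,
#'   `positions` (2-column matrix), `adjacency` (2-column integer matrix of
#'   sensor-index pairs, each pair once with first < second), `channel_kind`,
#'   and for planar layouts `site` (site index per channel).
#' @export
grid_layout <- function(n_rows = 8L, n_cols = 8L,
                        channel_kind = c("single", "planar_pair")) {
  channel_kind <- match.arg(channel_kind)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("grid dimensions must be positive")
  n_sites <- n_rows * n_cols
  pos <- cbind(col = rep(seq_len(n_cols), each = n_rows),
               row = rep(seq_len(n_rows), times = n_cols))
  # rook adjacency between sites
  site_id <- matrix(seq_len(n_sites), nrow = n_rows)
  horiz <- cbind(as.vector(site_id[, -n_cols, drop = FALSE]),
                 as.vector(site_id[, -1, drop = FALSE]))
  vert <- cbind(as.vector(site_id[-n_rows, , drop = FALSE]),
                as.vector(site_id[-1, , drop = FALSE]))
  adj <- rbind(if (n_cols > 1L) horiz, if (n_rows > 1L) vert)
  if (is.null(adj)) adj <- matrix(integer(0), ncol = 2L)
  if (channel_kind == "single") {
    layout <- list(
      sensor_ids = sprintf("S%03d", seq_len(n_sites)),
      positions = pos,
      adjacency = adj,
      channel_kind = channel_kind,
      site = seq_len(n_sites)
    )
  } else {
    # two orthogonal channels per site: channels 2k-1, 2k belong to site k
    chan_of <- function(site, which) 2L * (site - 1L) + which
    pairs <- list(cbind(chan_of(seq_len(n_sites), 1L),
                        chan_of(seq_len(n_sites), 2L)))
    for (w1 in 1:2) for (w2 in 1:2)
      pairs[[length(pairs) + 1L]] <-
        cbind(chan_of(adj[, 1], w1), chan_of(adj[, 2], w2))
    adj2 <- do.call(rbind, pairs)
    adj2 <- cbind(pmin(adj2[, 1], adj2[, 2]), pmax(adj2[, 1], adj2[, 2]))
    adj2 <- unique(adj2)
    layout <- list(
      sensor_ids = sprintf("S%03d%s", rep(seq_len(n_sites), each = 2L),
                           rep(c("a", "b"), n_sites)),
      positions = pos[rep(seq_len(n_sites), each = 2L), , drop = FALSE],
      adjacency = adj2,
      channel_kind = channel_kind,
      site = rep(seq_len(n_sites), each = 2L)
    )
  }
  class(layout) <- "sensor_layout"
  validate_layout(layout)
  layout
}

validate_layout <- function(layout) {
  n <- length(layout$sensor_ids)
  adj <- layout$adjacency
  if (nrow(adj) > 0) {
    if (any(adj[, 1] == adj[, 2])) stop("adjacency must be irreflexive")
    if (any(adj < 1L | adj > n)) stop("adjacency refers to unknown sensors")
  }
  if (n > 1L && length(unique(c(adj))) < n)
    stop("every sensor needs at least one neighbour")
  invisible(layout)
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat(sprintf("Sensor layout: %d channels (%s), %d adjacency pairs\n",
              length(x$sensor_ids), x$channel_kind, nrow(x$adjacency)))
  invisible(x)
}

#' Neighbour list from a sensor layout
#'
#' @param layout a `sensor_layout`.
#' @return list of integer vectors, neighbours of each sensor.
#' @export
adjacency_list <- function(layout) {
  n <- length(layout$sensor_ids)
  nb <- vector("list", n)
  adj <- layout$adjacency
  for (k in seq_len(nrow(adj))) {
    a <- adj[k, 1]; b <- adj[k, 2]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  lapply(nb, function(v) sort(unique(v)))
}

#' Generate the trial list of one session
#'
#' Expands a [study_design()] into a per-trial table with block-wise shuffled
#' order and uniform inter-trial intervals; responses are left unset (NA)
#' until [simulate_responses()] fills them in.
#'
#' @param design a `study_design`.
#' @param seed integer seed; the result is reproducible bit-for-bit.
#' @return A `data.frame` with columns `trial`, `block`, `condition`
#'   (`test`/`control`), `direction` (`inward`/`outward`), `soa`, `iti`,
#'   `response` (NA), `rt` (NA).
#' @export
generate_design <- function(design, seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  rng <- local_rng(seed)
  one_block <- function(b) {
    cond <- rep(c("test", "control"),
                times = 2 * c(design$test_per_block_per_direction,
                              design$control_per_block_per_direction))
    dir <- c(rep(c("inward", "outward"),
                 each = design$test_per_block_per_direction),
             rep(c("inward", "outward"),
                 each = design$control_per_block_per_direction))
    n <- length(cond)
    ord <- sample.int(n)
    data.frame(block = b, condition = cond[ord], direction = dir[ord],
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(design$n_blocks), one_block))
  out$trial <- seq_len(nrow(out))
  out$soa <- design$soa[out$direction]
  out$iti <- stats::runif(nrow(out), design$iti_range[1], design$iti_range[2])
  out$response <- NA_character_
  out$rt <- NA_real_
  rng$restore()
  out[, c("trial", "block", "condition", "direction", "soa", "iti",
          "response", "rt")]
}
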