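#' Cycle count of a fixed-bandwidth Morlet wavelet
#'
#' The wavelet family is parameterised by a fixed spectral bandwidth, defined
#' as twice the spectral standard deviation of the Gaussian kernel. A Morlet
#' wavelet with `n` cycles at centre frequency `f` has temporal SD
#' `n / (2*pi*f)` and spectral SD `f / n`, so a fixed bandwidth `b` implies
#' `n = 2 f / b`: the cycle count grows linearly with frequency while the
#' temporal extent of the wavelet stays constant at `1 / (pi * b)` seconds.
#'
#' @param f centre frequency (Hz).
#' @param bandwidth spectral bandwidth (Hz), twice the spectral SD.
#' @return Number of cycles (vectorised over `f`).
#' @export
cycles_for_frequency <- function(f, bandwidth = 3) {
  if (any(f <= 0) || bandwidth <= 0)
    stop("frequency and bandwidth must be positive")
  2 * f / bandwidth
}

#' Canonical frequency bands
#'
#' @return Named list of `[low, high]` Hz ranges: theta 4-7, alpha 8-12,
#'   beta 13-30, low_gamma 30-45, high_gamma 60-100.
#' @export
default_bands <- function() {
  list(theta = c(4, 7), alpha = c(8, 12), beta = c(13, 30),
       low_gamma = c(30, 45), high_gamma = c(60, 100))
}

#' Frequency band definition
#'
#' @param name one of the canonical band names, or any label when `range` is
#'   given explicitly.
#' @param range optional `[low, high]` Hz; defaults to the canonical range.
#' @return List with `name` and `range`.
#' @export
band_definition <- function(name, range = NULL) {
  if (is.null(range)) {
    bands <- default_bands()
    if (!name %in% names(bands)) stop("unknown band: ", name)
    range <- bands[[name]]
  }
  if (length(range) != 2L || range[1] >= range[2])
    stop("band range must be increasing [low, high]")
  list(name = name, range = as.numeric(range))
}

#' Single-trial Morlet wavelet transform
#'
#' Convolves every trial and channel with complex Morlet wavelets whose
#' spectral bandwidth is fixed (see [cycles_for_frequency()]); no baseline
#' normalisation is applied. Kernels are normalised so that a pure cosine of
#' amplitude `a` at a centre frequency yields coefficients of modulus `a`
#' (power `a^2`) and argument equal to the instantaneous phase.
#'
#' @param epochs an `epoch_set`.
#' @param freqs centre frequencies (Hz).
#' @param bandwidth spectral bandwidth (Hz).
#' @param n_sd Gaussian truncation, in temporal SDs on each side.
#' @param window optional `[start, end]` seconds; when given, coefficients
#'   are computed only at samples inside the window (direct convolution at
#'   those samples, numerically identical to the full transform followed by
#'   [extract_prestim()]).
#' @return Object of class `tf_result`: complex `coefficients` array
#'   (trials x sensors x frequencies x time), plus `times`, `freqs`,
#'   `sampling_rate`, `trial_ids`, `layout`, `bandwidth`.
#' @export
morlet_transform <- function(epochs, freqs, bandwidth = 3, n_sd = 4,
                             window = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  freqs <- sort(as.numeric(freqs))
  if (any(freqs <= 0)) stop("frequencies must be positive")
  fs <- epochs$sampling_rate
  d <- dim(epochs$data)
  nt <- d[1]; ns <- d[2]; ntime <- d[3]
  sigma_t <- 1 / (pi * bandwidth)        # constant across frequencies
  half <- ceiling(n_sd * sigma_t * fs)
  klen <- 2L * half + 1L
  if (klen > ntime)
    stop(sprintf(
      "wavelet (%d samples) longer than epoch (%d samples) at %g Hz",
      klen, ntime, freqs[1]))
  tk <- (-half:half) / fs
  env <- exp(-tk^2 / (2 * sigma_t^2))
  scale <- sum(env) / 2

  if (!is.null(window)) {
    # direct convolution at the requested output samples only
    tol <- 1e-9
    if (window[1] >= window[2]) stop("window must be increasing")
    out_idx <- which(epochs$times >= window[1] - tol &
                       epochs$times <= window[2] + tol)
    if (length(out_idx) == 0L) stop("window outside the epoch time range")
    x <- matrix(epochs$data, nrow = nt * ns)       # (trial*sensor) x time
    coef <- array(0i, dim = c(nt, ns, length(freqs), length(out_idx)))
    for (k in seq_along(freqs)) {
      kern <- env * exp(1i * 2 * pi * freqs[k] * tk) / scale
      K <- matrix(0i, ntime, length(out_idx))
      for (j in seq_along(out_idx)) {
        tj <- out_idx[j]
        src <- max(1L, tj - half):min(ntime, tj + half)
        K[src, j] <- kern[tj - src + half + 1L]
      }
      y <- x %*% Re(K) + (1i) * (x %*% Im(K))
      coef[, , k, ] <- array(y, dim = c(nt, ns, length(out_idx)))
    }
    times <- epochs$times[out_idx]
  } else {
    L <- stats::nextn(ntime + klen - 1L)
    x <- matrix(aperm(epochs$data, c(3L, 1L, 2L)), nrow = ntime)
    X <- stats::mvfft(rbind(x, matrix(0, L - ntime, ncol(x))))
    coef <- array(0i, dim = c(nt, ns, length(freqs), ntime))
    for (k in seq_along(freqs)) {
      kern <- env * exp(1i * 2 * pi * freqs[k] * tk) / scale
      K <- stats::fft(c(kern, rep(0, L - klen)))
      y <- stats::mvfft(X * K, inverse = TRUE) / L
      y <- y[(half + 1L):(half + ntime), , drop = FALSE]
      coef[, , k, ] <- aperm(array(y, dim = c(ntime, nt, ns)), c(2L, 3L, 1L))
    }
    times <- epochs$times
  }
  structure(list(
    coefficients = coef, times = times, freqs = freqs,
    sampling_rate = fs, trial_ids = epochs$trial_ids,
    layout = epochs$layout, bandwidth = bandwidth,
    subject_id = epochs$subject_id
  ), class = "tf_result")
}

#' @export
print.tf_result <- function(x, ...) {
  d <- dim(x$coefficients)
  cat(sprintf(
    "Time-frequency result: %d trials x %d sensors x %d freqs x %d samples\n",
    d[1], d[2], d[3], d[4]))
  cat(sprintf("  freqs %s Hz (bandwidth %g Hz); time %.3f..%.3f s\n",
              paste(x$freqs, collapse = ", "), x$bandwidth,
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Power, phase and unit phasors of a time-frequency result
#'
#' @param tf a `tf_result`.
#' @return `tf_power`: squared modulus; `tf_phase`: argument in (-pi, pi];
#'   `tf_phasors`: coefficients normalised to unit modulus.
#' @export
tf_power <- function(tf) Mod(tf$coefficients)^2

#' @rdname tf_power
#' @export
tf_phase <- function(tf) Arg(tf$coefficients)

#' @rdname tf_power
#' @export
tf_phasors <- function(tf) {
  m <- Mod(tf$coefficients)
  m[m == 0] <- 1
  tf$coefficients / m
}

#' Intertrial phase coherence
#'
#' Length of the mean unit phasor across trials: 0 for uniformly scattered
#' phases, 1 for perfect phase locking. Input may be phases in radians or
#' complex coefficients/phasors; trials must be the first array dimension.
#'
#' @param x numeric array of phases or complex array, trials on dimension 1.
#' @return Array (or scalar) of ITC over the remaining dimensions.
#' @export
compute_itc <- function(x) {
  d <- dim(x) %||% length(x)
  if (d[1] < 2L) stop("ITC needs at least 2 trials")
  if (is.complex(x)) {
    m <- Mod(x)
    m[m == 0] <- 1
    u <- x / m
  } else {
    u <- exp(1i * x)
  }
  if (is.null(dim(x)) || length(dim(x)) == 1L) return(Mod(mean(u)))
  um <- matrix(u, nrow = d[1])
  res <- Mod(colSums(um)) / d[1]
  if (length(d) == 2L) res else array(res, dim = d[-1])
}

#' Average an array over centre frequencies within a band
#'
#' Arithmetic mean over the centre frequencies falling inside the band range,
#' both edges inclusive.
#'
#' @param x array (e.g. power or ITC) with a frequency dimension, or a
#'   `tf_result` (whose power is then averaged).
#' @param band a [band_definition()], band name, or `[low, high]` vector.
#' @param freqs centre frequencies along the frequency dimension (taken from
#'   `x` when it is a `tf_result`).
#' @param dim index of the frequency dimension (default: third for
#'   `tf_result` power, otherwise the unique dimension matching
#'   `length(freqs)`).
#' @return Array with the frequency dimension averaged out.
#' @export
band_average <- function(x, band, freqs = NULL, dim = NULL) {
  if (inherits(x, "tf_result")) {
    freqs <- x$freqs
    x <- tf_power(x)
    dim <- 3L
  }
  if (is.character(band)) band <- band_definition(band)
  rng <- if (is.list(band)) band$range else as.numeric(band)
  sel <- which(freqs >= rng[1] & freqs <= rng[2])
  if (length(sel) == 0L) stop("no centre frequencies inside band")
  if (is.null(dim(x))) return(mean(x[sel]))
  if (is.null(dim)) {
    dim <- which(dim(x) == length(freqs))
    if (length(dim) != 1L)
      stop("cannot infer the frequency dimension; pass `dim`")
  }
  d <- dim(x)
  idx <- rep(list(quote(expr = )), length(d))
  idx[[dim]] <- sel
  xs <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  others <- setdiff(seq_along(d), dim)
  m <- matrix(aperm(xs, c(others, dim)), ncol = length(sel))
  array(rowMeans(m), dim = d[others])
}

#' Combine planar-pair channels with the Euclidean norm
#'
#' Orthogonal planar channels at one site are collapsed into a single
#' per-site value `sqrt(x^2 + y^2)`.
#'
#' @param x numeric vector/array of per-channel values (e.g. band power or
#'   POS), channels along `dim`.
#' @param site integer site index per channel (two channels per site);
#'   default pairs consecutive channels.
#' @param dim channel dimension of `x`.
#' @return Array with the channel dimension reduced to one entry per site.
#' @export
combine_planar <- function(x, site = NULL, dim = 1L) {
  n <- if (is.null(dim(x))) length(x) else dim(x)[dim]
  if (is.null(site)) {
    if (n %% 2L != 0L) stop("unpaired channel: odd channel count")
    site <- rep(seq_len(n %/% 2L), each = 2L)
  }
  tab <- table(site)
  if (any(tab != 2L)) stop("unpaired channel: every site needs two channels")
  sites <- as.integer(names(tab))
  pick <- function(s) {
    ch <- which(site == s)
    if (is.null(dim(x))) return(sqrt(x[ch[1]]^2 + x[ch[2]]^2))
    d <- length(dim(x))
    idx1 <- idx2 <- rep(list(quote(expr = )), d)
    idx1[[dim]] <- ch[1]; idx2[[dim]] <- ch[2]
    a <- do.call(`[`, c(list(x), idx1, list(drop = FALSE)))
    b <- do.call(`[`, c(list(x), idx2, list(drop = FALSE)))
    sqrt(a^2 + b^2)
  }
  parts <- lapply(sites, pick)
  if (is.null(dim(x))) return(unlist(parts))
  do.call(function(...) abind_along(list(...), dim), parts)
}

# minimal abind: bind arrays along dimension `along`
abind_along <- function(lst, along) {
  d <- dim(lst[[1]])
  d[along] <- length(lst)
  perm <- c(along, setdiff(seq_along(d), along))
  flat <- vapply(lst, function(a) as.vector(aperm(a, perm)),
                 numeric(prod(dim(lst[[1]]))))
  out <- array(t(flat), dim = c(length(lst), dim(lst[[1]])[perm[-1]]))
  aperm(out, order(perm))
}

#' Restrict an object to the prestimulus window
#'
#' Keeps samples with time inside `window` (endpoints inclusive, default
#' -600 to -200 ms), the segment preceding the first flash that is free of
#' poststimulus contamination and wavelet edge effects.
#'
#' @param x an `epoch_set` or `tf_result`.
#' @param window `[start, end]` seconds.
#' @return Object of the same class with the time axis restricted.
#' @export
extract_prestim <- function(x, window = c(-0.6, -0.2)) {
  if (window[1] >= window[2]) stop("window must be increasing [start, end]")
  tol <- 1e-9
  if (window[1] < x$times[1] - tol ||
      window[2] > x$times[length(x$times)] + tol)
    stop("window outside the epoch time range")
  keep <- which(x$times >= window[1] - tol & x$times <= window[2] + tol)
  x$times <- x$times[keep]
  if (inherits(x, "epoch_set")) {
    x$data <- x$data[, , keep, drop = FALSE]
  } else if (inherits(x, "tf_result")) {
    x$coefficients <- x$coefficients[, , , keep, drop = FALSE]
  } else stop("unsupported object")
  x
}

#' Reject epochs exceeding a peak-amplitude threshold
#'
#' @param epochs an `epoch_set`.
#' @param threshold positive amplitude threshold (signal units); an epoch is
#'   dropped when any sample on any channel exceeds it in absolute value.
#' @return The `epoch_set` with offending epochs removed (a warning is given
#'   if none survive). Attribute `"n_rejected"` records the count.
#' @export
reject_epochs <- function(epochs, threshold) {
  if (threshold <= 0) stop("threshold must be positive")
  peak <- apply(abs(epochs$data), 1L, max)
  keep <- peak <= threshold
  if (!any(keep)) warning("all epochs rejected")
  out <- subset_epochs(epochs, which(keep))
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Subset an epoch set by trial position
#'
#' @param epochs an `epoch_set`.
#' @param idx integer positions (rows of the data tensor) to keep.
#' @return The restricted `epoch_set` (latent table subset alongside).
#' @export
subset_epochs <- function(epochs, idx) {
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$trial_ids <- epochs$trial_ids[idx]
  if (!is.null(epochs$latent))
    epochs$latent <- epochs$latent[idx, , drop = FALSE]
  epochs
}

#' Equalise trial counts across response-by-direction cells
#'
#' Randomly subsamples, without replacement, every cell of the grouping
#' (default perceptual report by sequence direction) down to the size of the
#' smallest cell, so that condition comparisons are not confounded by trial
#' counts. Reproducible given `seed`.
#'
#' @param trials labelled trial table.
#' @param keys column names defining the cells.
#' @param seed integer seed.
#' @return The subsampled trial table (original order preserved). An error is
#'   raised when any combination of observed key levels is empty.
#' @export
equalize_trials <- function(trials, keys = c("label", "direction"),
                            seed = 1L) {
  if (!all(keys %in% names(trials))) stop("missing grouping columns")
  levs <- lapply(keys, function(k) unique(trials[[k]]))
  combos <- expand.grid(levs, stringsAsFactors = FALSE)
  names(combos) <- keys
  counts <- vapply(seq_len(nrow(combos)), function(i) {
    sel <- rep(TRUE, nrow(trials))
    for (k in keys) sel <- sel & trials[[k]] == combos[i, k]
    sum(sel)
  }, 0L)
  if (any(counts == 0L)) stop("empty cell in trial equalisation")
  m <- min(counts)
  rng <- local_rng(seed)
  keep <- integer(0)
  for (i in seq_len(nrow(combos))) {
    sel <- rep(TRUE, nrow(trials))
    for (k in keys) sel <- sel & trials[[k]] == combos[i, k]
    rows <- which(sel)
    keep <- c(keep, if (length(rows) == 1L) rows else sample(rows, m))
  }
  rng$restore()
  trials[sort(keep), , drop = FALSE]
}
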