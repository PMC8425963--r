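#' Phase-opposition sum
#'
#' `POS = ITC_ill + ITC_noill - 2 * ITC_all`. With equal trial counts per
#' condition (enforce upstream with [equalize_trials()]), POS is near 0 when
#' both conditions share the same phase distribution and approaches 2 when
#' the two conditions are perfectly locked to opposite phases (the pooled
#' phasors then cancel). POS always lies in `[-2, 2]`.
#'
#' @param itc_ill,itc_noill,itc_all ITC arrays of identical shape.
#' @return Pointwise POS array of the same shape.
#' @export
compute_pos <- function(itc_ill, itc_noill, itc_all) {
  if (!identical(dim(itc_ill) %||% length(itc_ill),
                 dim(itc_noill) %||% length(itc_noill)) ||
      !identical(dim(itc_ill) %||% length(itc_ill),
                 dim(itc_all) %||% length(itc_all)))
    stop("ITC shape mismatch")
  itc_ill + itc_noill - 2 * itc_all
}

# Flatten a trials x sensors x freqs x time phasor array to a unit-phasor
# matrix (trials x points) plus the map dimensions.
phasor_matrix <- function(phasors) {
  d <- dim(phasors)
  if (length(d) == 3L) {                 # no frequency dimension: insert one
    dim(phasors) <- c(d[1], d[2], 1L, d[3])
    d <- dim(phasors)
  }
  if (length(d) != 4L)
    stop("phasors must be trials x sensors x freqs x time")
  if (!is.complex(phasors)) phasors <- exp(1i * phasors)
  m <- Mod(phasors); m[m == 0] <- 1
  list(u = matrix(phasors / m, nrow = d[1]), dims = d)
}

# Band-average over the frequency dimension of a draws x (S*F*T) matrix,
# returning draws x (S*T).
freq_average_rows <- function(mat, dims) {
  ns <- dims[2]; nf <- dims[3]; ntm <- dims[4]
  if (nf == 1L) return(mat)
  a <- array(mat, dim = c(nrow(mat), ns, nf, ntm))
  a <- aperm(a, c(3L, 1L, 2L, 4L))
  matrix(colMeans(a), nrow = nrow(mat))
}

# Same for a (S*F*T) x draws matrix, returning (S*T) x draws.
freq_average_cols <- function(mat, dims) {
  ns <- dims[2]; nf <- dims[3]; ntm <- dims[4]
  if (nf == 1L) return(mat)
  a <- array(mat, dim = c(ns, nf, ntm, ncol(mat)))
  a <- aperm(a, c(2L, 1L, 3L, 4L))
  matrix(colMeans(a), ncol = ncol(mat))
}

#' Observed POS map of one subject
#'
#' Computes the ITC of each condition and of all trials for every sensor,
#' centre frequency and time point, averages the ITCs across the centre
#' frequencies (band averaging), and forms the POS.
#'
#' @param phasors complex array trials x sensors x freqs x time (unit
#'   phasors; see [tf_phasors()]); a 3-d array is treated as a single
#'   frequency. Numeric input is interpreted as phases in radians.
#' @param labels per-trial condition labels with exactly two levels
#'   (`"ILL"`/`"no-ILL"`), or a logical vector marking the first condition.
#' @return POS matrix (sensors x time).
#' @export
pos_observed <- function(phasors, labels) {
  pm <- phasor_matrix(phasors)
  ill <- as_ill_logical(labels)
  if (length(ill) != pm$dims[1]) stop("labels do not match trial count")
  n1 <- sum(ill); n2 <- sum(!ill)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 trials per condition")
  s_all <- colSums(pm$u)
  s_ill <- colSums(pm$u[ill, , drop = FALSE])
  pos <- Mod(s_ill) / n1 + Mod(s_all - s_ill) / n2 -
    2 * Mod(s_all) / (n1 + n2)
  out <- freq_average_rows(matrix(pos, nrow = 1L), pm$dims)
  matrix(out, nrow = pm$dims[2])
}

as_ill_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  lev <- unique(labels)
  if (length(lev) != 2L) stop("labels must have exactly two levels")
  labels == if ("ILL" %in% lev) "ILL" else lev[1]
}

#' Subject-level POS permutation null
#'
#' Shuffles the condition labels over trials (preserving the label counts)
#' and recomputes the band-averaged POS map for each permutation.
#'
#' @inheritParams pos_observed
#' @param n_perm number of permutations (study default 1000).
#' @param seed integer seed.
#' @return Object of class `pos_null` with `level = "subject"`, `samples`
#'   (points x n_perm matrix, points in sensor-fastest column-major order),
#'   `map_dim` (sensors, time), `n_permutations`, `seed`.
#' @export
subject_null <- function(phasors, labels, n_perm = 1000L, seed = 1L) {
  pm <- phasor_matrix(phasors)
  ill <- as_ill_logical(labels)
  if (length(unique(ill)) < 2L) stop("both condition labels must be present")
  n <- pm$dims[1]
  n1 <- sum(ill); n2 <- n - n1
  rng <- local_rng(seed)
  perm_idx <- replicate(n_perm, sample.int(n, n1))
  rng$restore()
  m <- matrix(0, nrow = n, ncol = n_perm)         # trials x perms indicator
  m[cbind(as.vector(perm_idx), rep(seq_len(n_perm), each = n1))] <- 1
  re_u <- Re(pm$u); im_u <- Im(pm$u)
  s_all_re <- colSums(re_u); s_all_im <- colSums(im_u)
  s1_re <- crossprod(re_u, m)                     # points x perms
  s1_im <- crossprod(im_u, m)
  # ITCs with per-point vectors recycled down the permutation columns
  pos <- sqrt(s1_re^2 + s1_im^2) / n1 +
    sqrt((s_all_re - s1_re)^2 + (s_all_im - s1_im)^2) / n2 -
    2 * sqrt(s_all_re^2 + s_all_im^2) / n
  samples <- freq_average_cols(pos, pm$dims)      # points x draws
  structure(list(level = "subject", samples = samples,
                 map_dim = c(pm$dims[2], pm$dims[4]),
                 n_permutations = n_perm, seed = seed),
            class = "pos_null")
}

#' Group-level POS null distribution
#'
#' Each group draw picks one permutation sample per subject uniformly at
#' random (with replacement across draws) and averages the picked POS maps
#' over subjects.
#'
#' @param subject_nulls list of subject-level `pos_null` objects with
#'   identical map dimensions.
#' @param n_draws number of group draws (study default 10000).
#' @param seed integer seed.
#' @param replace sample subject permutations with replacement (default);
#'   without replacement requires `n_draws <=` each subject's `n_perm`.
#' @return Object of class `pos_null` with `level = "group"`.
#' @export
group_null <- function(subject_nulls, n_draws = 10000L, seed = 1L,
                       replace = TRUE) {
  if (length(subject_nulls) < 1L) stop("need at least one subject null")
  dims <- lapply(subject_nulls, function(s) s$map_dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("subject nulls have mismatching shapes")
  rng <- local_rng(seed)
  nsub <- length(subject_nulls)
  nperm <- vapply(subject_nulls, function(s) ncol(s$samples), 0L)
  if (sum(nperm) * n_draws * 8 < 1e8) {
    # one selection-matrix product (fast for moderate sizes)
    big <- do.call(cbind, lapply(subject_nulls, `[[`, "samples"))
    sel <- matrix(0, sum(nperm), n_draws)
    off <- c(0L, cumsum(nperm))
    for (i in seq_len(nsub)) {
      idx <- sample.int(nperm[i], n_draws, replace = replace)
      sel[cbind(off[i] + idx, seq_len(n_draws))] <- 1
    }
    acc <- big %*% sel
  } else {
    acc <- NULL
    for (s in subject_nulls) {
      idx <- sample.int(ncol(s$samples), n_draws, replace = replace)
      acc <- if (is.null(acc)) s$samples[, idx, drop = FALSE]
      else acc + s$samples[, idx, drop = FALSE]
    }
  }
  rng$restore()
  structure(list(level = "group", samples = acc / length(subject_nulls),
                 map_dim = subject_nulls[[1]]$map_dim,
                 n_permutations = n_draws, seed = seed),
            class = "pos_null")
}

#' @export
print.pos_null <- function(x, ...) {
  cat(sprintf("POS %s-level null: %d draws over %d sensors x %d times\n",
              x$level, x$n_permutations, x$map_dim[1], x$map_dim[2]))
  invisible(x)
}

#' z-score an observed POS map against the group null
#'
#' @param observed POS matrix (sensors x time), e.g. the subject-average of
#'   [pos_observed()] maps.
#' @param null a group-level `pos_null`.
#' @return z-map of the same shape: `(pos - null mean) / null SD` pointwise.
#' @export
zscore_pos <- function(observed, null) {
  stopifnot(inherits(null, "pos_null"))
  if (ncol(null$samples) < 2L) stop("null needs at least 2 samples")
  obs <- as.vector(observed)
  if (length(obs) != nrow(null$samples)) stop("shape mismatch")
  s <- row_sds(null$samples)
  if (any(s == 0)) stop("zero null SD at some points")
  z <- (obs - rowMeans(null$samples)) / s
  if (is.matrix(observed)) matrix(z, nrow = nrow(observed)) else z
}
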