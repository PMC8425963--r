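# Internal helpers shared across modules.

# Seed the RNG locally: saves the caller's RNG state and returns a handle
# whose $restore() puts it back, so seeded package functions do not disturb
# the user's random stream.
local_rng <- function(seed) {
  if (is.null(seed)) return(list(restore = function() invisible(NULL)))
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  })
}

# Deterministic per-stage seed derivation (Lehmer step), kept within 32 bits.
derive_seed <- function(seed, stage) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in seq_len(stage)) s <- (s * 48271) %% 2147483647
  as.integer(s)
}

# Column means/SDs of a draws-by-points matrix without matrixStats.
col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 rows")
  m <- colMeans(x)
  sqrt(pmax(colMeans(x^2) - m^2, 0) * n / (n - 1))
}

# Per-column quantiles (type 7) of a draws-by-points matrix.
col_quantiles <- function(x, probs) {
  n <- nrow(x)
  h <- (n - 1) * probs + 1
  lo <- floor(h); hi <- ceiling(h); w <- h - lo
  xs <- apply(x, 2L, sort, method = "radix")
  out <- xs[lo, , drop = FALSE] * (1 - w) + xs[hi, , drop = FALSE] * w
  rownames(out) <- sprintf("%g%%", 100 * probs)
  out
}

# Per-row quantiles (type 7) of a points-by-draws matrix, via a single
# radix sort keyed on the row index (fast for many points, moderate draws).
row_quantiles <- function(x, probs) {
  p <- nrow(x); d <- ncol(x)
  o <- order(rep(seq_len(p), d), x, method = "radix")
  h <- (d - 1) * probs + 1
  lo <- floor(h); hi <- ceiling(h); w <- h - lo
  base <- (seq_len(p) - 1) * d
  out <- vapply(seq_along(probs), function(k)
    x[o[base + lo[k]]] * (1 - w[k]) + x[o[base + hi[k]]] * w[k],
    numeric(p))
  t(out)
}

# Row means and SDs of a points-by-draws matrix.
row_sds <- function(x) {
  d <- ncol(x)
  if (d < 2L) stop("need at least 2 columns")
  m <- rowMeans(x)
  sqrt(pmax(rowMeans(x^2) - m^2, 0) * d / (d - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stack equally-shaped matrices/arrays into a new leading dimension.
stack_first <- function(lst) {
  d <- dim(lst[[1]])
  flat <- vapply(lst, as.vector, numeric(prod(d)))
  aperm(array(flat, dim = c(d, length(lst))), c(length(d) + 1L, seq_along(d)))
}
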