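#' Configuration of a spatiotemporal cluster permutation test
#'
#' @param forming_alpha two-sided pointwise probability used to form
#'   supra-threshold points.
#' @param min_neighbors minimum number of supra-threshold spatial neighbours
#'   (at the same time point) a point needs to be kept (FieldTrip-style
#'   single-pass filter).
#' @param min_cluster_size minimum number of points per cluster.
#' @param n_permutations permutations (or null draws clustered) for the
#'   max-cluster-statistic correction.
#' @param alpha_level family-wise significance level for clusters.
#' @param cluster_stat `"sum"` (sum of the statistic over the cluster) or
#'   `"max"` (maximum absolute value over the cluster).
#' @return List of class `cluster_config`.
#' @export
cluster_config <- function(forming_alpha = 0.01, min_neighbors = 2L,
                           min_cluster_size = 0L, n_permutations = 4000L,
                           alpha_level = 0.05,
                           cluster_stat = c("sum", "max")) {
  cluster_stat <- match.arg(cluster_stat)
  if (!(forming_alpha > 0 && forming_alpha <= alpha_level &&
        alpha_level <= 1))
    stop("need 0 < forming_alpha <= alpha_level <= 1")
  if (min_neighbors < 0L || min_cluster_size < 0L || n_permutations < 1L)
    stop("counts must be non-negative (permutations >= 1)")
  if (n_permutations < 100L)
    warning("fewer than 100 permutations: p-values will be coarse")
  structure(list(forming_alpha = forming_alpha,
                 min_neighbors = as.integer(min_neighbors),
                 min_cluster_size = as.integer(min_cluster_size),
                 n_permutations = as.integer(n_permutations),
                 alpha_level = alpha_level,
                 cluster_stat = cluster_stat),
            class = "cluster_config")
}

# Connected components of a sensors x time logical mask under spatial
# (layout adjacency) + temporal (consecutive samples) connectivity.
# Returns a list of integer point-index vectors (column-major indices).
connected_components <- function(mask, layout) {
  pts <- which(mask)
  if (length(pts) == 0L) return(list())
  ns <- nrow(mask); ntm <- ncol(mask)
  id <- matrix(0L, ns, ntm)
  id[pts] <- seq_along(pts)
  edges <- NULL
  if (ntm > 1L) {
    both <- mask[, -ntm, drop = FALSE] & mask[, -1L, drop = FALSE]
    if (any(both))
      edges <- cbind(id[, -ntm, drop = FALSE][both],
                     id[, -1L, drop = FALSE][both])
  }
  adj <- layout$adjacency
  if (nrow(adj) > 0L) {
    ia <- id[adj[, 1], , drop = FALSE]
    ib <- id[adj[, 2], , drop = FALSE]
    both <- ia > 0L & ib > 0L
    if (any(both)) edges <- rbind(edges, cbind(ia[both], ib[both]))
  }
  if (is.null(edges)) {
    memb <- seq_along(pts)
  } else {
    g <- igraph::make_graph(edges = as.vector(t(edges)),
                            n = length(pts), directed = FALSE)
    memb <- igraph::components(g)$membership
  }
  split(pts, memb)
}

# Dense symmetric 0/1 adjacency matrix of a layout.
adjacency_matrix <- function(layout) {
  n <- length(layout$sensor_ids)
  a <- matrix(0, n, n)
  if (nrow(layout$adjacency) > 0L) {
    a[layout$adjacency] <- 1
    a[layout$adjacency[, 2:1, drop = FALSE]] <- 1
  }
  a
}

# Single-pass minimum-neighbour filter: a supra-threshold point must have at
# least `min_neighbors` supra-threshold spatial neighbours at the same time.
filter_min_neighbors <- function(mask, layout, min_neighbors,
                                 adj_mat = NULL) {
  if (min_neighbors <= 0L) return(mask)
  if (is.null(adj_mat)) adj_mat <- adjacency_matrix(layout)
  cnt <- adj_mat %*% mask
  mask & (cnt >= min_neighbors)
}

# Clusters of an already-thresholded mask; stat values summed from `stat`.
clusters_from_mask <- function(mask, stat, layout, min_cluster_size, sgn) {
  comps <- connected_components(mask, layout)
  out <- list()
  for (pts in comps) {
    if (length(pts) < min_cluster_size) next
    out[[length(out) + 1L]] <- list(
      points = pts,
      sensors = ((pts - 1L) %% nrow(mask)) + 1L,
      times = ((pts - 1L) %/% nrow(mask)) + 1L,
      size = length(pts),
      sum = sum(stat[pts]),
      max_abs = max(abs(stat[pts])),
      sign = sgn)
  }
  out
}

#' Clusters of supra-threshold points in a sensors-by-time map
#'
#' Thresholds the map two-sidedly (`stat >= upper` for positive points,
#' `stat <= lower` for negative points; thresholds may be scalars or
#' per-point matrices), applies the minimum-neighbour filter, and extracts
#' connected components under spatial adjacency plus temporal adjacency of
#' consecutive samples. Positive and negative clusters are kept separately;
#' components smaller than `min_cluster_size` are dropped.
#'
#' @param stat numeric sensors x time matrix.
#' @param lower,upper thresholds (scalar or matrix of the same shape).
#' @param layout a `sensor_layout` covering all rows of `stat`.
#' @param min_neighbors,min_cluster_size see [cluster_config()].
#' @return List of clusters; each has `points` (column-major indices),
#'   `sensors`, `times` (indices), `size`, `sum` (sum of `stat`), `max_abs`,
#'   `sign`.
#' @export
clusters_from_map <- function(stat, lower, upper, layout,
                              min_neighbors = 0L, min_cluster_size = 0L) {
  if (nrow(stat) != length(layout$sensor_ids))
    stop("layout does not cover all sensors")
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) stat >= upper else stat <= lower
    mask[!is.finite(stat)] <- FALSE
    mask <- filter_min_neighbors(mask, layout, min_neighbors)
    out <- c(out, clusters_from_mask(mask, stat, layout,
                                     min_cluster_size, sgn))
  }
  out
}

cluster_stat_value <- function(cl, what) {
  if (what == "sum") abs(cl$sum) else cl$max_abs
}

max_cluster_stat <- function(clusters, what) {
  if (length(clusters) == 0L) return(0)
  max(vapply(clusters, cluster_stat_value, 0, what = what))
}

perm_p_value <- function(null_max, observed) {
  (sum(null_max >= observed) + 1) / (length(null_max) + 1)
}

new_cluster_test <- function(clusters, null_max, config, map_dim, method) {
  for (i in seq_along(clusters))
    clusters[[i]]$p <- perm_p_value(null_max,
                                    cluster_stat_value(clusters[[i]],
                                                       config$cluster_stat))
  ord <- order(vapply(clusters, `[[`, 0, "p"))
  structure(list(clusters = clusters[ord], null_max_stats = null_max,
                 config = config, map_dim = map_dim, method = method),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("Spatiotemporal cluster test (%s): %d cluster(s), %d perms\n",
              x$method, length(x$clusters), length(x$null_max_stats)))
  for (cl in x$clusters)
    cat(sprintf(
      "  %s cluster: %d points (%d sensors), stat %.3f, p = %.4f%s\n",
      if (cl$sign > 0) "positive" else "negative", cl$size,
      length(unique(cl$sensors)),
      cluster_stat_value(cl, x$config$cluster_stat), cl$p,
      if (cl$p <= x$config$alpha_level) " *" else ""))
  invisible(x)
}

#' Significant clusters of a cluster test
#'
#' @param x a `cluster_test`.
#' @param alpha significance level (default from the test's configuration).
#' @return The clusters with `p <= alpha`.
#' @export
significant_clusters <- function(x, alpha = NULL) {
  alpha <- alpha %||% x$config$alpha_level
  Filter(function(cl) cl$p <= alpha, x$clusters)
}

#' Between-subject Spearman correlation map
#'
#' Correlates, at every sensor and time point, a per-subject brain map (for
#' example the ILL minus no-ILL prestimulus alpha-power difference) with a
#' per-subject behavioural scalar, using Spearman's rank correlation with
#' average ranks for ties, and attaches the t-transform
#' `t = r * sqrt((n-2) / (1-r^2))` used for cluster forming.
#'
#' @param brain numeric array subjects x sensors x time.
#' @param behavior numeric per-subject vector, aligned with the first
#'   dimension of `brain`.
#' @return Object of class `correlation_map`: `r` and `t` matrices
#'   (sensors x time), `n_subjects`, plus the inputs (`brain_ranks`,
#'   `behavior`) needed to recompute the map under subject permutations.
#' @export
spearman_map <- function(brain, behavior) {
  d <- dim(brain)
  if (length(d) != 3L) stop("brain must be subjects x sensors x time")
  n <- d[1]
  if (n < 4L) stop("need at least 4 subjects")
  if (length(behavior) != n) stop("behavior not aligned with subjects")
  if (stats::sd(behavior) == 0) stop("constant behavioural vector")
  bm <- matrix(brain, nrow = n)
  rx <- apply(bm, 2L, rank)
  rb <- rank(behavior)
  r <- suppressWarnings(as.vector(stats::cor(rx, rb)))
  r[!is.finite(r)] <- 0
  structure(list(r = matrix(r, nrow = d[2]),
                 t = matrix(t_from_r(r, n), nrow = d[2]),
                 n_subjects = n,
                 map_dim = d[2:3],
                 brain_ranks = rx,
                 behavior = behavior),
            class = "correlation_map")
}

t_from_r <- function(r, n) {
  r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
}

#' Cluster permutation test of a brain-behaviour correlation map
#'
#' Forms clusters from the t-transformed Spearman map at a two-sided
#' pointwise threshold (`forming_alpha`, each tail at half), sums the t
#' values per cluster, and corrects family-wise against the distribution of
#' the maximum absolute cluster sum obtained by shuffling the subjects'
#' behavioural labels. Positive and negative clusters are pooled into one
#' max-statistic null.
#'
#' @inheritParams spearman_map
#' @param layout a `sensor_layout`.
#' @param config a [cluster_config()]; study defaults: forming threshold
#'   0.01 two-sided, minimum 2 neighbours, 4000 permutations.
#' @param seed integer seed.
#' @return A `cluster_test`; element `map` holds the observed
#'   `correlation_map`.
#' @export
cluster_permutation_correlation <- function(brain, behavior, layout,
                                            config = cluster_config(),
                                            seed = 1L) {
  cm <- spearman_map(brain, behavior)
  n <- cm$n_subjects
  thr <- stats::qt(1 - config$forming_alpha / 2, df = n - 2)
  obs <- clusters_from_map(cm$t, -thr, thr, layout,
                           config$min_neighbors, config$min_cluster_size)
  rng <- local_rng(seed)
  perms <- replicate(config$n_permutations, sample.int(n))
  rng$restore()
  rb <- rank(cm$behavior)
  rb_perm <- matrix(rb[perms], nrow = n)
  r_perm <- suppressWarnings(stats::cor(cm$brain_ranks, rb_perm))
  r_perm[!is.finite(r_perm)] <- 0
  t_perm <- t_from_r(r_perm, n)                 # points x n_perm
  ns <- cm$map_dim[1]; ntm <- cm$map_dim[2]
  supra_p <- t_perm >= thr
  supra_n <- t_perm <= -thr
  if (config$min_neighbors > 0L) {
    am <- adjacency_matrix(layout)
    nb_ok <- function(supra) {
      cnt <- am %*% matrix(supra, nrow = ns)
      supra & matrix(cnt >= config$min_neighbors, nrow = nrow(supra))
    }
    supra_p <- nb_ok(supra_p)
    supra_n <- nb_ok(supra_n)
  }
  null_max <- numeric(config$n_permutations)
  for (k in seq_len(config$n_permutations)) {
    stat <- matrix(t_perm[, k], nrow = ns)
    cls <- c(clusters_from_mask(matrix(supra_p[, k], ns), stat, layout,
                                config$min_cluster_size, 1),
             clusters_from_mask(matrix(supra_n[, k], ns), stat, layout,
                                config$min_cluster_size, -1))
    null_max[k] <- max_cluster_stat(cls, config$cluster_stat)
  }
  res <- new_cluster_test(obs, null_max, config, cm$map_dim, "correlation")
  res$map <- cm
  res
}

#' Cluster permutation test of a group POS map
#'
#' Thresholds the observed group-average POS map pointwise at percentiles of
#' the group-level permutation null (2.5 and 97.5 by default, a two-sided
#' test at the forming level), clusters the supra-threshold points
#' (minimal cluster size 10 by default), sums the POS values per cluster,
#' and corrects family-wise against the maximum cluster statistic obtained
#' by running the identical clustering on the group-null draws themselves.
#'
#' @param observed group-average POS matrix (sensors x time).
#' @param null a group-level `pos_null` from [group_null()].
#' @param layout a `sensor_layout`.
#' @param config a [cluster_config()]; defaults here: forming 0.05
#'   two-sided, no neighbour floor, minimal cluster size 10,
#'   `n_permutations` null draws clustered.
#' @param seed seed used when subsampling null draws for the correction.
#' @return A `cluster_test`.
#' @export
cluster_permutation_pos <- function(observed, null, layout,
                                    config = cluster_config(
                                      forming_alpha = 0.05,
                                      min_neighbors = 0L,
                                      min_cluster_size = 10L,
                                      n_permutations = 1000L),
                                    seed = 1L) {
  stopifnot(inherits(null, "pos_null"))
  if (null$level != "group") stop("null must be group-level")
  nd <- ncol(null$samples)
  ns <- null$map_dim[1]
  pr <- c(config$forming_alpha / 2, 1 - config$forming_alpha / 2)
  if (nd < 1 / min(pr)) stop("too few null draws for requested percentiles")
  q <- row_quantiles(null$samples, pr)
  lower <- matrix(q[1, ], nrow = ns)
  upper <- matrix(q[2, ], nrow = ns)
  if (!identical(dim(observed), dim(lower))) stop("shape mismatch")
  obs <- clusters_from_map(observed, lower, upper, layout,
                           config$min_neighbors, config$min_cluster_size)
  use <- seq_len(nd)
  if (config$n_permutations < nd) {
    rng <- local_rng(seed)
    use <- sample.int(nd, config$n_permutations)
    rng$restore()
  }
  sub <- null$samples[, use, drop = FALSE]
  supra_p <- sub >= as.vector(upper)            # recycles per column
  supra_n <- sub <= as.vector(lower)
  if (config$min_neighbors > 0L) {
    am <- adjacency_matrix(layout)
    nb_ok <- function(supra) {
      cnt <- am %*% matrix(supra, nrow = ns)
      supra & matrix(cnt >= config$min_neighbors, nrow = nrow(supra))
    }
    supra_p <- nb_ok(supra_p)
    supra_n <- nb_ok(supra_n)
  }
  null_max <- numeric(length(use))
  for (k in seq_along(use)) {
    stat <- matrix(sub[, k], nrow = ns)
    cls <- c(clusters_from_mask(matrix(supra_p[, k], ns), stat, layout,
                                config$min_cluster_size, 1),
             clusters_from_mask(matrix(supra_n[, k], ns), stat, layout,
                                config$min_cluster_size, -1))
    null_max[k] <- max_cluster_stat(cls, config$cluster_stat)
  }
  new_cluster_test(obs, null_max, config, null$map_dim, "pos")
}

#' Conjunction of two correlation maps across conditions
#'
#' The conjunction value at each point is the signed minimum absolute
#' correlation across the two maps when both agree in sign, and 0 where they
#' disagree (the sign rule is a package choice; the magnitude rule is the
#' minimum of the absolute coefficients). Pointwise two-sided thresholds are
#' percentiles of a null built by jointly permuting the subjects of both
#' behavioural vectors; the cluster statistic is the maximum absolute
#' conjunction value over the cluster, corrected against the permutation
#' distribution of its maximum.
#'
#' @param map_a,map_b `correlation_map` objects on the same geometry (same
#'   subjects, e.g. the two motion directions).
#' @param layout a `sensor_layout`.
#' @param config a [cluster_config()]; defaults here: forming 0.01,
#'   `cluster_stat = "max"`, 4000 permutations.
#' @param seed integer seed.
#' @return A `cluster_test`; element `conjunction` holds the observed
#'   conjunction map.
#' @export
conjunction_test <- function(map_a, map_b, layout,
                             config = cluster_config(
                               forming_alpha = 0.01, min_neighbors = 0L,
                               n_permutations = 4000L,
                               cluster_stat = "max"),
                             seed = 1L) {
  stopifnot(inherits(map_a, "correlation_map"),
            inherits(map_b, "correlation_map"))
  if (!identical(map_a$map_dim, map_b$map_dim) ||
      map_a$n_subjects != map_b$n_subjects)
    stop("geometry mismatch between the two maps")
  n <- map_a$n_subjects
  conj <- function(ra, rb) {
    agree <- sign(ra) * sign(rb) > 0
    ifelse(agree, sign(ra) * pmin(abs(ra), abs(rb)), 0)
  }
  observed <- conj(map_a$r, map_b$r)
  rng <- local_rng(seed)
  perms <- replicate(config$n_permutations, sample.int(n))
  rng$restore()
  ra_perm <- permuted_r(map_a, perms)
  rb_perm <- permuted_r(map_b, perms)
  conj_perm <- conj(ra_perm, rb_perm)            # points x n_perm
  q <- row_quantiles(conj_perm,
                     c(config$forming_alpha / 2,
                       1 - config$forming_alpha / 2))
  lower <- matrix(q[1, ], nrow = map_a$map_dim[1])
  upper <- matrix(q[2, ], nrow = map_a$map_dim[1])
  obs <- clusters_from_map(observed, lower, upper, layout,
                           config$min_neighbors, config$min_cluster_size)
  null_max <- numeric(config$n_permutations)
  for (k in seq_len(config$n_permutations)) {
    m <- matrix(conj_perm[, k], nrow = map_a$map_dim[1])
    cls <- clusters_from_map(m, lower, upper, layout,
                             config$min_neighbors, config$min_cluster_size)
    null_max[k] <- max_cluster_stat(cls, config$cluster_stat)
  }
  res <- new_cluster_test(obs, null_max, config, map_a$map_dim,
                          "conjunction")
  res$conjunction <- observed
  res
}

permuted_r <- function(map, perms) {
  rb_perm <- matrix(rank(map$behavior)[perms], nrow = map$n_subjects)
  r <- suppressWarnings(stats::cor(map$brain_ranks, rb_perm))
  r[!is.finite(r)] <- 0
  r
}

#' Percentile bootstrap confidence interval for a Spearman correlation
#'
#' Resamples subject pairs with replacement and returns the percentile
#' interval of the Spearman coefficient. Resamples in which either vector is
#' constant are skipped and counted.
#'
#' @param x,y paired per-subject vectors (length >= 4).
#' @param n_boot bootstrap repetitions (study default 2000).
#' @param level confidence level.
#' @param seed integer seed.
#' @return List with `estimate`, `ci` (length 2), `n_boot_used`, `n_skipped`.
#' @export
bootstrap_ci <- function(x, y, n_boot = 2000L, level = 0.95, seed = 1L) {
  n <- length(x)
  if (length(y) != n || n < 4L) stop("need paired vectors of length >= 4")
  est <- stats::cor(x, y, method = "spearman")
  rng <- local_rng(seed)
  draws <- numeric(n_boot)
  used <- 0L
  for (b in seq_len(n_boot)) {
    i <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) next
    used <- used + 1L
    draws[used] <- stats::cor(x[i], y[i], method = "spearman")
  }
  rng$restore()
  if (used == 0L) stop("all bootstrap resamples degenerate")
  a <- (1 - level) / 2
  list(estimate = est,
       ci = unname(stats::quantile(draws[seq_len(used)], c(a, 1 - a))),
       n_boot_used = used, n_skipped = n_boot - used)
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether angles are uniformly distributed on the circle using the
#' resultant length: `Z = n * Rbar^2`, with the standard series
#' approximation for the p-value.
#'
#' @param angles numeric vector of angles (radians), length >= 2.
#' @return Object of class `htest` with statistic `Z`, the mean resultant
#'   length `Rbar`, and the approximate p-value.
#' @export
rayleigh_test <- function(angles) {
  angles <- angles[is.finite(angles)]
  n <- length(angles)
  if (n < 2L) stop("need at least 2 finite angles")
  rbar <- Mod(mean(exp(1i * angles)))
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  structure(list(statistic = c(Z = z),
                 parameter = c(n = n),
                 estimate = c(Rbar = rbar),
                 p.value = p,
                 method = "Rayleigh test of circular uniformity",
                 data.name = deparse(substitute(angles))),
            class = "htest")
}

#' Circular mean of angles
#'
#' Argument of the mean unit phasor, in `(-pi, pi]`.
#'
#' @param angles numeric vector of angles (radians), length >= 1.
#' @return The mean direction (radians). Errors when the resultant is
#'   (numerically) zero, in which case the mean direction is undefined.
#' @export
circular_mean <- function(angles) {
  if (length(angles) < 1L) stop("need at least one angle")
  m <- mean(exp(1i * angles))
  if (Mod(m) < 1e-10) stop("undefined circular mean: zero resultant")
  a <- Arg(m)
  if (a <= -pi) a <- a + 2 * pi
  a
}
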