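line_layout <- function(n) {
  # n sensors in a chain; built from a grid to reuse the constructor
  grid_layout(1, n)
}

test_that("Spearman maps match monotone and brute-force rank oracles", {
  n <- 6L
  brain <- array(0, c(n, 2L, 3L))
  beh <- c(2, 5, 1, 9, 4, 7)
  for (s in 1:2) for (t in 1:3) brain[, s, t] <- rank(beh) * (s + t)
  cm <- spearman_map(brain, beh)
  expect_true(all(abs(cm$r - 1) < 1e-12))
  cm_rev <- spearman_map(brain, -beh)
  expect_true(all(abs(cm_rev$r + 1) < 1e-12))
  # tie handling: average ranks, checked against the explicit formula
  x <- c(1, 2, 2, 3, 5, 4)
  brain2 <- array(rep(x, 6L), c(n, 2L, 3L))
  rx <- rank(x); ry <- rank(beh)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(cm2 <- spearman_map(brain2, beh)$r[1, 1], oracle,
               tolerance = 1e-12)
  expect_equal(spearman_map(brain2, beh)$t[1, 1],
               oracle * sqrt((n - 2) / (1 - oracle^2)), tolerance = 1e-9)
  expect_error(spearman_map(brain, rep(1, n)), "constant")
  expect_error(spearman_map(brain[1:3, , , drop = FALSE], beh[1:3]),
               "4 subjects")
})

test_that("cluster extraction respects adjacency, size and neighbours", {
  lay <- line_layout(4)
  stat <- matrix(0, 4, 20)
  expect_length(clusters_from_map(stat, -3, 3, lay), 0L)
  # one sensor, 12 consecutive supra-threshold samples
  stat[2, 5:16] <- 4
  cl <- clusters_from_map(stat, -3, 3, lay)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$size, 12L)
  expect_equal(cl[[1]]$sum, 48)
  expect_equal(cl[[1]]$sign, 1)
  expect_equal(sort(cl[[1]]$times), 5:16)
  # nine points below a minimum size of ten are dropped
  stat2 <- matrix(0, 4, 20)
  stat2[3, 1:9] <- 4
  expect_length(clusters_from_map(stat2, -3, 3, lay,
                                  min_cluster_size = 10L), 0L)
  expect_length(clusters_from_map(stat2, -3, 3, lay,
                                  min_cluster_size = 9L), 1L)
  # negative clusters are kept separately with their sign
  stat3 <- matrix(0, 4, 20)
  stat3[1, 1:3] <- -5
  stat3[4, 10:12] <- 5
  cl3 <- clusters_from_map(stat3, -3, 3, lay)
  expect_setequal(vapply(cl3, `[[`, 0, "sign"), c(1, -1))
  # spatial adjacency joins neighbouring sensors at one time point
  stat4 <- matrix(0, 4, 20)
  stat4[1:3, 7] <- 4
  cl4 <- clusters_from_map(stat4, -3, 3, lay)
  expect_length(cl4, 1L)
  expect_equal(cl4[[1]]$size, 3L)
  # a lone sensor fails a 1-neighbour requirement
  stat5 <- matrix(0, 4, 20)
  stat5[1, 5] <- 4
  stat5[3:4, 9] <- 4
  cl5 <- clusters_from_map(stat5, -3, 3, lay, min_neighbors = 1L)
  expect_length(cl5, 1L)
  expect_equal(sort(cl5[[1]]$sensors), 3:4)
})

test_that("cluster p-values are invariant under monotone rescaling", {
  set.seed(50)
  lay <- grid_layout(3, 3)
  brain <- array(rnorm(8 * 9 * 12), c(8, 9, 12))
  beh <- rnorm(8)
  cfg <- cluster_config(forming_alpha = 0.05, min_neighbors = 0L,
                        n_permutations = 120L)
  a <- suppressWarnings(
    cluster_permutation_correlation(brain, beh, lay, cfg, seed = 3))
  b <- suppressWarnings(
    cluster_permutation_correlation(brain, 10 + 3 * beh, lay, cfg, seed = 3))
  expect_equal(vapply(a$clusters, `[[`, 0, "p"),
               vapply(b$clusters, `[[`, 0, "p"))
})

test_that("an injected between-subject correlation is detected", {
  set.seed(51)
  lay <- grid_layout(4, 4)
  n <- 13L
  beh <- seq(0.1, 0.9, length.out = n)
  brain <- array(rnorm(n * 16 * 30, sd = 0.5), c(n, 16, 30))
  patch <- c(6, 7, 10, 11)
  for (s in patch) for (t in 10:25)
    brain[, s, t] <- brain[, s, t] + 3 * beh
  res <- cluster_permutation_correlation(
    brain, beh, lay, cluster_config(n_permutations = 300L), seed = 4)
  sig <- significant_clusters(res)
  expect_gt(length(sig), 0L)
  expect_true(any(unlist(lapply(sig, `[[`, "sensors")) %in% patch))
  expect_warning(cluster_permutation_correlation(
    brain, beh, lay, cluster_config(n_permutations = 50L), seed = 4),
    "100 permutations")
})

test_that("conjunction keeps the signed minimum where signs agree", {
  set.seed(52)
  n <- 10L
  brain <- array(rnorm(n * 4 * 6), c(n, 4, 6))
  beh <- rnorm(n)
  m <- spearman_map(brain, beh)
  lay <- grid_layout(2, 2)
  res <- conjunction_test(m, m, lay,
                          cluster_config(forming_alpha = 0.05,
                                         min_neighbors = 0L,
                                         n_permutations = 100L,
                                         cluster_stat = "max"), seed = 5)
  expect_equal(res$conjunction, m$r)
  # a zero map forces the conjunction to zero everywhere
  brain0 <- array(5, c(n, 4, 6))
  m0 <- spearman_map(brain0, beh)
  res0 <- conjunction_test(m, m0, lay,
                           cluster_config(forming_alpha = 0.05,
                                          min_neighbors = 0L,
                                          n_permutations = 100L,
                                          cluster_stat = "max"), seed = 5)
  expect_true(all(res0$conjunction == 0))
  bad <- spearman_map(array(rnorm(n * 8), c(n, 2, 4)), beh)
  expect_error(conjunction_test(m, bad, lay), "geometry")
})

test_that("bootstrap intervals behave on identical and correlated pairs", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  ci <- bootstrap_ci(x, x, n_boot = 100L, seed = 6)
  expect_equal(ci$estimate, 1)
  expect_equal(unname(ci$ci), c(1, 1))
  expect_equal(eval(formals(bootstrap_ci)$n_boot), 2000L)
  expect_equal(eval(formals(bootstrap_ci)$level), 0.95)
  expect_error(bootstrap_ci(x[1:3], x[1:3]), "length >= 4")
  # moderate-coverage check at reduced size
  set.seed(53)
  rho <- 0.5
  hits <- replicate(60, {
    z <- matrix(rnorm(26), ncol = 2) %*% chol(matrix(c(1, rho, rho, 1), 2))
    ci <- bootstrap_ci(z[, 1], z[, 2], n_boot = 300L,
                       seed = sample.int(1e6, 1))
    true_r <- rho   # population Spearman approx 2/pi*asin(rho/... ) ~ 0.48
    ci$ci[1] <= true_r & ci$ci[2] >= true_r
  })
  expect_gt(mean(hits), 0.75)
})

test_that("Rayleigh statistics follow the resultant-length formulas", {
  even <- seq(0, 2 * pi, length.out = 14)[-14]
  r1 <- rayleigh_test(even)
  expect_lt(r1$statistic[["Z"]], 1e-10)
  expect_gt(r1$p.value, 0.99)
  r2 <- rayleigh_test(c(0.3, 0.3 + pi))
  expect_lt(r2$statistic[["Z"]], 1e-20)
  expect_gt(r2$p.value, 0.99)
  r3 <- rayleigh_test(rep(1.1, 13))
  expect_equal(r3$statistic[["Z"]], 13)
  expect_lt(r3$p.value, 1e-4)
  expect_error(rayleigh_test(0.2), "2 finite")
})

test_that("circular means wrap correctly", {
  expect_equal(circular_mean(rep(0.8, 5)), 0.8)
  expect_equal(circular_mean(c(-pi / 4, pi / 4)), 0)
  expect_equal(circular_mean(c(170, -170) * pi / 180), pi)
  expect_error(circular_mean(c(0, pi)), "zero resultant")
})

test_that("permutation engines are seed-reproducible", {
  set.seed(54)
  lay <- grid_layout(3, 3)
  brain <- array(rnorm(8 * 9 * 10), c(8, 9, 10))
  beh <- rnorm(8)
  cfg <- cluster_config(n_permutations = 150L)
  a <- cluster_permutation_correlation(brain, beh, lay, cfg, seed = 11)
  b <- cluster_permutation_correlation(brain, beh, lay, cfg, seed = 11)
  expect_identical(a$null_max_stats, b$null_max_stats)
  ill <- array(rnorm(8 * 9 * 10), c(8, 9, 10))
  nil <- array(rnorm(8 * 9 * 10), c(8, 9, 10))
  p1 <- power_contrast(ill, nil, lay, seed = 12)
  p2 <- power_contrast(ill, nil, lay, seed = 12)
  expect_identical(p1$null_max_stats, p2$null_max_stats)
})
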