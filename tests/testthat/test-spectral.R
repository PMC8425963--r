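noiseless_epochs <- function(n_trials = 2L, amp = 1, freq = 10, phase = 0.7,
                             ref = -0.4, window = c(-0.8, 1.2)) {
  d <- study_design(n_blocks = 1L,
                    test_per_block_per_direction = ceiling(n_trials / 2),
                    control_per_block_per_direction = 1L,
                    epoch_window = window)
  lay <- grid_layout(2, 2)
  tt <- generate_design(d, seed = 1)[seq_len(n_trials), ]
  ep <- simulate_epochs(tt, subject_profile(alpha_amplitude = 0), lay, d,
                        seed = 1, noise_sd = 0, evoked_amp = 0)
  sig <- amp * cos(2 * pi * freq * (ep$times - ref) + phase)
  for (i in seq_len(n_trials)) for (s in 1:4) ep$data[i, s, ] <- sig
  ep
}

test_that("the fixed-bandwidth cycle rule is linear in frequency", {
  expect_equal(round(cycles_for_frequency(5.5), 1), 3.7)
  expect_equal(round(cycles_for_frequency(10), 1), 6.7)
  expect_equal(round(cycles_for_frequency(21.5), 1), 14.3)
  expect_equal(round(cycles_for_frequency(80), 1), 53.3)
  expect_equal(cycles_for_frequency(1.5), 1)
  f <- c(2, 7, 19, 42)
  expect_equal(cycles_for_frequency(2 * f), 2 * cycles_for_frequency(f))
  expect_error(cycles_for_frequency(-1), "positive")
  expect_error(cycles_for_frequency(10, 0), "positive")
})

test_that("wavelet power scales as amplitude squared, phase as instantaneous", {
  ep1 <- noiseless_epochs(amp = 1)
  ep2 <- noiseless_epochs(amp = 2)
  p1 <- mean(band_average(morlet_transform(ep1, 10, window = c(-0.6, -0.2)),
                          "alpha"))
  p2 <- mean(band_average(morlet_transform(ep2, 10, window = c(-0.6, -0.2)),
                          "alpha"))
  expect_equal(p1, 1, tolerance = 0.01)
  expect_equal(p2 / p1, 4, tolerance = 1e-6)

  tf <- morlet_transform(ep1, 10, window = c(-0.45, -0.35))
  hp <- hilbert_phase(ep1$data[1, 1, ])
  for (j in seq_along(tf$times)) {
    i_full <- which.min(abs(ep1$times - tf$times[j]))
    expect_lt(abs(Arg(exp(1i * (Arg(tf$coefficients[1, 1, 1, j]) -
                                  hp[i_full])))), 0.05)
  }
})

test_that("white noise yields comparable power in disjoint bands", {
  d <- study_design(n_blocks = 1L, test_per_block_per_direction = 10L,
                    control_per_block_per_direction = 1L)
  lay <- grid_layout(2, 2)
  tt <- generate_design(d, seed = 2)
  prof <- subject_profile(alpha_amplitude = 0, noise_exponent = 0)
  ep <- simulate_epochs(tt, prof, lay, d, seed = 3, evoked_amp = 0)
  tf <- morlet_transform(ep, c(8:12, 20:24), window = c(-0.6, -0.2))
  pw <- tf_power(tf)
  a <- mean(band_average(pw, c(8, 12), freqs = tf$freqs, dim = 3))
  b <- mean(band_average(pw, c(20, 24), freqs = tf$freqs, dim = 3))
  expect_lt(max(a, b) / min(a, b), 2)
})

test_that("a wavelet longer than the epoch names the frequency", {
  ep <- noiseless_epochs(window = c(-0.3, 0.3))
  expect_error(morlet_transform(ep, c(5, 10)), "5 Hz")
})

test_that("windowed and full transforms agree exactly", {
  d <- tiny_design()
  lay <- grid_layout(2, 2)
  tt <- generate_design(d, seed = 4)
  ep <- simulate_epochs(tt, subject_profile(), lay, d, seed = 5)
  full <- extract_prestim(morlet_transform(ep, c(9, 11)), c(-0.6, -0.2))
  win <- morlet_transform(ep, c(9, 11), window = c(-0.6, -0.2))
  expect_equal(full$coefficients, win$coefficients, tolerance = 1e-12)
  expect_identical(full$times, win$times)
})

test_that("ITC has its closed-form values and brute-force behaviour", {
  expect_equal(compute_itc(rep(1.2, 7)), 1)
  expect_equal(compute_itc(seq(0, 2 * pi, length.out = 9)[-9]), 0,
               tolerance = 1e-12)
  expect_equal(compute_itc(c(0, pi / 2)), sqrt(2) / 2)
  expect_error(compute_itc(0.3), "2 trials")
  set.seed(6)
  for (rep in 1:20) {
    ph <- runif(sample(2:30, 1), -pi, pi)
    oracle <- Mod(mean(complex(modulus = 1, argument = ph)))
    expect_equal(compute_itc(ph), oracle, tolerance = 1e-12)
    expect_gte(compute_itc(ph), 0)
    expect_lte(compute_itc(ph), 1)
  }
  arr <- array(runif(5 * 2 * 3, -pi, pi), c(5, 2, 3))
  itc <- compute_itc(arr)
  expect_equal(dim(itc), c(2L, 3L))
  expect_equal(itc[2, 3], compute_itc(arr[, 2, 3]))
})

test_that("band averaging is the arithmetic mean over in-band frequencies", {
  freqs <- 8:12
  x <- array(rep(1:5, each = 6), c(2, 3, 5))
  expect_equal(band_average(x, c(8, 12), freqs = freqs, dim = 3),
               array(3, c(2, 3)))
  expect_equal(band_average(x, c(10, 10.5), freqs = freqs, dim = 3),
               array(3, c(2, 3)))            # single frequency: identity
  ramp <- band_average(array(rep(c(2, 4, 6, 8, 10), each = 6), c(2, 3, 5)),
                       c(8, 12), freqs = freqs, dim = 3)
  expect_equal(ramp, array(6, c(2, 3)))
  expect_equal(band_average(c(1, 2, 3), c(9, 10), freqs = c(8, 9, 10)), 2.5)
  expect_error(band_average(x, c(40, 45), freqs = freqs, dim = 3),
               "inside band")
})

test_that("planar combination applies the Euclidean norm per site", {
  expect_equal(combine_planar(c(3, 4)), 5)
  expect_equal(combine_planar(c(0, 0)), 0)
  expect_equal(combine_planar(c(7, 0)), 7)
  expect_equal(combine_planar(c(3, 4, 1, 1)), c(5, sqrt(2)))
  x <- array(c(3, 4, 0, 1), c(4, 1, 1))
  out <- combine_planar(x, dim = 1)
  expect_equal(dim(out), c(2L, 1L, 1L))
  expect_equal(as.vector(out), c(5, 1))
  expect_error(combine_planar(c(1, 2, 3)), "unpaired")
})

test_that("prestimulus extraction keeps the inclusive window", {
  ep <- noiseless_epochs()
  pre <- extract_prestim(ep)
  expect_equal(length(pre$times), 133L)  # -0.8..1.2 s sampled at 333 Hz
  expect_true(all(pre$times >= -0.6 - 1e-9 & pre$times <= -0.2 + 1e-9))
  same <- extract_prestim(ep, range(ep$times))
  expect_equal(dim(same$data), dim(ep$data))
  expect_error(extract_prestim(ep, c(0.1, 0.05)), "increasing")
  expect_error(extract_prestim(ep, c(-2, -0.2)), "outside")
})

test_that("epoch rejection drops only supra-threshold epochs", {
  ep <- noiseless_epochs(n_trials = 4L, amp = 1)
  ep$data[2, 1, 10] <- 50
  out <- reject_epochs(ep, 10)
  expect_equal(dim(out$data)[1], 3L)
  expect_equal(attr(out, "n_rejected"), 1L)
  expect_false(ep$trial_ids[2] %in% out$trial_ids)
  expect_identical(reject_epochs(ep, Inf)$trial_ids, ep$trial_ids)
  expect_error(reject_epochs(ep, -1), "positive")
  expect_warning(reject_epochs(ep, 1e-9), "all epochs")
})

test_that("trial equalisation balances report-by-direction cells", {
  tr <- data.frame(
    trial = 1:100,
    label = rep(c("ILL", "no-ILL"), c(40, 60)),
    direction = "inward", stringsAsFactors = FALSE)
  out <- equalize_trials(tr, seed = 3)
  expect_equal(as.integer(table(out$label)), c(40L, 40L))
  expect_identical(equalize_trials(tr, seed = 3), out)
  expect_false(identical(equalize_trials(tr, seed = 4)$trial, out$trial))
  balanced <- tr[c(1:40, 41:80), ]
  expect_equal(sort(equalize_trials(balanced, seed = 1)$trial),
               balanced$trial)
  bad <- tr; bad$direction <- rep(c("inward", "outward"), c(40, 60))
  expect_error(equalize_trials(bad, seed = 1), "empty cell")
})
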