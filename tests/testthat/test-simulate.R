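make_latent <- function(n, phases = runif(n, -pi, pi),
                        power = rep(1, n)) {
  data.frame(trial = seq_len(n), alpha_phase = phases,
             alpha_amp = sqrt(power), alpha_power = power)
}

test_that("with couplings off the illusion rate matches the base rate", {
  d <- study_design(n_blocks = 1L, test_per_block_per_direction = 300L,
                    control_per_block_per_direction = 10L)
  tt <- generate_design(d, seed = 2)
  prof <- subject_profile(base_illusion_rate = 0.5)
  set.seed(10)
  lat <- make_latent(nrow(tt))
  tt <- simulate_responses(tt, prof, lat, seed = 3)
  tt <- classify_trials(tt)
  n_test <- sum(tt$condition == "test")
  rate <- mean(tt$label[tt$condition == "test"] == "ILL")
  # binomial 99% interval around 0.5 at n = 600
  expect_equal(n_test, 600L)
  expect_lt(abs(rate - 0.5), 2.58 * sqrt(0.25 / n_test))
})

test_that("cohort base rates stay within the configured span", {
  cohort <- simulate_cohort(
    13L, tiny_design(), grid_layout(2, 2), seed = 4)
  rates <- vapply(cohort, function(s) s$profile$base_illusion_rate, 0)
  expect_true(all(rates >= 0.12 & rates <= 0.95))
  expect_gt(diff(range(rates)), 0.3)   # spread across subjects
})

test_that("strong phase coupling separates condition phases by about pi", {
  n <- 400L
  d <- study_design(n_blocks = 1L, test_per_block_per_direction = n / 2L,
                    control_per_block_per_direction = 1L)
  tt <- generate_design(d, seed = 5)
  prof <- subject_profile(base_illusion_rate = 0.5, phase_coupling = 4,
                          preferred_phase = 1)
  set.seed(11)
  lat <- make_latent(nrow(tt))
  tt <- classify_trials(simulate_responses(tt, prof, lat, seed = 6))
  ph <- lat$alpha_phase[match(tt$trial, lat$trial)]
  m_ill <- circular_mean(ph[tt$label == "ILL"])
  m_no <- circular_mean(ph[tt$label == "no-ILL"])
  sep <- abs(Arg(exp(1i * (m_ill - m_no))))
  expect_gt(sep, pi - 0.5)             # Monte-Carlo oracle: opposed phases
  # and the illusion mean sits near the preferred phase
  expect_lt(abs(Arg(exp(1i * (m_ill - prof$preferred_phase)))), 0.5)
})

test_that("missing latent values raise an error", {
  tt <- generate_design(tiny_design(), seed = 1)
  prof <- subject_profile()
  expect_error(simulate_responses(tt, prof, NULL), "latent")
  bad <- make_latent(3)                 # fewer rows than trials
  expect_error(simulate_responses(tt, prof, bad), "latent")
})

test_that("a noiseless epoch concentrates power in the alpha band", {
  d <- study_design(n_blocks = 1L, test_per_block_per_direction = 2L,
                    control_per_block_per_direction = 1L)
  lay <- grid_layout(2, 2)
  tt <- generate_design(d, seed = 1)
  ep <- simulate_epochs(tt, subject_profile(alpha_amplitude = 1),
                        lay, d, seed = 2, noise_sd = 0, evoked_amp = 0,
                        amp_sdlog = 0)
  tf <- morlet_transform(ep, 4:30, window = c(-0.6, -0.2))
  pw <- tf_power(tf)
  alpha <- mean(band_average(pw, "alpha", freqs = tf$freqs, dim = 3))
  beta <- mean(band_average(pw, "beta", freqs = tf$freqs, dim = 3))
  theta <- mean(band_average(pw, "theta", freqs = tf$freqs, dim = 3))
  expect_gt(alpha, 10 * beta)
  expect_gt(alpha, 10 * theta)
})

test_that("doubling the alpha amplitude quadruples prestimulus power", {
  d <- study_design(n_blocks = 1L, test_per_block_per_direction = 2L,
                    control_per_block_per_direction = 1L)
  lay <- grid_layout(2, 2)
  tt <- generate_design(d, seed = 1)
  pw_of <- function(a) {
    ep <- simulate_epochs(tt, subject_profile(alpha_amplitude = a), lay, d,
                          seed = 2, noise_sd = 0, evoked_amp = 0,
                          amp_sdlog = 0)
    mean(band_average(morlet_transform(ep, 10, window = c(-0.6, -0.2)),
                      "alpha"))
  }
  expect_equal(pw_of(2) / pw_of(1), 4, tolerance = 1e-6)
})

test_that("the injected phase is recoverable from the wavelet transform", {
  d <- study_design(n_blocks = 1L, test_per_block_per_direction = 10L,
                    control_per_block_per_direction = 1L)
  lay <- grid_layout(2, 2)
  tt <- generate_design(d, seed = 3)
  ep <- simulate_epochs(tt, subject_profile(), lay, d, seed = 4,
                        noise_sd = 0, evoked_amp = 0)
  tf <- morlet_transform(ep, 10, window = c(-0.45, -0.35))
  i400 <- which.min(abs(tf$times + 0.4))
  es <- ep$effect_sensors[1]
  for (i in seq_len(nrow(tt))) {
    wav <- Arg(tf$coefficients[i, es, 1, i400])
    injected <- ep$latent$alpha_phase[i] +
      2 * pi * 10 * (tf$times[i400] + 0.4)   # latent referenced to -0.4 s
    expect_lt(abs(Arg(exp(1i * (wav - injected)))), 0.2)
    # analytic-signal oracle on the raw noiseless trace
    hp <- hilbert_phase(ep$data[i, es, ])
    i400_full <- which.min(abs(ep$times + 0.4))
    expect_lt(abs(Arg(exp(1i * (wav - hp[i400_full])))), 0.2)
  }
})

test_that("epoch simulation is bit-reproducible and validates its window", {
  d <- tiny_design()
  lay <- grid_layout(2, 2)
  tt <- generate_design(d, seed = 1)
  a <- simulate_epochs(tt, subject_profile(), lay, d, seed = 9)
  b <- simulate_epochs(tt, subject_profile(), lay, d, seed = 9)
  expect_identical(a$data, b$data)
  expect_identical(a$latent, b$latent)
  short <- study_design(n_blocks = 1L, test_per_block_per_direction = 1L,
                        control_per_block_per_direction = 1L,
                        epoch_window = c(-0.04, 0.04))
  expect_error(simulate_epochs(generate_design(short, 1), subject_profile(),
                               lay, short, seed = 1),
               "shorter than one alpha cycle")
})
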