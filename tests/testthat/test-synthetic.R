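test_that("the generator is deterministic and honors its config", {
  cfg <- generator_config(n_channels = 4, n_epochs = 2, epoch_s = 1, seed = 5)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$recording$samples, s2$recording$samples)
  expect_equal(dim(s1$recording$samples), c(2000L, 4L))
  expect_equal(s1$recording$positions, c(0, 25, 50, 75))
  s3 <- generate_session(generator_config(n_channels = 4, n_epochs = 2,
                                          epoch_s = 1, seed = 6))
  expect_false(identical(s1$recording$samples, s3$recording$samples))
  expect_error(generator_config(reference_power = -1), "nonnegative")
  expect_error(generator_config(vc_lambda_um = 0), "positive")
  expect_error(generator_config(local_ar = 1.2), "unit circle")
})

test_that("ground truth is analytic and consistent with the config", {
  cfg <- generator_config(n_channels = 5, reference_power = 2, vc_power = 0,
                          seed = 1)
  gt <- generate_session(cfg)$ground_truth
  # reference-only common signal: flat, equal across channels
  expect_true(all(gt$common_psd == 2))
  w <- 2 * pi * gt$freq_hz / cfg$fs_hz
  expect_equal(gt$neural_psd,
               cfg$local_sd^2 / (1 + cfg$local_ar^2 - 2 * cfg$local_ar * cos(w)) +
                 cfg$slow_sd^2 / (1 + cfg$slow_ar^2 - 2 * cfg$slow_ar * cos(w)))
  expect_equal(gt$ncr[3, ], gt$neural_psd / 2, ignore_attr = TRUE)
})

test_that("no common signal implies near-zero high-frequency coherence", {
  cfg <- generator_config(n_channels = 4, reference_power = 0, vc_power = 0,
                          slow_sd = 0, seed = 9)
  rec <- generate_session(cfg)$recording
  rep <- analyze_session(rec, include_gc = FALSE,
                         bins = list("25" = c(25, 25), "50" = c(50, 50),
                                     "75-150" = c(75, 150)),
                         ncr_band = c(200, 450))
  ps <- rep$pair_spectra
  hi <- ps[ps$signal_type == "unipolar" & ps$frequency > 100, ]
  # multitaper bias floor is ~1/72; stay within a small multiple of it
  expect_lt(mean(hi$coherence), 0.05)
})

test_that("a reference signal reproduces the closed-form coherence level", {
  cfg <- generator_config(reference_power = 0.25, vc_power = 0, seed = 17)
  sess <- generate_session(cfg)
  rep <- analyze_session(sess$recording, include_gc = FALSE)
  truth_c <- as.numeric(coherence_from_ncr(ground_truth_ncr(sess$ground_truth)))
  est_c <- mean(rep$ncr$coherence_band)
  expect_lt(abs(est_c - truth_c), 0.05)
})

test_that("scenario recordings reproduce the analytic spectra", {
  # scenario 2: independent channels with the connected system's spectra
  rec2 <- scenario_recording(2, n_samples = 1e5, seed = 23)
  emp2 <- empirical_coherence(rec2)
  expect_lt(mean(emp2$coherence), 0.03)
  # marginal spectra match the connected system (relative, band-averaged)
  q <- average_epochs(lapply(seq_len(nrow(rec2$samples) %/% 1000),
    function(e) multitaper_csd(rec2$samples[((e - 1) * 1000 + 1):(e * 1000), ],
                               fs = 2 * pi, pad = 1)))
  Qa <- ar_spectral_matrix(scenario_model("connected"), q$freq)
  for (ch in 1:2) {
    ratio <- Re(q$Q[, ch, ch]) * 2 * pi / Re(Qa$Q[, ch, ch])
    expect_equal(median(ratio), 1, tolerance = 0.05)
  }
  # scenario 1: empirical coherence tracks the analytic curve pointwise
  rec1 <- scenario_recording(1, n_samples = 2e5, seed = 31)
  emp1 <- empirical_coherence(rec1)
  Q1 <- ar_spectral_matrix(scenario_model("connected"), emp1$freq)
  expect_lt(max(abs(emp1$coherence - coherence_spectrum(Q1))), 0.05)
  # scenario 4: coherence increases with frequency (band means)
  rec4 <- scenario_recording(4, n_samples = 1e5, seed = 37)
  emp4 <- empirical_coherence(rec4)
  lo <- mean(emp4$coherence[emp4$freq < 0.5])
  hi <- mean(emp4$coherence[emp4$freq > 2.5])
  expect_gt(hi, lo + 0.1)
  # scenario 3 vs 1: power elevated by a roughly flat amount ~ UU*
  uu <- mean_neural_power(ar_spectral_matrix(scenario_model("connected")))
  rec3 <- scenario_recording(3, n_samples = 1e5, seed = 31)
  expect_equal(var(rec3$samples[, 1]) - var(rec1$samples[1:1e5, 1]), uu,
               tolerance = 0.05)
  # determinism
  expect_identical(scenario_recording(4, 5000, seed = 2)$samples,
                   scenario_recording(4, 5000, seed = 2)$samples)
})
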