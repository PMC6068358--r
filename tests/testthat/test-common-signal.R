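test_that("NCR/coherence closed forms invert each other", {
  expect_equal(ncr_from_coherence(0.5), sqrt(2) - 1, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(round(as.numeric(ncr_from_coherence(0.5)), 2), 0.41)
  expect_equal(as.numeric(coherence_from_ncr(1)), 0.25)
  expect_equal(as.numeric(coherence_from_ncr(0)), 1)
  expect_equal(as.numeric(ncr_from_coherence(1)), 0)
  expect_equal(as.numeric(ncr_from_coherence(0.25)), 1)
  for (x in c(0.1, 0.41, 2)) {
    expect_equal(as.numeric(ncr_from_coherence(coherence_from_ncr(x))), x,
                 tolerance = 1e-12)
  }
  expect_error(ncr_from_coherence(0), "unbounded")
  expect_error(ncr_from_coherence(1.2), "exceed")
  expect_error(coherence_from_ncr(-0.1), "nonnegative")
})

test_that("NCR/coherence maps are strictly monotone", {
  ncr <- seq(0, 6, by = 0.05)
  expect_true(all(diff(as.numeric(coherence_from_ncr(ncr))) < 0))
  C <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(as.numeric(ncr_from_coherence(C))) < 0))
})

test_that("injecting a flat common signal adds its power to every entry", {
  freq <- frequency_grid(8)
  Q <- spectral_matrix(freq, array(rep(c(1, 0, 0, 1), each = 8), c(8, 2, 2)))
  Qc <- inject_common(Q, common_signal_spec("flat", level = 1))
  expect_equal(Re(Qc$Q[3, , ]), matrix(c(2, 1, 1, 2), 2, 2))
  expect_equal(coherence_spectrum(Qc), rep(0.25, 8))
  # zero power leaves Q unchanged
  expect_equal(inject_common(Q, 0)$Q, Q$Q)
  # diagonal increment equals the injected power at every frequency
  u <- common_signal_spec("one_over_f", k = 2, omega0 = 0.1)
  Qf <- inject_common(Q, u)
  expect_equal(Re(Qf$Q[, 1, 1] - Q$Q[, 1, 1]), common_signal_power(u, freq))
  expect_silent(validate_spectral_matrix(Qf))
  expect_error(inject_common(Q, rep(1, 5)), "match")
})

test_that("injected-coherence algebra matches the general common-signal form", {
  # disconnected spectrum + flat common signal: coherence must equal
  # UU*^2 / ((S11+UU*)(S22+UU*)) exactly
  Qd <- scenario_model("disconnected")
  uu <- 0.7
  Qc <- inject_common(Qd, uu)
  s11 <- Re(Qd$Q[, 1, 1]); s22 <- Re(Qd$Q[, 2, 2])
  expect_equal(coherence_spectrum(Qc),
               uu^2 / ((s11 + uu) * (s22 + uu)), tolerance = 1e-12)
})

test_that("mean_neural_power averages the two auto-spectra", {
  freq <- frequency_grid(10)
  Q1 <- spectral_matrix(freq, array(rep(c(1, 0, 0, 1), each = 10), c(10, 2, 2)))
  expect_equal(mean_neural_power(Q1), 1)
  Q2 <- spectral_matrix(freq, array(rep(c(2, 0, 0, 4), each = 10), c(10, 2, 2)))
  expect_equal(mean_neural_power(Q2), 3)
  # scenario value agrees with the time-domain variances
  m <- scenario_model("connected")
  Q <- ar_spectral_matrix(m, frequency_grid(1024))
  y <- simulate_ar(m, 2e5, seed = 3)
  expect_equal(mean_neural_power(Q), mean(apply(y, 2, var)), tolerance = 0.02)
})

test_that("bipolar derivation cancels identical common signals exactly", {
  set.seed(1)
  x <- matrix(rnorm(300 * 3), 300, 3)
  u <- rnorm(300)
  clean <- recording(x, fs = 100, positions = c(0, 25, 50))
  dirty <- recording(x - u, fs = 100, positions = c(0, 25, 50))
  expect_equal(bipolar_derive(clean)$samples, bipolar_derive(dirty)$samples,
               tolerance = 1e-12)
  b <- bipolar_derive(clean)
  expect_equal(b$samples[, 1], x[, 1] - x[, 2])
  expect_equal(b$positions, c(12.5, 37.5))
  expect_identical(b$label, "bipolar")
  # identical channels cancel to zero
  same <- recording(cbind(x[, 1], x[, 1]), fs = 100, positions = c(0, 25))
  expect_true(all(bipolar_derive(same)$samples == 0))
  one <- recording(x[, 1, drop = FALSE], fs = 100, positions = 0)
  expect_error(bipolar_derive(one), "two channels")
})

test_that("shared-channel bipolar coherence follows its closed form", {
  expect_equal(shared_bipolar_coherence(1, 1, 1), 0.25)
  expect_equal(shared_bipolar_coherence(2, 0, 3), 0)
  expect_equal(shared_bipolar_coherence(0, 5, 0), 1)
  expect_error(shared_bipolar_coherence(0, 0, 1), "zero power")
  expect_error(shared_bipolar_coherence(-1, 1, 1), "nonnegative")
  # never exceeds the equal-NCR bound of 0.25... unless the shared channel
  # dominates; with outer powers >= shared power it stays below 0.25
  set.seed(42)
  for (rep in 1:200) {
    p <- stats::runif(3, 0.1, 10)
    ps <- min(p)
    expect_lte(shared_bipolar_coherence(p[1], ps, p[3]), 0.25)
  }
})

test_that("common-signal specs round-trip through JSON", {
  u <- common_signal_spec("one_over_f", k = 3, omega0 = 0.02)
  path <- withr::local_tempfile(fileext = ".json")
  common_signal_to_json(u, path)
  u2 <- common_signal_from_json(path)
  expect_equal(common_signal_power(u2, frequency_grid(16)),
               common_signal_power(u, frequency_grid(16)))
})
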