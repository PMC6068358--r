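test_that("transfer function of a lag-free model is the identity", {
  m <- ar_model(matrix(0, 2, 2), diag(2))
  td <- ar_transfer_function(m, frequency_grid(32))
  for (k in c(1, 16, 32)) {
    expect_equal(td$H[k, , ], diag(2) + 0i, tolerance = 1e-12)
  }
  expect_identical(td$noise_cov, diag(2))
})

test_that("connected scenario matches the closed-form transfer function", {
  td <- ar_transfer_function(scenario_model("connected"))
  w <- td$freq
  # channel 1 is a scalar AR(1): H11 = 1 / (1 - 0.1 e^{-iw})
  expect_equal(td$H[, 1, 1], 1 / (1 - 0.1 * exp(-1i * w)), tolerance = 1e-12)
  expect_equal(Re(td$H[1, 1, 1]), 1 / 0.9, tolerance = 1e-12)
  # no 2 -> 1 coupling
  expect_true(all(Mod(td$H[, 1, 2]) == 0))
})

test_that("unstable models are rejected with an informative error", {
  expect_error(ar_transfer_function(ar_model(matrix(1.01))), "not stable")
  expect_error(simulate_ar(ar_model(matrix(c(0.9, 0.5, 0.5, 0.9), 2, 2)),
                           1000), "not stable")
})

test_that("analytic spectra match closed forms", {
  # white bivariate noise: Q = identity everywhere
  Qw <- ar_spectral_matrix(ar_model(matrix(0, 2, 2)), frequency_grid(16))
  I2 <- array(rep(c(1, 0, 0, 1), each = 16), c(16, 2, 2))
  expect_lt(max(Mod(Qw$Q - I2)), 1e-12)
  # scalar AR(1): S(w) = 1 / |1 - 0.1 e^{-iw}|^2
  Q1 <- ar_spectral_matrix(ar_model(matrix(0.1)))
  expect_equal(Re(Q1$Q[1, 1, 1]), 1 / 0.9^2, tolerance = 1e-12)
  expect_equal(Re(Q1$Q[, 1, 1]),
               1 / Mod(1 - 0.1 * exp(-1i * Q1$freq))^2, tolerance = 1e-12)
})

test_that("scenario coherence at zero frequency matches the closed form", {
  Q <- ar_spectral_matrix(scenario_model("connected"))
  # closed form from the triangular transfer function at w = 0
  H11 <- 1 / 0.9; H21 <- 0.1 / (0.9 * 0.6); H22 <- 1 / 0.6
  C0 <- (H11 * H21)^2 / ((H11^2) * (H21^2 + H22^2))
  expect_equal(coherence_spectrum(Q)[1], C0, tolerance = 1e-12)
  expect_equal(C0, 0.0122, tolerance = 1e-2)
})

test_that("disconnected scenario keeps the auto-spectra, zeroes the rest", {
  Qc <- ar_spectral_matrix(scenario_model("connected"))
  Qd <- scenario_model("disconnected")
  expect_equal(Re(Qd$Q[, 1, 1]), Re(Qc$Q[, 1, 1]))
  expect_equal(Re(Qd$Q[, 2, 2]), Re(Qc$Q[, 2, 2]))
  expect_true(all(Mod(Qd$Q[, 1, 2]) == 0))
  expect_true(all(coherence_spectrum(Qd) == 0))
})

test_that("Q is Hermitian PSD at every grid point across the battery", {
  for (m in ar_battery()) {
    Q <- ar_spectral_matrix(m, frequency_grid(128))
    expect_silent(validate_spectral_matrix(Q))
    dets <- Re(Q$Q[, 1, 1] * Q$Q[, 2, 2]) - Mod(Q$Q[, 1, 2])^2
    tr <- Re(Q$Q[, 1, 1] + Q$Q[, 2, 2])
    expect_true(all(dets > -1e-10 * tr^2))
  }
})

test_that("mean auto-spectrum over the circle equals the process variance", {
  # oracle: long time-domain simulation
  for (nm in c("connected", "strong_feedback")) {
    m <- ar_battery()[[nm]]
    Q <- ar_spectral_matrix(m, frequency_grid(1024))
    y <- simulate_ar(m, 2e5, seed = 42)
    for (ch in 1:2) {
      # grid mirrored to [0, 2pi): endpoints weighted once, interior twice
      s <- Re(Q$Q[, ch, ch])
      circ_mean <- (sum(s) + sum(s[-c(1, length(s))])) / (2 * (length(s) - 1))
      expect_equal(circ_mean, var(y[, ch]), tolerance = 0.01)
    }
  }
})

test_that("simulation is deterministic and has the right second moments", {
  m <- ar_model(matrix(0.1))
  y1 <- simulate_ar(m, 5e4, seed = 7)
  y2 <- simulate_ar(m, 5e4, seed = 7)
  expect_identical(y1, y2)
  expect_equal(var(y1[, 1]), 1 / (1 - 0.01), tolerance = 0.03)
  yw <- simulate_ar(ar_model(matrix(0, 2, 2)), 5e4, seed = 8)
  expect_equal(cov(yw), diag(2), tolerance = 0.03)
})

test_that("analytic coherence agrees with multitaper coherence of a long run", {
  m <- scenario_model("connected")
  emp <- empirical_coherence(m, n = 2e5, seed = 99)
  Qa <- ar_spectral_matrix(m, emp$freq)
  expect_lt(max(abs(coherence_spectrum(Qa) - emp$coherence)), 0.02)
})

test_that("AR models round-trip through JSON", {
  m <- ar_battery()$bidirectional_ar2
  path <- withr::local_tempfile(fileext = ".json")
  ar_model_to_json(m, path)
  m2 <- ar_model_from_json(path)
  expect_equal(m2$coeffs, m$coeffs)
  expect_equal(m2$noise_cov, m$noise_cov)
})

test_that("tidy and glance summarize AR models", {
  m <- scenario_model("connected")
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$estimate[td$row == 2 & td$col == 2], 0.4)
  g <- glance(m)
  expect_true(g$stable)
  expect_equal(g$order, 1L)
})
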