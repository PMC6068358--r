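test_that("coherence closed forms", {
  freq <- frequency_grid(8)
  Qd <- spectral_matrix(freq, array(rep(c(1, 0, 0, 2), each = 8), c(8, 2, 2)))
  expect_equal(coherence_spectrum(Qd), rep(0, 8))
  Qc <- spectral_matrix(freq, array(rep(c(2, 1, 1, 2), each = 8), c(8, 2, 2)))
  expect_equal(coherence_spectrum(Qc), rep(0.25, 8))
  # rank-1: perfectly dependent
  Qr <- spectral_matrix(freq, array(rep(c(4, 2, 2, 1), each = 8), c(8, 2, 2)))
  expect_equal(coherence_spectrum(Qr), rep(1, 8))
  Qz <- spectral_matrix(freq, array(rep(c(0, 0, 0, 1), each = 8), c(8, 2, 2)))
  expect_error(coherence_spectrum(Qz), "zero")
})

test_that("transformed coherence stretches as documented", {
  expect_equal(round(transform_coherence(0.01), 4), 0.0101)
  expect_equal(round(transform_coherence(0.99), 4), 4.6052)
  expect_equal(transform_coherence(0), 0)
  expect_true(all(diff(transform_coherence(seq(0, 0.99, 0.01))) > 0))
  expect_error(transform_coherence(1), "unbounded")
  expect_equal(transform_coherence(1, cap = 30), 30)
  expect_error(transform_coherence(1.3), "lie in")
})

test_that("scenario 1 decomposition: no backward GC, no instantaneous term", {
  Q <- scenario_spectrum(1)
  gd <- granger_decompose(Q)
  expect_lt(max(abs(gd$gc_backward)), 1e-8)
  expect_lt(max(abs(gd$instantaneous)), 1e-8)
  # forward GC at w=0 equals the closed form ln(1 + d^2 / |1-a|^2)
  expect_equal(gd$gc_forward[1], log(1 + 0.01 / 0.81), tolerance = 1e-6)
  # and equals the transformed coherence since the other terms vanish
  expect_equal(gd$gc_forward, gd$transformed_coherence, tolerance = 1e-7)
  expect_equal(pct_instantaneous(gd), rep(0, nrow(gd)), tolerance = 1e-5)
})

test_that("disconnected system: everything is zero, percentage undefined", {
  gd <- granger_decompose(scenario_spectrum(2))
  expect_equal(gd$coherence, rep(0, nrow(gd)))
  expect_lt(max(abs(gd$total_gc)), 1e-8)
  expect_lt(max(abs(gd$instantaneous)), 1e-8)
  expect_true(all(is.na(gd$pct_instantaneous)))
})

test_that("decomposition identity holds across the battery", {
  for (m in ar_battery()) {
    Q <- ar_spectral_matrix(m, frequency_grid(256))
    gd <- granger_decompose(Q)
    resid <- max(abs(gd$transformed_coherence -
                       (gd$gc_forward + gd$gc_backward + gd$instantaneous)))
    expect_lt(resid, 1e-6)
    expect_lt(attr(gd, "decomposition_residual"), 1e-6)
    # directional GC nonnegative on PSD inputs
    expect_gt(min(gd$gc_forward), -1e-8)
    expect_gt(min(gd$gc_backward), -1e-8)
  }
})

test_that("coherence and GC are invariant under scalar channel rescaling", {
  m <- ar_battery()$correlated_noise
  Q <- ar_spectral_matrix(m, frequency_grid(128))
  k <- 3.7
  Qs <- Q
  Qs$Q[, 1, 1] <- Qs$Q[, 1, 1] * k^2
  Qs$Q[, 1, 2] <- Qs$Q[, 1, 2] * k
  Qs$Q[, 2, 1] <- Qs$Q[, 2, 1] * k
  g1 <- granger_decompose(Q)
  g2 <- granger_decompose(Qs)
  expect_lt(max(abs(g2$coherence - g1$coherence)), 1e-8)
  expect_lt(max(abs(g2$gc_forward - g1$gc_forward)), 1e-8)
  expect_lt(max(abs(g2$gc_backward - g1$gc_backward)), 1e-8)
  expect_lt(max(abs(g2$instantaneous - g1$instantaneous)), 1e-8)
})

test_that("a common signal raises instantaneous interaction and lowers GC", {
  g1 <- granger_decompose(scenario_spectrum(1))
  g3 <- granger_decompose(scenario_spectrum(3))
  g4 <- granger_decompose(scenario_spectrum(4))
  # scenario 3 vs 1: total GC strictly decreases at every frequency
  expect_true(all(g3$total_gc < g1$total_gc))
  expect_true(all(g3$instantaneous > 0))
  # scenario 4: transformed coherence dominated by instantaneous interaction
  expect_true(all(g4$pct_instantaneous > 80))
  expect_true(all(g4$coherence > 0))
  expect_true(all(diff(g4$coherence) > -1e-9))
})

test_that("instantaneous interaction may be negative and is flagged, not clipped", {
  # correlated noise with opposing lagged coupling can drive f_{1.2} < 0
  found <- FALSE
  for (g in c(-0.6, -0.4, 0.6)) {
    m <- ar_model(matrix(c(0.5, 0.4, -0.4, 0.5), 2, 2),
                  matrix(c(1, g, g, 1), 2, 2))
    gd <- granger_decompose(ar_spectral_matrix(m, frequency_grid(128)))
    if (any(gd$instantaneous < -1e-6)) {
      found <- TRUE
      expect_true(attr(gd, "negative_instantaneous"))
    }
  }
  expect_true(found)
})

test_that("a mismatched factorization is refused", {
  Q <- scenario_spectrum(1)
  td <- ar_transfer_function(scenario_model("connected"), Q$freq)
  td$noise_cov <- td$noise_cov * 2
  expect_error(granger_decompose(Q, td), "does not factorize")
})
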