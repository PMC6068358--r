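# Battery of stable bivariate AR models exercised by the factorization and
# connectivity tests. Poles kept moderate so lag-truncated factorizations
# converge tightly.
ar_battery <- function() {
  list(
    connected = scenario_model("connected"),
    correlated_noise = ar_model(matrix(c(0.3, 0.2, 0, 0.5), 2, 2),
                                matrix(c(1, 0.4, 0.4, 2), 2, 2)),
    bidirectional_ar2 = ar_model(
      list(matrix(c(0.4, 0.2, -0.1, 0.3), 2, 2),
           matrix(c(-0.2, 0.05, 0.1, -0.15), 2, 2)),
      matrix(c(1.5, -0.2, -0.2, 0.8), 2, 2)),
    near_white = ar_model(matrix(c(0.05, 0.02, 0.01, 0.08), 2, 2), diag(2)),
    strong_feedback = ar_model(matrix(c(0.7, 0.25, 0, 0.6), 2, 2),
                               diag(c(1, 0.5)))
  )
}

# coherence of a long realization, multitaper over non-overlapping epochs;
# independent oracle for the analytic spectra
empirical_coherence <- function(model_or_rec, n = 2e5, seed = 99,
                                epoch_len = 1000, n_tapers = 9) {
  if (inherits(model_or_rec, "ar_model")) {
    y <- simulate_ar(model_or_rec, n, seed = seed)
  } else {
    y <- model_or_rec$samples
  }
  n_ep <- nrow(y) %/% epoch_len
  qs <- lapply(seq_len(n_ep), function(e) {
    multitaper_csd(y[((e - 1) * epoch_len + 1):(e * epoch_len), ],
                   fs = 2 * pi, n_tapers = n_tapers, pad = 1)
  })
  q <- average_epochs(qs)
  list(freq = q$freq, coherence = coherence_spectrum(q))
}
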