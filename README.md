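# commonsig

Common signals — electrical activity at a non-silent reference electrode,
or volume conduction from a nearby source — contaminate every channel of a
multichannel electrophysiology recording at once. They inflate power,
create coherence between neurally independent sites, and distort spectral
Granger causality. `commonsig` is an R toolbox for *diagnosing* these
artifacts: it implements the joint analysis of power, coherence, and the
Granger decomposition that reveals common signals, together with bipolar
re-referencing and a synthetic linear-array LFP generator with analytic
ground truth, so every stage of the pipeline can be exercised without
external data.

## The quantities at its core

For a unipolar channel `y_i(t) = x_i(t) - u(t)` (neural signal minus a
common signal), with everything expressed through the cross-spectral
density matrix `Q(ω)`:

- **Coherence** `C_ij(ω) = |S_ij|² / (S_ii S_jj)`. If the neural signals
  are independent at a frequency and share only the common signal, the
  coherence is pinned by the **neural-to-common-signal ratio**:
  `C = 1 / (NCR + 1)²`, hence `NCR = 1/√C − 1`. High coherence at
  frequencies with no plausible neural coupling is the fingerprint of a
  common signal, and its level measures the contamination.
- **Spectral Granger causality** via the factorization
  `Q(ω) = H(ω) Σ H*(ω)` (Wilson's algorithm; no AR model fit needed). The
  transformed coherence decomposes exactly as
  `−ln(1 − C_ij) = f_{i→j} + f_{i←j} + f_{i·j}`,
  splitting lagged directional influence from the **instantaneous
  interaction** `f_{i·j}`, which is what a common signal inflates.
- **Bipolar derivations** `by_i = y_i − y_{i+1}` cancel a shared common
  signal exactly — except that two derivations built from a shared channel
  inherit *it* as a new common signal, bounding their coherence by 0.25
  when powers are equal.

## Worked example

```r
library(commonsig)

# analytic route: the canonical two-node simulation scenarios
Q1 <- scenario_spectrum(1)            # unidirectionally connected
gd <- granger_decompose(Q1)           # Wilson factorization inside
gd[1, c("coherence", "gc_forward", "gc_backward", "instantaneous")]
#> coherence = 0.0122, gc_forward = 0.0123, gc_backward = 0, instantaneous = 0

ncr_from_coherence(0.5)               # 0.414: neural power < half the common power
coherence_from_ncr(1)                 # 0.25: the equal-power ceiling

# empirical route: a synthetic 15-channel, 8 x 2.25 s session
sess <- generate_session(generator_config(seed = 7))
rep  <- analyze_session(sess$recording)
glance(rep)
#> n_pairs = 195, n_freq = 2251, ncr_median = 0.0969, fs = 1000, n_epochs = 8
attr(rep$ncr, "ncr_median")           # 0.0969 vs analytic ground truth 0.081
autoplot(rep)                         # bin-averaged spectra, unipolar vs bipolar
```

The numbers mean: in the connected scenario all of the (transformed)
coherence is lagged influence in the 1→2 direction and none is
instantaneous; in the synthetic session the estimated NCR of ~0.1 says the
reference signal carries roughly ten times the neural power in the
200–450 Hz band, which is exactly what the generator injected.

A thin CLI wraps the same functions
(`inst/scripts/commonsig simulate|analyze|synth|ncr`).

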