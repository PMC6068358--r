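---
title: "Dissecting common-signal artifacts with power, coherence and Granger causality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting common-signal artifacts with power, coherence and Granger causality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commonsig)
```

## The problem and the model

A channel recorded against a distant, non-silent reference measures
`y_i(t) = x_i(t) - u(t)`: the neural signal of interest minus a signal
common to every channel. More generally the common contribution decomposes
into a global reference term `r(t)` and a volume-conducted term `vc_i(t)`
whose amplitude decays with distance from its source,
`y_i = x_i + vc_i - r`. If the common signal is independent of the neural
activity (the working assumption throughout this package, enforced by
`inject_common()` and stated on its help page), then:

* **Power** gains an additive term: `S_ii = X_i X_i* + U U*`. Power alone
  cannot reveal connectivity changes, because the gain is the same whether
  or not the channels interact.
* **Coherence** becomes nonzero even between independent neural signals.
  At frequencies `ω_h` high enough that genuine neural coupling is
  implausible, and if the neural-to-common-signal ratio
  `NCR = X X* / U U*` is comparable across channels, coherence collapses
  to a one-parameter family `C = 1/(NCR + 1)²`. Inverting it
  (`ncr_from_coherence()`) turns observed high-frequency coherence into an
  estimate of contamination strength: `C = 0.5` means `NCR ≈ 0.41`, i.e.
  the neural signal is weaker than the common signal.
* **Granger causality** is analyzed through the identity
  `-ln(1 - C_ij) = f_{i→j} + f_{i←j} + f_{i·j}`. The two directional terms
  capture lagged influence; the *instantaneous interaction* `f_{i·j}`
  absorbs zero-lag dependence. A common signal is exogenous and zero-lag,
  so it loads almost entirely on `f_{i·j}` — and, less obviously, it also
  *depresses* the directional terms. The percentage
  `100 f_{i·j} / (-ln(1-C))` is therefore a practical common-signal
  indicator.

The directional terms require the spectral factorization
`Q(ω) = H(ω) Σ H*(ω)`. `granger_decompose()` accepts either the true AR
transfer function (parametric route, `ar_transfer_function()`) or the
non-parametric factorization of `wilson_factorize()`; the test suite
checks that both routes agree to 1e-4 pointwise across an AR model
battery. With correlated innovations (`γ ≠ 0`) the corrected entries
`H̃_22 = H_22 + (γ/Γ) H_21` and `H̃_11 = H_11 + (γ/Σ) H_12` are always
used; we derived these from the noise-decorrelation argument (write
`ε = ε' + (γ/Γ)η` with `ε' ⊥ η`), which is the convention under which a
system with no 2→1 coupling yields `f_{2→1} ≡ 0` for any `γ` — the sanity
property the tests pin down. Instantaneous interaction is computed from
its closed form `ln(H̃_11 Σ H̃_11* · H̃_22 Γ H̃_22* / |Q|)` rather than as
a residual; the residual of the decomposition identity is recorded as a
cross-check on every call. `f_{i·j}` can be legitimately negative; it is
reported unclipped and flagged via the `negative_instantaneous` attribute,
with no stance taken on its interpretation.

## Numerical choices

* **AR sign convention.** Models are entered in the natural form
  `y(t) = Σ Φ(l) y(t-l) + ε`; the lag-operator representation with
  identity at lag 0 is built internally, so the canonical scenario
  coefficients (0.1, 0.4, 0.1) produce spectra that decay with frequency.
* **Frequency grid.** 512 linearly spaced points from 0 to the Nyquist
  frequency inclusive, normalized radians by default, Hz when a sampling
  rate is given. Stability is gated on a companion-matrix spectral radius
  below `1 - 1e-6`; simulations discard a 1000-sample burn-in (2000 in the
  session generator).
* **Wilson factorization.** Initialization is the symmetric PSD square
  root of the frequency-averaged spectrum; the spectrum is mirrored onto a
  `2(n-1)`-point circle; convergence requires the relative change of both
  `Σ` and the factor to drop below 1e-9 (default), with at most 1000
  iterations. Analytic AR spectra converge to ~1e-9 residuals. *Estimated*
  spectra are generally not exactly factorizable with finite lag support,
  so the iteration settles into a tiny limit cycle at its numerical floor;
  the plateau is detected (no 1% improvement over 50 iterations) and
  accepted when the relative residual is below 1e-3, and reported in the
  `residual`/`stalled` attributes. Degenerate (rank-deficient) spectra get
  a relative diagonal jitter of 1e-10 and a warning. Exact coherence of 1
  makes `-ln(1-C)` unbounded; `transform_coherence()` errors by default
  and accepts a finite cap when asked.
* **Multitaper estimation.** Slepian tapers come from the symmetric
  tridiagonal eigenproblem (top-k Lanczos via `igraph::arpack`, dense
  fallback), cached per configuration. The default 9 tapers with
  time-bandwidth `NW = (K+1)/2 = 5` reproduce the stated half bandwidth
  `(K+1)/(2T) = 2.22 Hz` for 2.25 s epochs. Taper FFTs are zero-padded by
  a factor 2 so the implied circular grid carries the full sample
  autocovariance — without padding, downstream factorization hits an
  aliasing floor around 1e-3 for strongly coherent pairs.
* **Preprocessing order** is fixed: line-noise removal per epoch, then
  linear detrend, then z-score. Line noise is removed by sliding-window
  least-squares sinusoid regression (0.75 s windows, 0.375 s steps,
  defaults 50/150 Hz), a deliberately simple cleaner validated by its own
  contract: ≥ 20 dB reduction at the line, < 1 dB change elsewhere.
  Power summaries are computed from the *detrended but not z-scored*
  epochs: per-channel variance normalization equalizes total power, which
  would make the unipolar-vs-bipolar power comparison meaningless, while
  coherence and the Granger quantities are scale-invariant and use the
  fully normalized epochs. This ordering is the package's choice and is
  the only point where the two stages diverge.
* **Distance bins.** Pairs are grouped by inter-position distance into
  25 / 50 / 75–150 / 175–325 µm bins (±1 µm tolerance); pairs beyond
  325 µm are excluded. On a 15-channel, 25 µm-pitch array this yields
  14 / 13 / 42 / 35 pairs.
* **NCR estimation** uses the 200–450 Hz band — above plausible fly
  neural coupling, below the 500 Hz Nyquist — and, by default, only the
  farthest available separation bin, where volume conduction and genuine
  coupling are weakest and the equal-NCR assumption is most defensible.
  Band-averaged coherence is debiased by the standard small-sample
  correction `C - (1-C)²/ν` with `ν = tapers × epochs` before inverting;
  without it the estimator overshoots noticeably for weak coherences
  (NCR ≳ 3).

## What the synthetic generator emulates

`generate_session()` mimics a linear-array fly-brain preparation:
15 unipolar channels at 25 µm pitch, 1000 Hz, 8 consecutive epochs of
2.25 s. Each channel is `y_i = z_i + s_i + vc_i - r`:

* `z_i` — independent local AR(1) streams (φ = 0.8, sd 0.3): broadband
  activity that is spatially uncorrelated.
* `s_i` — a shared slow field: near-unit-root AR(1) (φ = 0.97, sd 0.35)
  driven by innovations with exponential spatial correlation
  (length 75 µm). This gives adjacent channels highly similar
  low-frequency activity while leaving high frequencies essentially
  independent — which is what makes the bipolar power smaller than the
  unipolar power at *every* frequency and lets shared-channel bipolar
  pairs approach the 0.25 coherence ceiling at high frequencies. A
  frequency-flat nearest-neighbour innovation mixing cannot do both (its
  correlation is capped at 0.5 and does not decay with frequency), which
  is why the generator uses a spatio-temporally structured field instead.
* `r` — a global white reference signal (variance 1 by default), the
  dominant common signal; with the default spectra the implied band-level
  NCR is ≈ 0.08, i.e. strongly contaminated high frequencies, comparable
  to coherences around 0.8 for adjacent pairs.
* `vc_i` — a white source at the array centre with exponentially decaying
  amplitude (variance 0.5, length 100 µm), giving unipolar coherence its
  distance dependence.

The analytic ground truth (per-channel neural and common spectra, implied
NCR) is derived from the configuration, not estimated. Sessions are fully
deterministic given the seed.

What the generator does *not* emulate: non-stationarity, evoked activity,
spike leakage, realistic 1/f exponents, non-Gaussian artifacts, or
biophysically detailed volume conduction. Passing tests therefore show
that the pipeline recovers known ground truth under the stated
assumptions, not that real recordings satisfy those assumptions. Two
caveats found while validating are worth knowing about: (i) volume
conduction leaves amplitude *differences* in bipolar derivations that
interfere destructively with the shared-channel term, so the 0.25 ceiling
claim is tested with the reference-only configuration where its
equal-power assumptions actually hold; (ii) the percentage of
instantaneous interaction is reported as `NA` where the transformed
coherence vanishes, and is numerically meaningless wherever coherence sits
at the multitaper bias floor (~`1/(tapers × epochs)`).

## Scale of the bundled analyses

The default grids (512 analytic points; 2251 spectral bins for 2.25 s
epochs padded ×2) and session sizes (15 channels × 18 s) keep a full
session analysis, including ~200 pairwise Wilson factorizations, in the
tens of seconds on one core; the NCR-recovery sweep runs five such
sessions without the Granger stage. These sizes are the package defaults
and are what the test suite exercises.

## Known limitations

* Strictly pairwise: no conditional/partial Granger causality, no
  multivariate referencing schemes (ICA/PCA), no significance testing —
  the decomposition is descriptive.
* The full distance-resolved coherence expression under simultaneous
  reference and volume-conduction contamination is not modeled
  quantitatively; the package preserves the qualitative prediction
  (high-frequency coherence decreasing with separation) only.
* `remove_line_noise()` is a regression cleaner, not a Thomson F-test
  detector; it assumes stationary line amplitude within its 0.75 s
  windows.
* EDF/NEV/NWB import is out of scope; the interchange format is delimited
  text plus a JSON sidecar.
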