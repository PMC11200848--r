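---
title: "Methods: multiscale phase-space complexity of electrodermal activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale phase-space complexity of electrodermal activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcomeda)
```

## The problem

Electrodermal activity (EDA) is the skin-conductance correlate of
sympathetic nervous system activation: a slowly wandering tonic baseline
carrying fast phasic skin-conductance responses (SCRs). Its mean and
variance drift within a recording, and its amplitude is spiky — two features
that break the distance thresholds on which Approximate and Sample Entropy
rest. The indices implemented here sidestep both issues by measuring
complexity in the *directions* of the reconstructed phase-space trajectory
rather than in its amplitudes.

## Pre-processing

`preprocess_eda()` fixes the pipeline order as: **resample to 5 Hz →
tonic/phasic decomposition → noiseless reconstruction (tonic + phasic) →
z-score**. Decomposing at the analysis rate rather than the acquisition rate
is a deliberate choice: all downstream analysis is defined at 5 Hz, the
decomposition is cheaper there, and a zero-phase filter sees the same
frequency content either way. One `eda_signal` is one stimulus window, so
the z-score is per stimulus.

* Downsampling uses a zero-phase frequency-domain low-pass (raised-cosine
  transition, cutoff `0.4 * target_fs`) before index decimation. Zero phase
  matters because phase distortion would warp the embedded trajectory; DC is
  preserved exactly by construction. No DSP package exists in the target
  environment, so the filter is implemented in-package.
* The decomposition interface is pluggable. The bundled `"lowpass"` backend
  takes tonic = zero-phase low-pass at 0.05 Hz (the conventional
  tonic/phasic boundary, configurable) and phasic = remainder, with zero
  residual, so tonic + phasic + residual reconstructs the input exactly. A
  `"cvxeda"` backend name is reserved for an external convex-optimisation
  decomposition; it is cited work, not re-implemented, and requesting it
  without an implementation raises an error that names the fallback. With
  the lowpass backend the "noiseless" reconstruction equals the input; the
  stage still matters as the hook where a sparsity-based decomposition would
  actually denoise.

## Embedding parameters

τ is the first local minimum of the auto mutual information (AMI), m the
first dimension whose false-nearest-neighbour (FNN) fraction drops below 5%.

* **AMI estimator**: equal-width 2-D histogram plug-in, default
  `n_bins = min(ceiling(sqrt(N)), 64)`, `max_lag = min(N/4, 100)` samples.
  The histogram plug-in is the reference-implementation norm; anything
  fancier changes τ by at most a sample or two on these short windows.
* **Local-minimum rule**: smallest lag ℓ ≥ 1 with a strict drop from ℓ−1 and
  no rise to ℓ+1; plateaus take their first index. If no local minimum
  exists the global minimum is used; a monotone non-increasing curve falls
  back to `max_lag` with a warning — such a τ usually makes the multiscale
  trend untruncatable and should be treated as a data-quality flag.
* **FNN**: Kennel criteria with r_tol = 15, a_tol = 2, Theiler window = τ,
  candidate dimensions 1…10. These are the canonical thresholds; the
  sources this design follows do not state their own. m is floored at 2
  because angular statistics need at least a plane. Zero-distance neighbour
  pairs (exact trajectory repeats, e.g. a sampling-commensurate sine) are
  excluded from the fraction, since the distance ratio is undefined there.

## The single-scale index

For the n = N − (m−1)τ delay vectors, every unordered pair contributes the
cosine of its angle, d_ij ∈ [−1, 1]. Self-matches are excluded; pairs where
either vector's norm is below 1e-12 are skipped (cosine undefined), and more
than 1% skipped pairs is a hard error, because that signals a near-constant
signal rather than noise.

The distribution of the d_ij is estimated with a **diffusion kernel density
estimator**: Gaussian kernel, bandwidth chosen by the improved
Sheather–Jones fixed point solved in the DCT domain (seven plug-in stages),
evaluated on a 2^14-point mesh. Numerical choices:

* The mesh spans **[−1, 1]**, the geometric support of a cosine, rather than
  the observed data range — the estimate cannot leak probability into
  impossible values. Binning then uses the observed range, so empty extreme
  bins do not dilute the entropy.
* Bin masses are obtained by **integrating the mesh density over each of the
  B Sturges bins** (rectangle rule on the fine mesh) and renormalizing, not
  by evaluating the density at bin centres: Rényi entropy consumes masses,
  not point densities. B = ⌈log₂ n_pairs⌉ + 1 is computed from the number of
  **distance samples** (the PDF's sample size), not the number of embedded
  vectors; the sources leave this ambiguous and the distance count is the
  statistically meaningful one.
* If the fixed point cannot be bracketed (ultra-regular data) the standard
  `0.28 N^(−2/5)` fallback bandwidth is used. All distances identical is a
  degenerate single-bin PDF and yields index 0 with a warning.

ComEDA = R₂ / log₂ B with R₂ = −log₂ Σ p_i². The printed form of this
normalization in the source literature is typographically garbled; division
by log₂ B is the only reading that lands in [0, 1] with equality at the
uniform distribution. Because only angles enter, ComEDA(c·x) = ComEDA(x) for
any c > 0 — exactly in theory, to ~1e-15 in floating point (the test suite
asserts 1e-12).

## The multiscale index

Coarse-graining at scale β replaces the series by means of consecutive
non-overlapping β-blocks, dropping the remainder (the classical
multiscale-entropy construction; the index bound in the defining sum forces
truncation). (τ, m) are estimated **once at β = 1 and reused at every
scale** — re-estimating per scale would change the geometry being compared
across scales. MComEDA is the **trapezoidal** area under ComEDA(β) with unit
β spacing: the minimal-assumption quadrature for integer scales. The raw
area (bounded by β_max − 1) is the default; `normalize = TRUE` divides by
the span for a [0, 1] variant, since whether the reference implementation
normalizes is unknown.

Scale ranges follow recording length: β ∈ [1, 20] needs ≥ 30 samples at the
coarsest scale (a two-minute 5 Hz recording), shorter recordings use
β ∈ [1, max_scale(N, 25)]. When a fixed (τ, m) makes a high scale
unembeddable, the default is a hard error; the `"truncate"` policy instead
cuts the trend at the last valid scale with a warning, which is what the
cohort pipeline uses so that every subject contributes an AUC.

## EDASymp and the statistics workflow

EDASymp is the mean power spectral density in [0.045, 0.25] Hz, one
Hamming-tapered periodogram per non-overlapping 30-s window, averaged over
full windows (partial tails dropped). The taper and estimator are not fixed
by the source description; a single tapered periodogram per window is
declared here and a within-window Welch average would be a reasonable
alternative.

Group comparisons mirror standard psychophysiology practice: per-subject
averaging of repeated stimuli into one value per condition
(`aggregate_by_condition`), Lilliefors normality flags (Monte-Carlo null by
default — the analytic Dallal–Wilkinson approximation is available — since
no Lilliefors implementation exists in the target environment), a Friedman
test with mid-rank tie correction as the gate, and pairwise two-sided
Wilcoxon signed-rank tests with Bonferroni correction (family = all
k(k−1)/2 pairs, capped at 1). The Wilcoxon implementation drops zero
differences (classical convention, matching the MATLAB `signrank` default),
uses mid-ranks for ties, and computes the exact null by dynamic programming
over doubled ranks for n ≤ 25 — exactness under ties is the reason for
hand-rolling rather than wrapping `stats::wilcox.test`, whose exact path
refuses ties. Above n = 25 it switches to the tie- and continuity-corrected
normal approximation.

## The synthetic generator

`generate_eda()` emulates the structure the pre-processing assumes: tonic
level + slow sinusoidal drift (0.003 Hz, random phase), Poisson-timed SCRs
with log-normal amplitudes (CV 0.5) convolved with a Bateman kernel (rise
0.75 s, decay 10 s — physiologically typical), plus white measurement noise.
Defaults (120 s at 5 Hz, 4 SCRs/min, 0.5 µS mean amplitude, 2 µS baseline)
describe a plausible stimulus window; "arousal" is operationalized purely as
SCR rate. `generate_cohort()` adds subject-level random effects (tonic
offset, amplitude scale) shared across conditions so paired tests see real
within-subject pairing, with child seeds derived from one master seed.

What the generator does **not** emulate: motion artefacts, electrode drift
and detachment, SCR shape variability between and within subjects,
non-Poisson temporal clustering of responses, or any valence-specific
waveform difference. A green directional test therefore establishes that the
pipeline orders SCR-rate conditions correctly with paired statistics — not
that it reproduces any particular empirical effect size on real recordings,
which require the external datasets and are out of scope here.

## Known limitations

* All-pairs cosine computation is O(n²) memory and time; fine for the
  ultra-short windows targeted (n ≈ 600), not for hour-long recordings.
* The lowpass decomposition backend cannot remove noise (residual ≡ 0); a
  sparsity-based decomposition would change absolute index values, though
  the z-score and the scale invariance of the cosine limit the impact.
* A monotone AMI curve (no local minimum) falls back to the maximum lag,
  which usually makes high scales unembeddable; the warning should be
  heeded rather than silenced.
* The Lilliefors Monte-Carlo p-value inherits the caller's RNG stream; set a
  seed for reproducible flags.
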