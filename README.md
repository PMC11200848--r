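# mcomeda

Multiscale complexity analysis of electrodermal activity (EDA) in R.

Skin conductance reflects sympathetic nervous system activity: a slowly
drifting tonic baseline with fast, spiky skin-conductance responses (SCRs)
superimposed. Classical entropy measures (Approximate/Sample Entropy) behave
poorly on such non-stationary, spiky series. This package implements a
phase-space complexity index built for EDA, **ComEDA**, and its multiscale
extension **MComEDA**, for researchers in psychophysiology and affective
computing who want to quantify how "complex" the electrodermal response to a
stimulus is — e.g. to separate high- from low-arousal conditions — even on
ultra-short (≤ 2 min) recordings.

## The indices

Given a pre-processed series *y(1) … y(N)* (5 Hz, tonic+phasic "noiseless"
reconstruction, z-scored):

1. **Takens embedding.** Delay vectors
   *Y(j) = [y(j), y(j−τ), …, y(j−(m−1)τ)]*, *n = N − (m−1)τ* of them.
   τ is the first local minimum of the auto mutual information; m comes from
   the false-nearest-neighbours criterion (Kennel thresholds r = 15, a = 2).
2. **Angular distances.** For every unordered pair,
   *d\_ij = ⟨Y(i), Y(j)⟩ / (‖Y(i)‖₂ ‖Y(j)‖₂)* — the cosine of the angle
   between the two state vectors. Using angles instead of amplitudes makes
   the index exactly invariant to positive rescaling of the signal.
3. **Entropy of the distance distribution.** A diffusion kernel density
   estimate (Gaussian kernel, improved Sheather–Jones bandwidth) of the
   *d\_ij*, integrated over *B = ⌈log₂ n\_pairs⌉ + 1* Sturges bins, gives bin
   masses *p\_i*; the quadratic Rényi entropy *R₂ = −log₂ Σ p\_i²* is
   normalized to
   **ComEDA = R₂ / log₂ B ∈ [0, 1]**.
4. **Multiscale view.** The series is coarse-grained at scale β
   (non-overlapping block means, Eq. *x^(β)(i) = (1/β) Σ y(b)*), ComEDA is
   evaluated at each β with the scale-1 (τ, m), and
   **MComEDA = trapezoidal area under ComEDA(β)**, bounded by β\_max − 1.

Also included: the spectral sympathetic index **EDASymp** (mean PSD in
[0.045, 0.25] Hz over non-overlapping 30-s windows) for comparison, and the
paired nonparametric group workflow: Lilliefors normality flags, Friedman
test as a gate, pairwise Wilcoxon signed-rank tests (exact null up to n = 25,
ties handled) with Bonferroni correction.

## Worked example

```r
library(mcomeda)

# synthetic two-minute EDA recording at 5 Hz, 6 SCRs/min (high arousal)
raw    <- generate_eda(synth_config(duration_s = 120, fs = 5,
                                    scr_rate = 6, seed = 42))
sig    <- preprocess_eda(raw)            # 5 Hz, tonic+phasic, z-scored
params <- estimate_embedding(sig)
#> <embedding params> tau = 17 samples, m = 3

comeda(sig, params)
#> [1] 0.9060  — single-scale complexity, in [0, 1]

trend <- multiscale_trend(sig, params, betas = 1:10)
#> b1     b2     b3     b4     b5     b6     b7     b8     b9    b10
#> 0.9060 0.9754 0.9859 0.9801 0.9876 0.9927 0.9837 0.9511 0.9852 0.9502

mcomeda(trend)
#> [1] 8.7699  — area under ComEDA(beta), max possible 9 for beta 1..10

edasymp(sig)
#> [1] 0.5072  — mean sympathetic-band PSD (power/Hz), z-scored units
```

ComEDA near 1 says the angular-distance distribution is close to uniform
across its Sturges bins: the phase-space trajectory explores directions
richly, as dense phasic activity produces. A sparse, low-arousal recording
scores lower, and the gap widens across scales: in the bundled cohort
experiment (30 synthetic subjects, 1 vs 6 SCRs/min, β ∈ [1, 10]) the group
medians are ≈ 5.7 vs ≈ 8.4 with Bonferroni-adjusted Wilcoxon p ≈ 2 × 10⁻⁶
(`arousal_separation_experiment(n_subjects = 30, seed = 1)`).

Group statistics from a per-stimulus metric table:

```r
cohort <- generate_cohort(30, list(low  = synth_config(scr_rate = 1),
                                   high = synth_config(scr_rate = 6)), seed = 1)
tab     <- run_compute(cohort, betas = 1:10)          # one row per recording
reports <- run_stats(tab)                             # per metric
reports$mcomeda                                       # Friedman + pairwise table
```

A command-line front end with `synth`, `compute` and `stats` subcommands is
installed at `system.file("cli", "mcomeda", package = "mcomeda")`.

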