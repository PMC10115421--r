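---
title: "Methods: synthetic-data validation of a pain EEG connectivity pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic-data validation of a pain EEG connectivity pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

painconn implements, end to end, the statistical machinery of a
within-subject pain-perception EEG study — spectral power, phase
connectivity, directed connectivity, Bayes-factor inference and
model comparison — and validates every stage on synthetic data with
known ground truth. This vignette documents the model assumptions,
the parameter choices and their rationale, the numerical methods, and
the limitations of the synthetic generator.

## The experimental design

The design is a 2×2 within-subject factorial: stimulus **intensity**
(low/high) crossed with cued **expectation** (low/high). The four cells
are labelled `liLE`, `liHE`, `hiLE`, `hiHE` (canonical order throughout
the package). The **prediction error (PE)** contrast is the
intensity-by-expectation interaction; it loads on the cue/stimulus
mismatch cells `hiLE` and `liHE`. A probabilistic cue design yields
unequal cell sizes, by default 60/20/20/60 trials (75 % cue validity).
Six regions of interest (S1, cPO, iPO, ACC, cPFC, iPFC) are treated as
abstract signal sources; epochs span −1 to +1 s around stimulus onset at
500 Hz.

## Synthetic generator

`simulate_epochs()` builds each ROI signal as a sum of:

1. **Narrowband components**, one per analysis band: Gaussian noise
   band-passed to the band (order-4 Butterworth, zero-phase), unit
   variance. Condition effects are *multiplicative amplitude* changes
   (`power_effect`), applied in the trials where the factor's high level
   is active. Between-subject variability is log-normal:
   amplitude × exp(`subject_sd` · z), `subject_sd` = 0.2 by default.
2. **Lagged shared components** (`coupling_effect`): one narrowband
   stream added to both ROIs of a pair, with a quarter-period lag
   between them so the coupling has a non-zero phase lag and is visible
   to the (zero-lag-insensitive) dwPLI. Coefficients are additive;
   factor `"all"` sets a condition-independent baseline.
3. **Directed MVAR components** (`directed_edge`): a stable AR(2)
   resonator at the band centre (pole radius exp(−π·smoothing/rate))
   drives a second resonator at a fixed sample lag with a configurable
   cross-coefficient. The companion-matrix spectral radius is checked at
   configuration time and unstable edge sets are rejected with the
   offending edge named.
4. **White observation noise** (`noise_sd` = 1).

Each trial is simulated with a 1-s burn-in that is discarded, so filter
and AR transients never reach the analysis window. All randomness
derives from one master seed via `derive_seed(master, stage_name)`
(a multiplicative-congruential hash, keeping every seed inside the
32-bit integer range), so runs are bit-reproducible and stages are
statistically independent.

**Why short edge lags for directed effects.** PDC direction recovery
from narrowband signals is *phase-ambiguous* at lags near a quarter
period: a lag of +T/4 is indistinguishable from −T/4 of the reversed
direction once observation noise blurs the envelope. The generator's
default study configurations therefore use short sample lags
(e.g. 2 samples = 4 ms at 500 Hz) for directed edges, which is also the
physiologically plausible regime for cortico-cortical conduction. The
lagged *shared* components used for undirected coupling keep the
quarter-period lag, because dwPLI only needs a non-zero phase lag, not
an identifiable direction.

**Benign cross-talk.** The generating mechanisms are not orthogonal in
feature space. A coupling effect adds a shared band-limited component
to both member ROIs, so it also raises their band *power* in the
affected conditions; conversely a power effect changes the
signal-to-noise ratio of any coupling sharing that ROI and band, which
shifts the measured dwPLI. Recovery checks therefore assert that each
generated effect is detected on its own contrast and that the pattern
call includes the generated factor (`"multiple"` calls on strongly
modulated features are generator-correct, not false positives).

Ratings are generated additively on the 0–100 scale
(intercept 40 + 20·intensity + 5·expectation + subject offset + noise;
no generated interaction), clipped with a warning if cell means sit
outside the scale by more than 3 noise SDs.

## Spectral analysis

Band power uses multitaper estimation with discrete prolate spheroidal
(Slepian) tapers, computed from the classic symmetric tridiagonal
eigenproblem. For a window of T seconds and smoothing half-width W Hz,
K = ⌊2WT⌋ − 1 tapers are used. The three analysis bands are estimated
as a single smoothed estimate at the band centre whose bandwidth covers
the whole band:

| band  | range (Hz) | centre | smoothing W | K (1-s window) |
|-------|-----------|--------|-------------|-----------------|
| alpha | 8–12      | 10     | 2           | 3               |
| beta  | 14–30     | 22     | 8           | 15              |
| gamma | 60–100    | 80     | 20          | 39              |

Windows are demeaned before tapering. The default analysis window is
0–1 s post-stimulus; `control_window()` provides band-specific
response-latency windows (alpha 0.5–0.9 s, beta 0.3–0.6 s, gamma
0.15–0.35 s). `tfr_percent_change()` provides a descriptive
time-frequency view (Hanning windows, 500 ms below 30 Hz / 250 ms
above, percent change against a −0.75 to −0.25 s baseline).

## Source reconstruction

`lcmv_filter()` implements the linearly constrained minimum-variance
beamformer per frequency band: the band-limited sensor covariance C
(covariance of the Butterworth band-passed, concatenated trials) is
regularized as C + reg·(tr C/n)·I with reg = 0.05 (5 % of mean sensor
power, the conventional default), and each ROI's weights are
w = C⁻¹L/(LᵀC⁻¹L), passing the ROI's leadfield column with unit gain
(enforced to 1e−6 in tests) while minimizing output variance. With a
free-orientation (3-column) leadfield, the orientation maximizing the
filter output is chosen (minimal eigenvector of LᵀC⁻¹L). The package
ships only a random toy leadfield — the ROIs are abstract sources, and
no geometric head model is claimed; `read_leadfield()` is the import
path for a real one.

## Connectivity

**dwPLI.** Phase connectivity uses the debiased weighted phase lag
index. With Im Sᵢ the imaginary parts of the cross-spectra over
observations (trial × taper by default),

dwPLI = ((Σᵢ Im Sᵢ)² − Σᵢ (Im Sᵢ)²) / ((Σᵢ |Im Sᵢ|)² − Σᵢ (Im Sᵢ)²).

Being built from imaginary parts only, it is insensitive to
instantaneous (zero-lag) mixing, the dominant EEG volume-conduction
artifact; the debiasing term removes the positive finite-sample bias of
the plain squared WPLI. Small negative values are retained — clipping
at zero would re-introduce bias. Per subject, dwPLI is computed per
condition cell, ROI pair and band from that cell's trials only.

**PDC.** Directed connectivity fits a bivariate MVAR model by
multi-trial least squares (each trial contributes its own lagged
regressors; one coefficient set). The partial directed coherence from
channel j to i is |Āᵢⱼ(f)| normalized by the root sum of squares of
column j, where Ā(f) = I − Σₘ Aₘ e^(−i2πfm/rate); band values are means
over a 1-Hz grid. The default order is 5 at 500 Hz (the data are
band-limited and the generating edges are short-lag;
`select_mvar_order()` offers BIC selection over 1–20). The **asymmetry
score** (PDC_{A→B} − PDC_{B→A})/(PDC_{A→B} + PDC_{B→A}) ∈ [−1, 1]
summarizes net flow direction; it is NA-with-flag when both strengths
are zero. In the pipeline, directed analysis runs on pairs flagged by
the connectivity rmANOVA — with all trials for main-effect flags, and
mismatch trials only for interaction-only flags — and the per-subject
asymmetries are tested against zero.

## Bayesian inference

**rmANOVA Bayes factors.** For a subjects × 4 cell matrix, the model is
y = μ1 + Σ_b X_b β_b + ε with orthonormalized blocks: normalized
Helmert subject contrasts (random effect, prior scale r = 1) and the
three ±1/2 condition contrasts (fixed effects, r = 0.5). Each β_b has a
block g-prior β_b | g_b ~ N(0, σ²g_b I) with g_b ~ InvGamma(1/2, r²/2),
and (μ, σ²) carry the Jeffreys prior. Conditional on g the marginal
likelihood is closed-form (Woodbury identity; the orthonormal blocks
make XᵀX diagonal, so each block collapses to sufficient statistics);
the g's are integrated numerically. Reported BFs are *top-down*: full
model versus the full model with one effect removed
(`method = "inclusion"` averages over the standard model space
instead).

**Numerical choice.** Gauss–Hermite quadrature after the substitution
g = r²/z² fails here — the integrand is proportional to |z|, whose kink
at the origin defeats polynomial quadrature (errors up to ~20 %).
Instead each g is mapped to t = g/(g + r²) ∈ (0, 1) and integrated by
tensor-product Gauss–Legendre (48/32/24/16 nodes per dimension for 1–4
blocks); this agrees with a brute-force dense Monte-Carlo oracle to
well under the 5 % acceptance tolerance.

**Pattern calls.** A feature is called `intensity`, `expectation` or
`PE` when exactly one of the three BFs exceeds 3; `multiple` when more
than one does; `evidence_against` when all three are below 1/3; `none`
otherwise.

**Rank-based one-sample test.** Group asymmetry scores are tested with
a rank-based Bayesian one-sample test: the signed ranks are represented
by latent normal variables with mean δ and unit variance, Gibbs-sampled
under the ordering/sign constraints they imply; δ carries a
Cauchy(0, 1/√2) prior via normal/inverse-gamma augmentation, and BF₁₀
is the Savage–Dickey ratio at δ = 0 with a Rao-Blackwellized posterior
density (8000 draws, 1000 burn-in, fixed internal seed; the
Monte-Carlo SE of log BF is reported). The data's sign is canonicalized
before sampling, making the BF exactly invariant to a global sign flip,
and the use of ranks makes it invariant to monotone transformations.
`method = "parametric"` gives the standard JZS t-test instead.

**Sample size.** `required_sample_size_rmanova()` reproduces the
convention of the standard power tools for a one-group,
m-measurement repeated-measures within factor: noncentrality
λ = N f² m ε/(1 − ρ), df₁ = (m−1)ε, df₂ = (N−1)(m−1)ε. With power
0.95, α = 0.05, f = 0.25, m = 4, ρ = 0.5, ε = 1 the smallest adequate N
is 36 (N = 35 gives power 0.946).

## Model comparison

For each contrast (intensity, expectation, PE), every feature — 18
per-ROI band powers and 45 per-pair band dwPLIs, over subject × cell
observations — is scored by the log evidence of a Bayesian logistic
model (intercept + z-scored feature, independent N(0, 1) priors)
predicting the contrast label. Evidence is computed by Laplace
approximation at the posterior mode (Newton iterations; the proper
prior keeps it defined under perfect separation), validated against 2-D
grid quadrature to 0.05 nats. The family-level Bayes factor
BF_pow/conn is the ratio of arithmetic means of the evidences
(computed in log space), i.e. equal-prior Bayesian model averaging
within each family.

## Pipeline, matching, calibration

`run_pipeline()` chains: simulate (or load) → optional sensor
projection + per-band LCMV → trial matching → subject exclusion →
ratings rmANOVA → power table + rmANOVAs → dwPLI table + rmANOVAs →
directed analysis on flagged pairs + one-sample BF → model comparison.
Trial matching subsamples every cell to the minimum cell count
(seeded, single subsample by default); subjects with fewer than
`min_trials = 10` matched trials per cell are excluded. Provenance
(config hash, seed, matched counts, package version) is stamped on
every result object.

**Calibration band.** The null behaviour of the feature screens is
fixed a priori: with all generator effects at zero, at most 15 % of
features per family (power, connectivity) may be flagged (BF > 3 occurs
in roughly 2–4 % of null features per effect, so with three effects per
feature the expected flag rate is well under 15 %), and the replicate
geometric mean of each aggregate model-comparison BF must lie in
[1/3, 3]. This band is enforced by the acceptance suite on five
fixed-seed null runs.

The null runs set the between-subject amplitude SD to zero. Subject
amplitude heterogeneity is a nuisance parameter of the generator, not
an experimental effect, and it interacts asymmetrically with the two
feature families: it inflates the total variance of every power feature
with a component that is orthogonal to the (balanced) within-subject
condition labels, shrinking those features' chance separation after
z-scoring, while connectivity features — dominated by trial-level
estimation noise — keep their full chance fluctuation. Under
heterogeneity the family-mean aggregate therefore tilts persistently
below 1 even with all effects at zero (observed geometric means around
0.3–0.4 at the default SD of 0.2). Centring features within subject
before the logistic fit removes the tilt but makes the heavy-tailed
family mean far *more* volatile under the null, so it is deliberately
not done (see `run_model_comparison()`); aggregate BFs from
heterogeneous-subject data should be read against a null band centred
below 1, and the enforced calibration band applies to the
homogeneous-subject null.

## Problem sizes used in validation

The generator defaults *are* the study conditions (n = 40 subjects,
60/20/20/60 trials, 6 ROIs, 500 Hz, 2-s epochs). The acceptance suite
runs reduced but honest scales chosen for a 1-CPU budget: directed-flow
recovery at n = 40 subjects with 15/5/5/15 trials plus 20 direction
replicates at n = 8; the dissociation study at n = 20 subjects with
30/10/10/30 trials; null calibration over five replicate runs at
n = 10 with 8 trials per cell; debiasing checks at 30 trials per
estimate (the debiased estimator retains a small genuine negative bias
at very low trial counts, e.g. ~8 trials); oracle equivalence at n ≤ 6
subjects (ANOVA) and n = 50 observations (logistic). Beamformer
round-trip fidelity is scored against the *identically band-passed*
sources: the zero-phase IIR is applied per 2-s trial, and its edge
transients — not source leakage, which is measured separately and is
negligible — are what limit raw source/reconstruction correlations.

## What the generator does and does not emulate

It emulates: condition-dependent band-power modulation with subject
variability, genuinely lagged phase coupling, unidirectional band-limited
information flow, volume-conduction-like instantaneous mixing (via the
sensor projection), artifact-like trial loss, and additive rating
structure. It does not emulate: 1/f background spectra, non-stationary
induced responses (power effects are sustained over the epoch),
phase-amplitude coupling, realistic head geometry, muscle/ocular
artifacts, or non-sinusoidal waveform shape. Conclusions from the
validation are therefore about the *estimators and inference chain*,
not about claims that real EEG satisfies the generating model.
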