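---
title: "Methods: autonomic indices and PLS path modeling in anspm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autonomic indices and PLS path modeling in anspm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anspm)
```

# The scientific problem

Emotion-laden advertisements are designed to engage the autonomic nervous
system (ANS); whether that engagement translates into better recall of the
advertised message is an empirical question. `anspm` implements the full
analysis chain for a study design in which subjects watch a one-minute
baseline followed by six one-minute spots while ECG and electrodermal
activity (EDA) are recorded, then answer a recall questionnaire scored on
a 0–15 scale. Per-spot autonomic indices feed a latent-variable structural
model estimated by partial least squares path modeling (PLS-PM).

# The structural model and its estimation

Four constructs are measured reflectively: *Sympathetic* (`lf`, `sdnn`,
`ns_scr`, `mean_scl`), *Vagal* (`hf`, `pnn50`, `rmssd`), *ANS* (`lf_hf`,
`avnn`) and *Recall* (`recall_score`), with edges Sympathetic → ANS,
Vagal → ANS, ANS → Recall. Reflective measurement assumes each indicator
is caused by its construct, hence indicators within a block must be
positively aligned: before fitting, an indicator is negated when its
correlation with the block's first principal component is negative
(`align_indicator_signs()`). The component is oriented to the block's
first indicator, which makes the flip set — and therefore the whole fit —
deterministic.

Estimation (`fit_plspm()`) is the classical iterative composite scheme:

1. standardize all indicators;
2. outer approximation: each latent score is the weighted sum of its
   block's indicators, re-standardized to unit variance;
3. inner approximation: each construct's "inner estimate" is a weighted
   sum of connected constructs' scores. The default *path* scheme weights
   predecessors by their multiple-regression coefficients and successors
   by correlations; *centroid* (signs of correlations) and *factorial*
   (correlations) are also available;
4. Mode A outer update: each indicator's weight is proportional to its
   covariance with the inner estimate of its construct;
5. iterate until the largest change of the (unit-variance-normalized)
   outer weights falls below `tol`.

Defaults: `tol = 1e-7`, `max_iter = 300`, path scheme, outer weights
initialized at 1. On the shipped model the fixed point is reached in a
handful of iterations; non-convergence is reported via a warning and a
`converged = FALSE` flag rather than an error, so partial fits can be
inspected.

Path coefficients β are ordinary-least-squares coefficients of each
endogenous construct's score on its predecessors' scores; with
unit-variance scores these are standardized betas, and for a
single-predictor construct β equals the score correlation exactly — a
closed-form identity the test suite asserts at `1e-9`. Fit is summarized
by R² per endogenous construct, indicator communalities (squared
loadings), and

$$\mathrm{GoF} = \sqrt{\overline{\mathrm{communality}} \times \overline{R^2}}.$$

Communality is averaged over *all* indicators, including single-indicator
blocks (communality exactly 1). Classical practice sometimes excludes
single-indicator blocks from that average; with this model the inclusive
convention raises GoF slightly and is applied uniformly.

## Significance machinery

*Bootstrap* (`bootstrap_paths()`): rows are resampled with replacement,
each resample is re-aligned and refitted, and a path is significant at
level α when its two-sided percentile interval excludes zero (defaults
`n_boot = 500`, α = 0.05). Resamples producing a zero-variance indicator
or singular structural regression are redrawn and counted. A
normal-approximation p-value is reported alongside for convenience; the
decision rule is the percentile interval.

*Multigroup comparison* (`permutation_group_test()`): the statistic per
edge is the difference of group-wise β; the null distribution comes from
refitting both groups under random label permutations, and
$p = (1 + \#\{|\Delta_{perm}| \ge |\Delta_{obs}|\})/(1 + n_{perm})$,
which is never exactly zero. Defaults `n_perm = 999`. Type-I calibration
of both procedures at α = 0.05 (empirical rate within 5% ± 2% under null
simulations, and approximate uniformity of permutation p-values) is part
of the acceptance suite.

No multiple-testing correction is applied across the six spots or three
edges; reports carry a note to that effect.

## Attenuation: what "recovering β" means with noisy indicators

Composite-based estimation is *attenuation-biased* when loadings are
below 1. For a block of $k$ standardized indicators with common
indicator–construct correlation $r$, the equally-weighted composite
correlates with its construct at
$\rho_k = r\sqrt{k}/\sqrt{1+(k-1)r^2}$, and the population value of a
fitted path is the true β multiplied by the $\rho$ of both endpoint
blocks. With $r = 0.8$ the shipped model's attenuation is roughly 17% on
the Sympathetic → ANS edge. The parameter-recovery acceptance test
therefore checks noise-free tables against the raw truth (±0.05 at
n = 1000) but noisy tables against this closed-form population value
(within 3 Monte-Carlo standard errors over 100 replicates): demanding the
raw truth under noise would fail for any correctly implemented Mode A
estimator. Practically: fitted β from real data should be read as lower
bounds on the latent effect.

# Signal processing choices

**R-peak detection** is a Pan–Tompkins-style energy detector: zero-phase
5–15 Hz band-pass, derivative, squaring, 150 ms moving-window
integration, adaptive threshold (0.3 × the 90th percentile of candidate
peak heights), R localization as the raw-signal maximum within ±100 ms,
and a 200 ms refractory period throughout. It is deliberately behind a
one-function interface so an alternative detector can be swapped in.

**Ectopic exclusion** (`build_nn_series()`): an interval deviating more
than 20% (configurable) from a running 5-interval median marks its
terminating beat as ectopic, and *both* intervals adjacent to that beat
are excluded — a non-sinus beat corrupts the interval into it and out of
it. Successive-difference statistics (RMSSD, pNN50) only use pairs of
retained intervals that were adjacent in the original series.

**Time-domain indices**: AVNN (mean), SDNN (sample standard deviation,
n − 1 denominator), RMSSD, and pNN50 as the *proportion* in [0, 1] of
absolute successive differences strictly greater than 50 ms. The
proportion convention is used consistently everywhere (tables, model
indicators).

**Frequency-domain indices**: the retained tachogram is cubic-spline
interpolated to 4 Hz, linearly detrended, Hann-tapered, and turned into a
one-sided periodogram (a Welch estimate with a single full-epoch segment —
60 s epochs leave no room for segment averaging, a resolution limitation
worth stating: Δf ≈ 0.017 Hz). Band powers integrate VLF (0.003–0.04 Hz),
LF (0.04–0.15 Hz) and HF (0.15–0.4 Hz); normalized powers divide by total
power above 0.04 Hz, so `lf_norm + hf_norm ≤ 100` holds by construction,
and `lf_hf` is the ratio of absolute band powers. VLF estimates on epochs
shorter than ~333 s are flagged `vlf_reliable = FALSE` but still enter
the normalization denominator's complement as defined. The spectral
precondition accepts tachogram spans ≥ 55 s because a nominal 60 s epoch
necessarily spans slightly less between its first and last beats.

**EDA decomposition**: the tonic level is extracted with a zero-phase
low-pass at 0.1 Hz and `mean_scl` is its epoch mean; zero-phase filtering
keeps that mean unbiased by group delay. Filtering is implemented by
applying the squared-magnitude response of a 4th-order Butterworth design
in the frequency domain on a reflect-padded signal — exactly zero phase
with no edge transients, which matters for 60 s epochs that are short
relative to a 0.1 Hz cut-off. The trace is decimated to 20 Hz first,
since a 0.1 Hz FIR/IIR at 1 kHz is numerically awkward and the tonic
band is far below the decimated Nyquist.

**SCR counting** follows the downsample/differentiate/Bartlett pipeline:
decimate to 20 samples/s (anti-alias filtered), first-difference,
convolve with a 20-point Bartlett window (centred alignment), then count
local maxima of the resulting spiky signal above threshold with ≥ 1 s
separation. Neither an amplitude criterion nor a separation rule is
canonical in the source procedure, so the threshold defaults to
`max(0.01, 3 × MAD(spiky signal))` — scale-adaptive, robust to tonic
drift, never firing below a 0.01 µS-scale response — and both knobs are
configurable and echoed in the output.

# Recall scoring

Each questionnaire item carries a point budget awarded in full on a
correct answer; the total spans 0 (no recall) to 15 (perfect recall).
The original item-level allocation is not public, so the shipped default
spreads 15 points equally over 10 items (six spontaneous-message items,
one emotion-match, two suggested yes/no, one suggested multi-select);
whether spontaneous and suggested sections should weigh equally is
genuinely open and therefore a configuration input, not a constant.
Multi-select items award proportional credit (correct minus incorrect
selections over the number of correct options, floored at zero). Missing
responses score zero and are listed in the result. Scoring is additive,
hence monotone in item correctness and invariant to item order — both are
tested properties.

# The synthetic-data module: what it does and does not establish

The generators state a fixed world with known ground truth:

- **NN series**: mean RR plus additive LF and HF sinusoids plus white
  jitter. All modulation power sits at two known frequencies, giving an
  analytic spectral oracle; this is *not* an integral-pulse-frequency
  model and makes no claim of physiological realism beyond band content.
- **ECG**: one biphasic (Mexican-hat) template per beat on a flat
  baseline plus white noise — detectable R-peaks, nothing more. No P/T
  waves, no baseline wander, no motion artifacts.
- **EDA**: level + linear drift + bi-exponential (Bateman-type) SCRs,
  peak-normalized to their stated amplitudes — the standard sudomotor
  impulse-response shape, exercising the detector realistically.
- **Indicator tables**: exogenous latent scores are independent standard
  normals; endogenous scores add a disturbance with variance
  1 − explained, so every construct is exactly unit-variance and the
  simulated βs read as standardized coefficients. Indicators are
  loading · LV + Gaussian noise.

Pipeline defaults for simulated subjects (signals mode) are ordinary
resting values chosen once: RR 850 ms, 25 ms LF/HF modulation, 10 ms
jitter, SCL 5 µS with 0.2 µS/min drift, ~0.4 µS SCRs at a few per minute,
mild emotion-dependent shifts (emotional spots damp HF, raise LF and SCR
rate). No per-emotion effect sizes are published for the source design,
so these shifts are user-configurable style choices, not calibrated
values.

A green test on this world establishes *algorithmic correctness*
(round-trips, closed forms, calibration), not field validity: real ECG
morphology, respiration-coupled HRV, motion artifacts and semantic recall
coding are all outside the generator. The end-to-end β-recovery oracle
uses table mode, because raw-signal mode has no known β ground truth —
its physiological indices are not generated from a latent model; signals
mode is instead tested for shape, validity and determinism.

# Numerical and reproducibility choices

- One master seed per study; every stochastic stage derives its own
  substream seed via a multiplicative hash (`derive_seed`), all below
  2³¹. Reports are byte-identical across reruns of the same config+seed.
- RNG state is saved and restored around every seeded generator, so
  package calls never perturb the caller's stream.
- Zero-variance indicators, cyclic structural graphs, singular structural
  regressions, too-short epochs, and flat ECG traces raise typed errors
  (`anspm_*` condition classes) rather than producing NaNs.
- Degenerate bootstrap resamples are redrawn (capped at 10 × `n_boot`);
  degenerate permutation replicates count as exceedances, which is
  conservative.
- Rows with missing indicators are dropped with a count kept on the fit.

# Known limitations

- 60 s epochs give coarse spectral resolution; LF/HF estimates per spot
  are noisy, and VLF is unreliable by construction (flagged).
- Mode A composites attenuate structural paths (quantified above);
  loadings near 1 or many indicators per block mitigate this.
- The permutation and bootstrap procedures refit per replicate without
  caching; runtime scales linearly in `n_perm`/`n_boot`.
- Respiratory influence on HRV and non-linear construct relations are out
  of scope, as is deconvolution-based phasic EDA analysis — the model
  uses only the SCR count and mean SCL.
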