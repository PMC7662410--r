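# anspm

Modeling autonomic nervous system (ANS) engagement during emotion-laden
advertisements — and its link to what viewers later recall — from raw
physiological recordings.

The package is aimed at psychophysiology and consumer-neuroscience studies
with the following design: subjects watch a baseline period followed by a
sequence of one-minute advertisement spots (each conveying a predominant
emotion) while ECG and electrodermal activity (EDA) are recorded; afterwards
a questionnaire measures spontaneous and suggested recall on a 0–15 scale.
`anspm` turns those recordings into per-spot autonomic indices and fits a
latent-variable structural model per spot.

## The model

Four latent variables (LVs) are estimated from nine manifest variables
(MVs) with *reflective* indicators, using partial least squares path
modeling (PLS-PM, Mode A):

| Latent variable | Manifest variables |
|---|---|
| Sympathetic | `lf`, `sdnn`, `ns_scr`, `mean_scl` |
| Vagal       | `hf`, `pnn50`, `rmssd` |
| ANS         | `lf_hf`, `avnn` |
| Recall      | `recall_score` |

with structural edges Sympathetic → ANS, Vagal → ANS, ANS → Recall. Path
coefficients β are standardized OLS weights of the latent scores, per-spot
fit is summarized by R² of the endogenous constructs and the
goodness-of-fit GoF = √(mean communality × mean R²). Significance of β
comes from bootstrap percentile intervals; gender differences are tested by
permutation of the group labels.

HRV indices (AVNN, SDNN, RMSSD, pNN50, normalized LF/HF power, LF/HF
ratio) are computed from R-peaks detected with a Pan–Tompkins-style
detector, after ectopic-beat exclusion. EDA is split into the tonic skin
conductance level (zero-phase 0.1 Hz low-pass; `mean_scl`) and phasic skin
conductance responses counted by the downsample → differentiate → Bartlett
convolution pipeline (`ns_scr`).

Because raw study data of this kind are rarely shareable, a first-class
synthetic-data module generates NN-interval series with controllable LF/HF
spectral content, ECG traces with beats at prescribed times, EDA traces
with injected SCR events, and indicator tables with known loadings and
path coefficients — so every stage is testable round-trip against ground
truth.

## Worked example

```r
library(anspm)
truth <- latent_ground_truth(loadings = 0.9,
                             path_coefficients = c(0.6, -0.5, 0.35),
                             noise_sd = 0.3, n_subjects = 120, seed = 42)
tab <- generate_indicator_table(truth)
fit <- fit_plspm(tab)
print(fit)
#> <plspm_fit> 120 rows, scheme 'path', converged in 4 iterations
#> Path coefficients:
#>         from     to       beta
#>  Sympathetic    ANS  0.5743380
#>        Vagal    ANS -0.4526502
#>          ANS Recall  0.2372590
#> R^2: ANS = 0.612, Recall = 0.056
#> GoF: 0.558
```

The fitted β are the standardized structural weights: sympathetic activity
raises the ANS construct (β ≈ 0.57), vagal activity lowers it (β ≈ −0.45),
and the ANS explains only ~6% of recall variance here — close to the
simulated truth (0.6, −0.5, 0.35) up to sampling noise and the mild
attenuation expected with 0.9 loadings.

```r
bootstrap_paths(tab, n_boot = 500, seed = 42)[, c(1:3, 5:7)]
#>         from     to   beta  ci_lo  ci_hi significant
#>  Sympathetic    ANS  0.574  0.439  0.693        TRUE
#>        Vagal    ANS -0.453 -0.573 -0.323        TRUE
#>          ANS Recall  0.237  0.054  0.400        TRUE

permutation_group_test(tab, group = tab$gender, n_perm = 999, seed = 42)
#> <group_comparison> F vs M, 999 permutations
#>         from     to     beta_a     beta_b        diff p_value
#>  Sympathetic    ANS  0.5418786  0.6008865 -0.05900799   0.662
#>        Vagal    ANS -0.4388558 -0.4720352  0.03317943   0.814
#>          ANS Recall  0.1188829  0.3565452 -0.23766229   0.181
```

All three paths are significant at α = 0.05 (their 95% percentile CIs
exclude zero), and — as expected, since the generator makes no gender
distinction — no path differs between groups.

An end-to-end study (segmentation → features → scoring → per-spot fits →
gender comparison → report) runs from one config:

```r
cfg <- study_config(
  synthetic = list(mode = "table", n_subjects = 50,
                   path_coefficients = c(0.4, -0.55, 0.3)),
  analysis = list(seed = 11))
report <- run_study(cfg)
write_study_report(report, "out/")
```

or from the command line:

```sh
Rscript -e 'anspm::anspm_cli()' run --config study.yaml --seed 11 --out out/
```

CLI verbs: `simulate` (write a synthetic study), `features` (signal CSVs →
indicator table), `fit` (table → fit JSON), `run` (end-to-end), `report`
(re-render CSV summaries).

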