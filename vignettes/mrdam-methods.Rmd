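---
title: "Methods: models, estimators and simulation design in mrdam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and simulation design in mrdam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdam)
```

`mrdam` reimplements, as tested reusable code, a cross-species quantitative
pipeline that links adiposity to sleep: human-genetics causal inference
(per-SNP association scanning with FDR control and Mendelian randomisation
on GWAS summary statistics) on one side, and *Drosophila* behavioural and
metabolic quantification (DAM sleep scoring, starvation death calling,
climbing index, CAFE feeding, comparative-Ct qPCR, Kaplan–Meier/log-rank
survival) on the other. Because the human cohort data that motivate the
scan and MR components (biobank-scale genotype–phenotype panels, eQTL and
GWAS consortia summary files) are access-restricted, the package ships a
first-class synthetic-data module with recorded ground truth, and every
downstream method is validated against that truth or against independent
hand/package oracles.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the simulations do and do not
establish.

## 1. The cohort model

`simulate_genotypes()` draws additive effect-allele dosages per SNP as
Binomial(2, MAF) — Hardy–Weinberg equilibrium with no linkage
disequilibrium. Independence between SNPs is deliberate: it keeps the
instrument-independence assumptions of the downstream MR literal, and no
LD-pruning rule is part of the modelled workflow. `simulate_cohort()` then
builds

$$x_i = \textstyle\sum_j \beta^{exp}_j g_{ij} + a U_i + \varepsilon_i,
\qquad
y_i = \theta x_i + \textstyle\sum_j \beta^{dir}_j g_{ij} + b U_i + \eta_i,$$

with a single latent standard-Gaussian confounder $U$ and independent
Gaussian noise. The exposure plays the role of a continuous obesity marker
(waist-to-hip-ratio-like) and the outcome a continuous sleep duration in
hours; both are treated as Gaussian, matching the linear-regression
analyses being modelled (no binary/odds-ratio path in v1). Defaults are
$a = b = 0.5$ and unit noise SDs — moderate confounding against unit-scale
traits, chosen once as a realistic cohort regime and not revisited.
Covariates are user-specified via a named plan (`dist`, parameters,
loadings); no covariate list is hard-coded because the modelled study
defines its covariates only in a figure.

Every generator takes an explicit seed and restores the caller's RNG state
(`with_seed()`), so a cohort is a pure function of `(params, seed)`.

`simulate_summary_stats()` reduces two *independent* cohorts to per-variant
marginal OLS summary statistics (effect, SE, p, allele frequencies) — the
two-sample MR input. One-sample analyses reuse a single cohort; no
sample-overlap correction is applied anywhere, and users should treat
one-sample SEs as slightly optimistic.

## 2. Association scan and FDR

`scan_snps()` fits one OLS regression per SNP
(`phenotype ~ intercept + dosage + covariates`) over complete cases, via QR
with SEs from the residual variance and t-based p-values. Genotypes are
coded additively (0/1/2 effect-allele copies), the standard biobank
convention. The "scaled estimate" is the coefficient with both phenotype
and dosage z-standardised, which equals `beta * SD(dosage)/SD(phenotype)`
exactly — both scales are always reported. Monomorphic SNPs are flagged and
excluded from the FDR family rather than dropped silently; complete-case
counts are logged per scan.

`adjust_fdr()` is the Benjamini–Hochberg step-up with q-values
`min_{j>=i} m p_(j)/j`, capped at 1, restored to input order. The FDR
family is one scan (one phenotype against one SNP set), matching per-panel
correction; pooling across phenotypes is possible by concatenating p-value
vectors but is off by default.

## 3. Mendelian randomisation

### Harmonization

`harmonize()` intersects exposure and outcome tables on variant id, aligns
the outcome to the exposure's effect allele (sign and frequency flip when
swapped), attempts strand complementation before declaring a mismatch, and
handles palindromic (A/T, C/G) variants by allele frequency: orientation by
frequency concordance when both MAFs are informative, dropped as ambiguous
when `min(eaf, 1-eaf) > 0.42` (configurable; `"drop"` and `"keep"` policies
available). Harmonization is idempotent and logs every dropped variant with
a reason. Instrument selection happens upstream (scan rejections or
eQTL-style hits); no p-value thresholding is applied inside the MR module.

### Estimators

*Wald ratio* (single instrument): `beta = beta_out/beta_exp` with the full
delta-method SE
`|beta| * sqrt(se_out^2/beta_out^2 + se_exp^2/beta_exp^2)`, reducing to
`se_out/|beta_exp|` in the `beta_out = 0` limit; Wald z-test and normal CI.

*IVW*: precision-weighted average of per-instrument ratios,
`beta = sum(w_j r_j)/sum(w_j)`, `w_j = s_j^{-2}`, fixed-effect SE
`(sum w_j)^{-1/2}`. The choice of $s_j$ matters more than is often
appreciated, and the package measured three conventions on 1000 simulated
replicates of its own recovery design (20 instruments with mean effect 0.2,
two samples of n = 5000, true effect 0.3):

| ratio-SE convention | 95% CI coverage |
|---|---|
| first-order, `se_out/|beta_exp|` | ~0.93 (SEs ignore exposure noise) |
| per-variant second-order | ~0.90 (weights correlate with per-variant error) |
| modified second-order (default) | ~0.95, reported SE matches empirical SD |

The default therefore evaluates the delta SE at the *pooled* estimate,
`s_j^2 = (se_out^2 + beta^2 se_exp^2)/beta_exp^2`, iterated twice from the
first-order fit: exposure-side uncertainty is accounted for without letting
noisy per-variant outcome betas leak into the weights. Both alternatives
remain available via `weights=`. A single-instrument input collapses
exactly to the Wald ratio. Random-effects mode inflates the SE
multiplicatively by `max(1, sqrt(Q/(J-1)))` and never deflates it.

*Weighted median*: the weighted 50th percentile of the ordered ratios
(cumulative-weight midpoints, linear interpolation at 0.5), consistent when
valid instruments carry over half the total weight. Its SE comes from a
seeded parametric bootstrap (default 1000 replicates, seed 20230421):
resample each summary beta from a normal with its reported SE, recompute,
take the SD. Here the per-variant *second-order* SEs are the default
weights: an instrument with a directionally inflated gene–outcome effect
receives a larger ratio SE and hence less weight, which measurably reduces
finite-sample bias under directional pleiotropy (mean bias 0.034 vs 0.070
with first-order weights in the package's 30%-contamination design). With
`se_exp = 0` the two conventions coincide.

`mr_analysis()` harmonizes once, routes single-instrument inputs to the
Wald ratio, runs every requested estimator, and collects per-method errors
without aborting the rest.

## 4. DAM sleep architecture

The native resolution is the 30-s activity bin; all minute-level rules are
expressed in whole bins. Sleep is the field convention: a maximal run of
zero-count bins lasting at least 5 minutes (configurable). Scoring starts
at the first lights-on (ZT0) after recording start and covers whole 24-h
cycles; day is ZT0–12 under the default 12:12 cycle. A bout spanning
lights-off contributes minutes to each phase pro rata (per bin); an
"assign to onset phase" alternative is a flag. Waking activity is total
counts divided by non-sleep minutes, undefined (flagged, not numeric) for a
fly that never wakes. Sleep + waking minutes always partition the scored
window exactly.

The rhythmicity index answers "is there a circadian component?", since the
program named by the modelled workflow defines its score only by a
threshold of 1. The implementation aggregates activity to 30-min bins,
takes the peak positive autocorrelation at lags 22–26 h, and divides by a
one-sided white-noise envelope Bonferroni-corrected across the lags
examined at family level 0.01: an arrhythmic (white-noise) fly scores >= 1
with probability at most 1%, while even weak genuine 24-h periodicity
scores far above 1. This is a documented interpretation with the same
decision rule, not a reproduction of the original score. Exclusion order is
fixed and logged: dead flies first (terminal flat tail >= 24 h for
multi-day sleep assays), then arrhythmic (RI < 1), then scoring.

Death calling uses the "last bout of waking activity" rule: a record ending
with at least `flat_tail_hours` of zeros (default 12 h, the starvation
endpoint convention) is a death at the end of the last nonzero bin.
Mid-record quiescence followed by renewed activity is never a death.

### What the activity generator emulates — and what it does not

`simulate_activity()` alternates wake and sleep bouts with geometric
lengths (phase-dependent means: 30-min night sleep bouts vs 10-min day
bouts by default, yielding ~540 night and ~180 day sleep minutes — a
typical healthy-male profile), bimodal morning/evening waking activity, and
optional deaths. Under the noiseless default, waking bins are
zero-truncated and generated sleep bouts never fall below the scoring
threshold, so scored sleep equals the generator's bout-constructed truth
*exactly* — this is what the green ground-truth tests establish. They do
not establish robustness to real-data pathologies: position-dependent beam
sensitivity, micro-movements below beam resolution, bout fragmentation at
the 5-min boundary, or monitor dropouts (the `noisy = TRUE` profile
reintroduces zero-count waking bins only). The recorded death truth is the
observable quantity (end of the last nonzero bin), so death-calling tests
verify the rule, not biological death times.

## 5. Bench assays

The climbing index for the five-trial counter-current apparatus is the
weighted average `sum(i * n_i) / (5 * sum(n_i))` over chambers 0–5: 0 when
every fly fails the first trial, 1 when every fly passes all five. The
printed source formula was unreadable in extraction (figure image); this
transcription is the standard convention and satisfies every pinned
property (range endpoints, scale invariance, monotonicity under moving a
fly up one chamber). CAFE intake converts capillary displacement (mm) to
volume via the 1-µl graduation calibration, sums the vial's capillaries,
and reports per fly and per fly per hour (19-h feeding default); both are
emitted because the reporting convention is ambiguous. An optional
evaporation-blank column can be subtracted by the caller; none is applied
by default because the modelled protocol describes no evaporation control.

Comparative-Ct fold changes average technical replicates after excluding
any (sample, gene) whose replicate CV of raw Ct exceeds 3% (CV is computed
on raw Ct, not linearised quantities — the convention is unstated, so the
simpler reading is used and configurable). ΔCt subtracts the reference gene
per sample; ΔΔCt subtracts the *mean control-group* ΔCt per target gene
(a single-calibrator mode is the natural alternative and can be emulated by
a one-sample control group); fold change is `2^(-ΔΔCt)`, making the
control-group mean exactly 1. Plate-reader normalisation to protein (or
per-fly weight normalisation) is the generic elementwise ratio
`normalize_per_reference()` with strict positivity checks.

## 6. Survival

`kaplan_meier()` is the product-limit estimator over distinct event times
with Greenwood variance; at tied times deaths are processed before
censorings (the standard convention). Grouped vial transfers every 2–3 days
make death times interval-censored in principle; they are treated as exact
at the recorded day, matching common practice. `logrank_test()` is the
two-group Mantel–Haenszel statistic with hypergeometric expectations and
variances, chi-square on 1 df; only pairwise comparisons are provided, as
every modelled comparison is pairwise. The asymptotic p-value is compared
in tests against an exact permutation enumeration at 8 events (agreement to
within the discreteness of 70 permutation atoms) and calibrated under the
null over 2000 exponential simulations.

## 7. Numerical and engineering choices

- OLS uses QR; rank deficiency raises an explicit singular-design error
  rather than dropping columns. Coefficients are verified against explicit
  normal-equation solves to 1e-8 on random small instances.
- BH, KM and the log-rank statistic are hand implementations (they are the
  operations under test); `stats::p.adjust` and the `survival` package
  serve as independent oracles in the test suite only.
- All seeds are explicit arguments; derived seeds stay below 2^31.
- DAM parsing accepts one fixed 36-column dialect (index, date, time,
  status, 32 channels) with strict grid checks and row-numbered errors;
  rows with non-valid status become `NA` bins (treated as waking, zero
  counts) and are logged. A long-format CSV fallback exists.
- Simulation sizes in the default test run are scaled to a single CPU:
  the full 200-replicate acceptance designs run in the acceptance suite
  (~4.5 min total); module-level property tests use smaller screening
  versions of the same designs.

## 8. Known limitations

- No LD, no allele-frequency stratification, no binary traits, no
  sample-overlap correction in one-sample MR.
- No MR-Egger/MR-PRESSO/Steiger filtering; the weighted median is the only
  pleiotropy-robust estimator.
- The rhythmicity score is an interpretation (autocorrelation-based), not
  the original program's statistic; only its decision rule is shared.
- Sleep scoring assumes a strictly regular grid and whole-bin rules; no
  periodogram-based period estimation or actogram rendering.
- The climbing and CAFE formulas are transcribed conventions (see above),
  pinned by property tests rather than by the unreadable printed images.
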