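---
title: "Methods: miRNA deregulation analysis against DCIS risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA deregulation analysis against DCIS risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcismir)
library(dplyr)
```

`dcismir` analyses miRNA expression deregulation in ductal carcinoma
in situ (DCIS) lesions relative to the Oncotype DX® DCIS
recurrence-risk score. This vignette is the package's account of the
statistical model, the choices made where the design was genuinely
open, and the limits of what the shipped tests demonstrate.

## The cohort table and its coding rules

The packaged fixture `dcis_cohort41.csv` describes 41 ER-positive DCIS
lesions with Oncotype DX DCIS scores between 0 and 78, stratified
into low (< 39, n = 26), intermediate (39–54, n = 10) and high
(≥ 55, n = 5) risk groups. Three coding rules matter:

* **Censored ages are boundary-coded.** Two patients have ages
  recorded only as bounds ("≤30", "≥80"). They enter every summary
  at the boundary value (30 and 80) with the censoring flag kept in
  the `age_censor` column. This is the only coding under which the
  cohort's reported group mean ages (overall 63.5, low 64.8, high
  56.4) are reproduced, so it is frozen as the package's convention.
* **Missing nuclear grade is excluded listwise** from the grade ×
  risk-group contingency analysis (one lesion is ungraded, leaving
  n = 40 there).
* **Group means are reported at one decimal; medians are exact**
  (midpoint of the central pair for even n).

The contingency test is a Pearson chi-square without continuity
correction. Some expected cell counts are below 5, so the asymptotic
p-value is approximate; the test suite checks it against a
10,000-shuffle permutation null on the fixture table and finds
agreement within Monte-Carlo error (the permutation p is ~0.072
against the asymptotic 0.079).

```{r cohort}
clin <- read_clinical(dcismir_example("dcis_cohort41.csv"))
cohort_age_summary(clin, by_group = TRUE)
glance(grade_group_contingency(clin, collapse_int_high = TRUE))
```

## Correlation screens

Counts are total-count normalized: per-sample fractions, and a log2
counts-per-million scale with pseudocount 1 added to the raw counts
before scaling. The pseudocount keeps zero counts finite while
preserving ordering; both `scale` and `pseudocount` are arguments of
`normalize_counts()` because the field has no single convention for
this transform.

`screen_vs_score()` correlates each miRNA's log2 expression with the
continuous DX score (Pearson), `screen_vs_age()` with age (Spearman
— the appropriate choice for a monotone-but-not-necessarily-linear
age trend). p-values come from the t-distribution with n − 2 degrees
of freedom; Spearman p-values are computed as Pearson-on-mid-ranks
with the same t reference, which handles ties by averaging ranks.
Benjamini–Hochberg adjustment is applied across all testable miRNAs;
BH is the standard default of the count-based differential-expression
tools this kind of screen sits alongside, and the adjustment method
is deliberately the only one offered to keep the family-wise
bookkeeping simple. Constant expression rows (or a constant
covariate) are flagged `testable = FALSE` rather than erroring, so a
genome-wide screen never aborts on a degenerate row.

Because multi-sample barcoded libraries can carry batch effects, the
screens offer a batch-partial mode: expression **and** covariate are
residualized on the library factor before correlating, and the
p-value reference loses one degree of freedom per extra batch level.
Residualizing only one side would attenuate estimates whenever batch
happens to correlate with the covariate in a finite sample, which is
why the partial (two-sided) form was chosen. The default is the
naive screen, since the generator's round-robin batch assignment is
unconfounded by design.

All tests are two-sided throughout the package; directions
("up"/"down") are reported descriptively from the sign of the
estimate, with "down" meaning expression falls as the score (or age)
rises.

`select_panel()` unions the top `k_score = 10` score-associated and
`k_age = 9` age-associated miRNAs passing adjusted p < 0.05,
mirroring the 17 + 9 hit structure the screens are designed around;
the `both` provenance marks miRNAs found by both screens, and a
`both` member takes its direction from the score screen.

## ΔΔCt quantification

Triplicate Ct values are averaged over detected replicates with a
quality flag: `partial` below three detections, `discordant` when
the replicate SD exceeds 0.5 cycles (a conventional qPCR
repeatability tolerance — configurable), `undetected` when nothing
amplified. Undetected reactions are treated as missing, **not** as
Ct = 40: imputing the cycle ceiling would fabricate a fold-change
where there is no measurement.

ΔCt subtracts the sample's endogenous-control (RNU6B) mean Ct; ΔΔCt
subtracts the per-miRNA mean ΔCt of the low-risk reference group
(group mean rather than a single calibrator sample, so the reference
group's fold changes have geometric mean exactly 1); fold change is
2^−ΔΔCt with amplification efficiency fixed at 2 — no
standard-curve efficiency correction is attempted. Group comparisons
report both Welch t and Mann–Whitney U p-values per miRNA; the
Mann–Whitney p is the primary one by default because ΔΔCt
distributions from small FFPE cohorts are routinely non-normal, and
the choice is configurable. The Mann–Whitney p is exact (full
enumeration) when the smaller group has ≤ 8 observations and there
are no ties, otherwise a tie-corrected normal approximation with
continuity correction is used; the threshold keeps exhaustive
enumeration instant.

NGS–qPCR concordance (`ngs_qpcr_concordance()`) correlates log2
sequencing expression with **−ΔCt** by default, because Ct is
inversely proportional to log2 template abundance; a concordant
assay pair therefore shows a positive r. The raw-ΔCt orientation
(mirror image) is available as an option for comparison with
conventions that plot Ct directly.

## The composite miRNA score

Each panel miRNA is z-standardized across samples with the sample SD
(n − 1 denominator — the usual small-sample default; the plain sum
is not rescaled by panel size). The score is the signed sum
`Σ s_m z_m,i` with `s_m = −1` for downregulated members, so the
score increases as panel expression falls, i.e. with risk. Only the
all-downregulated case strictly needs a convention; the signed
generalization lets mixed-direction panels (such as the packaged
17-miRNA sequencing panel) contribute coherently, and reduces to the
negative-z sum when every member is down. On the ΔΔCt scale the
signs flip internally (higher ΔΔCt already means lower expression),
which makes scoring ΔΔCt values and scoring −ΔΔCt on the expression
scale provably identical — a property the tests assert.

Consequences asserted as invariants: scores sum to zero across
samples for any panel; they are invariant under independent positive
affine transforms of each member's expression; flipping one member's
direction changes exactly its own contribution by −2 s_m z_m.
Constant panel members cannot be standardized and are excluded with
a warning rather than an error.

`score_group_discrimination()` defaults to low vs pooled
intermediate/high — in this setting the expression differences
concentrate between those two blocks, and the pooled comparison also
keeps both groups large enough for a meaningful rank test in a
41-patient cohort. `rank_extremity()` reports a sample's
descending-score rank within its own group with ties broken by
sample-id order (documented, deterministic).

## The synthetic-cohort generator

The generator defines the study conditions under which the pipeline
is validated; its defaults are fixed, not tuned:

| parameter | default | rationale |
|---|---|---|
| `n_samples`, `group_weights` | 41; 26/10/5 ÷ 41 | the cohort's design |
| `score_ranges` | 0–38 / 39–54 / 55–80 | risk-group score intervals |
| `age_mean`, `age_sd` | 64.8/63.7/56.4; 12/13/10 yr | group age structure, boundary-coded |
| `n_mirnas` | 300 | order of reliably quantified miRNAs in FFPE small-RNA data |
| `n_score_assoc`, `n_age_assoc` | 15, 9 | the screens' expected hit structure |
| `beta`, `gamma` | 0.8 log2 / realized SD | places planted Pearson r in the 0.3–0.65 band |
| `frac_up_score`, `frac_up_age` | 10/17, 2/9 | the sign mix the screens report |
| `batch_count`, `batch_max`, `batch_sd` | 4, 18, 0.25 log2 | four 18-plex barcoded libraries; mild batch noise |
| `dispersion` | θ = 10 | moderate NB overdispersion (var = μ + μ²/θ) |
| `libsize_range` | 2×10⁵–2×10⁶ (log-uniform) | small-RNA library depth spread |
| `planted_mean`, `planted_sd` | log2(0.003), 0.8 | centers planted miRNAs on the 0.1–1 % abundance band |
| `ct_intercept`, `ct_control`, `ct_sigma` | 18, 20, 0.3 cycles | Ct ≈ 25–30 for panel miRNAs; sub-half-cycle replicate noise |

Effects are planted on the log2 scale against the **realized**
cohort mean/SD of the covariate, so `beta` stays interpretable as
log2 change per SD regardless of n. Score and age standardization,
compositional normalization (fractions sum to 1) and NB sampling
mean that planted effects interact realistically: age-planted
miRNAs, for example, show genuine score correlations through the
group–age structure, which is why the truth-based "FDR" at the
reference configuration is not forced to zero — those discoveries
are not artifacts. FDR control proper is asserted under the global
null configuration (no planted effects), where BH keeps the mean
discovery fraction far below the nominal 0.05.

The Ct generator inverts the batch-free log2 relative expression
(`Ct = intercept − log2 rel. expr. + noise`), so at `ct_sigma = 0`
the ΔΔCt pipeline recovers planted fold changes *exactly* — the
closed-form inversion the tests exploit.

Determinism: each generator seeds R's RNG from `cfg$seed` with a
fixed offset (clinical +0, counts +1, Ct +2) and restores the
ambient RNG state afterwards, so runs are bit-reproducible and
independent of call order.

What the generator does **not** emulate: FFPE degradation and
fixation bias, adapter/ligation sequence bias, the calibrator-spike
normalization chemistry, miRNA–miRNA correlation structure beyond
what compositionality induces, and qPCR efficiency drift. Passing
tests therefore demonstrate the pipeline's statistical correctness
under a clean NB model, not robustness to every artifact of archival
tissue.

## Numerical choices and degenerate inputs

* Correlations with r² numerically at 1 are clamped before the t
  transform (`pmax(1 − r², eps)`), giving p ≈ 0 rather than NaN.
* Welch's test on two zero-variance groups returns p = 1 (identical)
  or p = 0 (separated) instead of erroring, since simulated ΔΔCt
  panels can be exactly degenerate at σ = 0.
* BH adjustment propagates `NA` (untestable) entries without
  counting them toward the family size m.
* Zero-total samples, empty panels, unknown miRNAs/samples and
  degenerate contingency tables raise informative errors naming the
  offending unit; constant rows degrade to flags, not errors.

## Problem sizes used by the shipped checks

The test suite and acceptance script validate at sizes chosen to
make the distributional checks sharp while staying lightweight: 20
synthetic cohorts (n = 32, 300 miRNAs) for planted-effect recovery,
50 global-null cohorts for FDR control, 1,000 random panels for the
composite-score invariants, 10,000 label shuffles for the
permutation cross-check of the contingency p, 5,000 replicates for
the Pearson size check, and 200 replicates for the 1.5 SD
discrimination-power estimate. The full synthetic pipeline
(simulate → screen → qPCR → score → cohort statistics) runs end to
end in a few seconds.

## Known limitations

* The per-miRNA correlation screen is a univariate analysis; it does
  not replicate NB-GLM differential expression (DESeq2/edgeR-style
  model fits are out of scope by design).
* Recurrence outcomes in the cohort table (two events) are
  descriptive only; no survival modeling is attempted.
* All cohort age summaries are computed from the boundary-coded ages
  in the shipped table (intermediate-group mean 63.7); codings that
  treat the two censored ages differently will shift the group means
  that involve them.
* Exact Mann–Whitney p-values are only guaranteed without ties;
  heavily tied small samples fall back to the corrected normal
  approximation.
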