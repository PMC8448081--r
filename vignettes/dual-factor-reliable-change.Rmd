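---
title: "Dual-factor reliable change analysis: models, defaults and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-factor reliable change analysis: models, defaults and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualchange)
```

## The problem

Group-mean improvement on a well-being scale and on a distress scale can
coexist with very different stories inside individuals: some people improve
on both dimensions, some only on one, some on neither. Under the dual-factor
view of mental health — well-being and distress as distinct, negatively
correlated dimensions — an evaluation should therefore report (a) the usual
group-level multivariate and univariate tests and (b) a within-individual
classification of *reliable* change on each dimension. `dualchange`
implements both halves plus the measurement layer underneath (scoring,
severity cutoffs, internal consistency) and a synthetic cohort generator so
the whole pipeline is testable without access to participant data.

## Measurement layer

Four instruments are shipped as declarative `scale_definition`s:

| outcome | instrument | scoring | range | healthy criterion |
|---|---|---|---|---|
| overall_wellbeing | MHC-SF, 14 items (0–5) | sum | 0–70 | ≥ 48 ("high") |
| life_satisfaction | SWLS, 5 items (1–7) | sum | 5–35 | ≥ 20 ("high") |
| dass_depression | DASS-21 items ×2 | 2×sum | 0–42 | < 10 (below "mild") |
| dass_anxiety | DASS-21 items ×2 | 2×sum | 0–42 | < 8 |
| dass_stress | DASS-21 items ×2 | 2×sum | 0–42 | < 15 |
| resilience | BRS, 6 items (1–5, 3 reversed) | mean | 1–5 | ≥ 3.00 ("normal") |

DASS-21 subscale sums are doubled so the standard DASS-42 severity bands
(normal/mild/moderate/severe/extremely severe) apply directly. Cutoff lower
bounds are *inclusive* — a score exactly at the "mild" bound is mild, which
matches the usual "met the threshold" phrasing. Severity bands and the DASS
bands come from the instrument manuals; the numeric "high well-being",
"high life satisfaction" and BRS bounds are not standardised in the
literature and are shipped as **documented implementer defaults** in
`inst/extdata/scales.json` (MHC-SF ≥ 48, SWLS ≥ 20 — Diener's neutral
point — BRS normal ≥ 3.00 / high ≥ 4.31). They are config values, not code:
pass an override file to `default_scales(path)` to change them.

Missing items: the default policy is complete-case per scale (the record is
scored `NA` for that instrument); there is deliberately no silent zero-fill.
Cronbach's α uses the classical variance-decomposition form and raises an
explicit degenerate-input error when total-score variance is zero rather
than propagating `NaN`.

## Reliable change

For each outcome, with pre score $x_1$ and post score $x_2$:

$$\mathrm{RCI} = \frac{x_1 - x_2}{SE_\text{diff}}$$

Two variants of $SE_\text{diff}$ are provided, estimated from the analysed
sample itself:

* `"difference"` (default): $SD_d\,\sqrt{1 - r_{12}}$ with $SD_d$ the SD of
  the difference scores and $r_{12}$ the pre–post Pearson correlation. This
  reproduces the formula printed in the study this pipeline models.
* `"jacobson_truax"`: $SD_{x_1}\sqrt{2(1 - r_{12})}$, the classic form.

**These are not interchangeable.** Under equal pre/post variances,
$SD_d = SD_{x_1}\sqrt{2(1-r_{12})}$, so the classic denominator *is* the SD
of the difference scores and the RCI is a unit-variance z-score under the
no-change null: null rate of "reliable improvement" ≈ 2.5%. The
`"difference"` variant divides by a denominator smaller by $\sqrt{1-r}$,
giving the index null variance $1/(1-r)$ — at $r = .7$ about 14% of
unchanged participants exceed 1.96 in the improvement direction. We keep
`"difference"` as the default because reproducing the published procedure
is the package's first job, but the null-calibration acceptance test runs
the calibrated `"jacobson_truax"` variant, and the anticonservatism of the
default is itself asserted in that test. Users doing fresh analyses should
prefer `"jacobson_truax"`.

Classification uses strict inequalities: improved iff RCI > 1.96,
deteriorated iff RCI < −1.96; exactly 1.96 is "no reliable change". The RCI
sign is orientation-normalised (positive = improvement) using each scale's
direction, so DASS decreases and MHC-SF increases read the same way.

**Patterns.** The well-being dimension is {overall_wellbeing,
life_satisfaction} and the distress dimension the three DASS subscales —
either outcome suffices for its dimension. Resilience is excluded from the
two-dimension pattern (its dimension membership is genuinely ambiguous) but
is tracked, so an improvement only on resilience counts toward "any
reliable change" without making the participant `wellbeing_only`. The
pattern split (`both` / `wellbeing_only` / `distress_only`) is reported
over the participants with ≥ 1 reliable improvement, with exact fractions
retained and integer-rounded display percentages. Deteriorations are
tracked and reported even though improvement is the headline. Subgroup
breakdowns condition on "met the mild threshold at baseline **and** showed
some reliable improvement", with the distress dimension restricted to the
named subscale; the denominator is reported explicitly (it may be 0).

A note on the source study's printed numbers: its pattern counts
(42+24+17 = 83) do not match its printed denominator (82), and 17/82 is
printed as 20%. `dualchange` reports exact counts and fractions and does
not reproduce that internal inconsistency.

## Group-level statistics

All three multivariate designs are Hotelling T² with the exact-F
transformation, so Wilks Λ, F, dfs and partial η² = 1 − Λ satisfy their
identities to machine precision (the test suite asserts
`partial_eta_from_f(F, p, n−p) = 1 − Λ` and the p = 1 reductions to the
paired and pooled t tests):

* pre–post: one-sample T² on difference scores, df (p, n−p);
* baseline cohort difference: two-sample T² on pre scores, df (p, n₁+n₂−p−1);
* group×time interaction: the same two-sample T² applied to difference scores.

The stratified Table-3-style tests default to Welch's correction (the
source tables show heterogeneous dfs consistent with per-outcome
corrections whose rule is unrecoverable, so the mode is a logged config
switch; pooled df is available). Cohen's d divides the mean-change gap by
the pooled SD of change scores, since the contrast is between mean changes.
Mann–Whitney U re-runs accompany — never replace — the t tests; the exact
null distribution is used only for small tie-free groups. An optional
rank-based inverse-normal re-run mirrors the usual
transformed-vs-untransformed robustness check; untransformed results are
primary. Outlier handling is flag-only at |z| > 3.29: exclusions are an
explicit `exclude_ids` decision recorded in the run log. No multiplicity
correction is applied anywhere, matching the modelled workflow.

## The synthetic cohort generator

`generate_cohort()` draws (pre, post) for the six outcomes from a
12-dimensional Gaussian:

* **Margins.** Defaults are the published total-sample pre/post means and
  SDs (e.g. overall well-being 45.81 (11.18) → 49.39 (12.19)); the implied
  mean changes are the "true" effects. n = 89, student fraction 32/89.
* **Correlations.** Cross-outcome |r| = 0.50 (the reported band is
  .40–.65), positive within each dimension and negative across; pre–post
  r = 0.7 per outcome. The pre–post cross-block is
  $A R A$ with $A = \mathrm{diag}(\sqrt{\rho_j})$, which for common ρ is
  the Kronecker product of two correlation matrices and hence positive
  definite; general configurations are eigenvalue-checked before sampling.
  Because no pre–post correlations are published, ρ = 0.7 is an implementer
  default chosen as typical test–retest stability for these instruments
  over ~5 weeks; sensitivity tests vary it.
* **Students.** A mean-preserving 0.5-pre-SD gap in the unhealthy
  direction at both timepoints: students sit below the general cohort, the
  configured means remain the *total-cohort* means (they describe the whole
  analysed sample), and the within-cohort covariance is shrunk by the
  mixture-variance share $f(1-f)\,\text{gap}^2$ so marginal SDs also stay
  on target. The shift is identical pre and post — worse baselines, no
  group×time interaction, which is what the modelled study found.
* **Bounds.** The configured DASS margins put non-trivial Gaussian mass
  below 0 (≈ 17% for anxiety at mean 6.54, SD 6.77; ≈ 13% depression; ≈ 6%
  stress). Clamping that much mass would visibly distort the means, SDs and
  covariance the analyses rely on, so the default is `bounds_action =
  "none"`: out-of-bounds fractions are always computed and attached as the
  `truncation` attribute, and `"clamp"` is opt-in for users who need
  range-respecting scores. Scores are kept continuous (the analyses treat
  them as continuous); severity classification clips to the scale range at
  lookup only.
* **Missingness** (`missing_post_fraction`) is completely at random at the
  participant level, emulating study attrition; informative dropout is out
  of scope. A single seed governs the whole cohort.

`generate_item_level()` supports α testing: a one-factor model whose
common inter-item correlation solves $\alpha = k\,r/(1+(k-1)r)$ for the
target α, inflated by an analytically computed attenuation factor (the
squared correlation between a standard normal and its equal-probability
binning into the item's response levels) so the *discretised* responses hit
the target; unattainable targets error with the attainable bound.

**What a green test does and does not establish.** The generator emulates
the first and second moments and the correlation geometry of a realistic
cohort. It does not emulate DASS right-skew (an optional stress-test with
skewed margins was considered and deliberately left out of the default
world; scores are symmetric Gaussians), item-level response styles,
floor/ceiling discreteness, or informative dropout. Green pipeline tests
therefore establish computational correctness and calibration under the
stated Gaussian world, not robustness to every distributional feature of
real questionnaire data — which is precisely why the inference layer also
carries the Mann–Whitney and rank-transform robustness paths.

## Numerical choices and degenerate inputs

* Severity bounds are inclusive; RCI thresholds strictly exclusive at 1.96.
* Covariance singularity is detected via Cholesky + reciprocal condition
  number (< 1e−12) and reported as advice to drop a redundant outcome, not
  as a numeric traceback.
* `SE_diff = 0` (zero-variance differences or r = 1) is flagged degenerate
  and downstream RCI computation refuses it by name.
* Percentages are displayed with `round()` (banker's rounding at .5);
  exact fractions are always retained in machine-readable output.
* p-values print as `P<.001` below the 3-decimal display threshold.
* All statistics are invariant to participant ordering; re-running an
  identical config byte-identically reproduces every CSV/JSON output.

## Known limitations

* The dual-factor pattern depends on the configured grouping; alternative
  memberships for resilience are a config change, not a code change.
* SEdiff is estimated from the analysed sample (self-referential), so RCI
  classifications change when the sample changes; no external reliability
  coefficients are built in.
* The exact per-outcome pooled-vs-Welch rule of the modelled study's
  stratified table is unrecoverable; only the two documented modes exist.
* No clinically-significant-change criterion (RCI combined with crossing a
  normative cutoff) — the modelled workflow used RCI alone.
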