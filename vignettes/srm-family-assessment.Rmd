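---
title: "Norm-referenced SRM family assessment: model, transformation, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Norm-referenced SRM family assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srmassess)
```

## The model

The Social Relations Model treats a directed dyadic measurement in a
four-person family as the sum of four latent components,

$$X_{ij} = \mathit{Fam} + \mathit{Act}_i + \mathit{Par}_j + \mathit{Rel}_{ij},$$

one family-level effect shared by all 12 directed dyads, an actor effect
per person (their general tendency as a rater), a partner effect per
person (the tendency they elicit as a target), and a directed
relationship effect per ordered pair. With a single indicator per
relationship, measurement error is not separable from the relationship
effect and is absorbed by it; relationship effects should therefore be
interpreted with more caution than the others. Components are assumed
mutually independent except for two association patterns: *generalized
reciprocity*, the within-person covariance between actor and partner
effect, and *dyadic reciprocity*, the covariance between the two directed
relationship effects of the same unordered dyad.

The package is deliberately restricted to families of exactly four: all
21 effects are identified there, the closed-form weights below are the
n = 4 case, and other family sizes are rejected with an error rather than
silently generalized.

## Per-family ANOVA scores

Arranging the 12 scores in a 4 × 4 actor-by-partner table leaves the
diagonal empty (no self-ratings), so raw row and column means are biased
for the actor and partner effects. The classical weighted estimators
correct for the missing cells; for family size $n$,

$$\widehat{Act}_i = \tfrac{(n-1)^2}{n(n-2)}\,\bar r_i +
  \tfrac{n-1}{n(n-2)}\,\bar c_i - \tfrac{n-1}{n-2}\,\bar g,$$

with $\bar r_i$, $\bar c_i$, $\bar g$ the row, column and grand mean; the
partner estimator swaps $\bar r_i$ and $\bar c_i$. At $n = 4$ the weights
are 9/8, 3/8 and −3/2. The family score is the grand mean and each
relationship score is the residual
$X_{ij} - \widehat{Act}_i - \widehat{Par}_j - \bar g$. By construction
the four actor scores sum to zero, the four partner scores sum to zero,
the relationship scores sum to zero within each actor row and each
partner column, and the 21 scores reconstruct every measurement exactly;
the test suite asserts these identities on randomly generated round
robins at tolerance 1e-9.

All 21 estimators are linear in the dyad vector, which the package makes
explicit as a 21 × 12 weight matrix `anova_weight_matrix()` (family row
1/12 everywhere; actor rows 1/4 on outgoing dyads, 0 on incoming, −1/8
elsewhere; partner rows mirrored; relationship rows as indicator minus
those three). The direct formulas and the matrix route are implemented
independently and tested against each other.

```{r}
round(anova_weight_matrix(c("M", "F", "C1", "C2"))[1:3, 1:6], 3)
```

## From published CFA parameters to the norm distribution of the scores

A norm-referenced Z score needs the mean and SD that the ANOVA scores
have *across the families of the norm population*. Norm studies, however,
publish CFA estimates of the latent component means, variances and
reciprocities. Because both the measurements and the ANOVA scores are
linear in the latent effects, the link is exact:

1. assemble the model-implied distribution of the dyad vector,
   $\mu_{ij} = \mu_{Fam} + \mu_{Act_i} + \mu_{Par_j} + \mu_{Rel_{ij}}$
   and the 12 × 12 covariance $\Sigma$ built from the family variance
   (all cells), shared-actor and shared-partner variances,
   generalized-reciprocity covariances wherever one dyad's actor is the
   other's partner, relationship variances on the diagonal and dyadic
   reciprocity covariances between the two directions of each dyad
   (`dyad_law()`);
2. propagate through the weight matrix: for effect $k$,
   $\mathrm{mean}_k = w_k \mu$ and
   $\mathrm{sd}_k = \sqrt{w_k \Sigma w_k^\top}$
   (`sampling_distribution()`).

Reciprocities published as correlations are first rescaled to
covariances, $r\sqrt{v_1 v_2}$; covariance-scale input is accepted as-is
after a Cauchy–Schwarz check. All reciprocity covariances, including
those of the relationship effects, enter the propagation — notably they
contribute to the variance of the family score (through the $2/144$ and
$18/144$ aggregation terms), and the built-in worked example reproduces
the published family-effect Z only when they are included, which settles
that design question in favour of inclusion.

Under the identification constraints usual for SRM means (actor means,
partner means, and relationship means within each actor row and partner
column sum to zero), the propagation leaves the family, actor and partner
means unchanged — the ANOVA scores are unbiased for the latent means —
which the test suite checks with exactly constrained random parameter
sets. Published parameters are rounded, so `validate_srm_norms()` only
warns (absolute tolerance 0.01, matching 3-decimal rounding) when the
constraints are violated; negative variances, correlations outside
[−1, 1] and Cauchy–Schwarz violations are errors.

```{r}
head(sampling_distribution(case_study_norms()), 5)
```

## Assessment

For each effect, $Z = (\text{score} - \text{mean}_k)/\text{sd}_k$; the
sign follows score − norm mean, so negative Z means below the norm. The
p-value is the two-sided standard-normal tail $2(1-\Phi(|Z|))$: the
normal reference matches the large-sample setting of the published
estimates, and no finite-sample t correction is attempted because the
norm-sample size is not an input. Flags use two thresholds on $|Z|$,
`elevated` (default 1, a potential risk factor) and `extreme` (default
2, a clear deviation); both are user-settable with the constraint
0 < elevated < extreme. P-values are reported raw by default — the
assessment is a screening instrument, and 21 simultaneous tests will
produce occasional false positives — with an optional Holm familywise
adjustment (`adjust = "holm"`).

Degenerate inputs are handled explicitly rather than propagated as
infinities: an effect whose propagated SD falls below 1e-8 is flagged
`non_assessable` (Z and p are `NA`); a negative propagated variance,
which can only arise from inconsistent published estimates making the
assembled covariance non positive semi-definite, is an error that reports
the smallest eigenvalue. If a norm file marks some component variances as
not significant in the norm sample, the corresponding rows are annotated
(`norm_var_significant = FALSE`) but never suppressed.

## The simulator, and what passing its checks does and does not show

`srm_simulate()` draws families from the generative model: the family
effect from a univariate normal, each person's (actor, partner) pair and
each dyad's (rel, rel-reversed) pair from bivariate normals factorized by
a 2 × 2 Cholesky (zero-variance blocks short-circuit to constants). Two
modelling points are deliberate:

* latent draws do **not** impose the zero-sum constraints per family —
  the constraints identify population means, not single families;
* multivariate normality is an assumption. The CFA framework and the
  two-standard-deviations convention both presuppose it, but the
  generator inherits it, so the Monte-Carlo checks validate the *linear
  propagation*, not distributional robustness.

The draw order (family effect, persons in role order, dyads in canonical
order) is fixed, so a fixed seed reproduces a run bit for bit.
`empirical_sampling_check()` compares the empirical mean and SD of every
effect's simulated ANOVA scores against the analytic values at 3
Monte-Carlo standard errors. The test suite runs this at 10,000 families
(plus a 100,000-family check of the dyad-level means and covariance and a
per-effect extreme-flag rate check against $2\Phi(-2) \approx 4.55\%$),
sizes chosen to keep Monte-Carlo error well below the tolerances while
the whole suite runs in seconds.

What these passes do not show: robustness to skewed or heavy-tailed
constructs, to informatively missing dyads (any missing dyad is a hard
error here), or to norm samples whose published estimates poorly describe
the population a particular family belongs to.

## Worked example and a note on its published reference table

The embedded case (RS-anxiety in one mother/father/two-child family,
norms from a 208-family sample) reproduces the published assessment table
to well within its printed rounding: the test suite asserts every Z
within 0.02 and every p within 0.005 of the printed values, and the
observed deviations are an order of magnitude smaller still. One printed
reference entry deserves a note: the published ANOVA
score for relationship F→C1 (−0.497) is internally inconsistent — the
printed scores of that actor row sum to −0.002 although the estimator
guarantees exactly zero, and the entry's own printed Z (−1.350)
back-solves to −0.495, which is what the exact decomposition yields. The
test suite documents this discrepancy explicitly instead of papering over
it.

```{r}
report <- srm_assess(case_study_dyads(), case_study_norms())
subset(as.data.frame(report), flag == "extreme",
       select = c(effect, anova_score, z, p))
```

## Limitations

* Four-person families only; no three-person or five-plus designs and no
  longitudinal round robins.
* No covariate adjustment: age, gender or other external variables that
  shift SRM effects are not modelled, so a deviating Z may reflect a
  demographic mismatch with the norm sample rather than dysfunction.
* Relationship effects include measurement error whenever only one
  indicator per relationship is available.
* The tool consumes published CFA estimates; it does not fit the SRM to
  raw norm data, and it cannot repair inconsistent published estimates
  (a non-PSD assembled covariance stops the analysis rather than being
  silently projected to the nearest PSD matrix).
* Results are a screening aid, not a clinical verdict; values should be
  corroborated by other assessment methods.
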