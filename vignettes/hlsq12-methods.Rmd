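---
title: "Scoring and validating the HLS19-Q12: models, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and validating the HLS19-Q12: models, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlsq12)
library(dplyr)
```

## The instrument and its data model

The HLS19-Q12 is a 12-item short form measuring general health literacy.
Conceptually it spans a 3 x 4 matrix — three domains of health-related
tasks (health care, disease prevention, health promotion) crossed with four
stages of handling health information (access, understand, appraise,
apply) — with one item per cell. Respondents rate how easy each task feels
on a four-point scale: 1 "very difficult", 2 "difficult", 3 "easy",
4 "very easy". `hls_instrument()` carries this definition; all analysis
functions take an ordinary data frame whose item columns are named after
the instrument ids, plus optional covariates (`sex`, `age`, `education` in
ISCED levels 0–8, `status` 1–10, `findep` 1–4, `health` 1–5, `mode`) and a
post-stratification `weight`.

Two conventions are fixed here because the field data's coding book is not
public. First, any item entry outside 1..4 — blanks, "don't know" codes —
is treated as missing, and `validate_responses()` counts and reports each
conversion. Second, `median_split()` assigns persons exactly at the median
to the *low* group; some tie rule must be fixed for the split-based
diagnostics to be reproducible, and this one keeps the low group weakly
larger. Weights are carried as given and never renormalised; each analysis
decides whether to use them (descriptives and validity regressions do, the
likelihood-based item response analyses do not, matching the usual practice
of the reference IRT software).

## Scores and levels

The **type D score** dichotomizes implicitly: it is the percentage of a
person's validly answered items rated "easy" or "very easy". The **type P
score** rescales the polytomous sum linearly to 0–100: for complete
responses \( 100(\sum_i x_i - 12)/36 \). Both scores are computed only when
at least 80% of the items have valid responses (10 of 12); otherwise the
score is missing. For incomplete rows above that threshold the type P score
uses the mean of the valid codes, \(100(\bar{x}-1)/3\), which coincides
with the sum formula on complete rows — the sum formula alone is undefined
there.

Levels (`excellent`, `sufficient`, `problematic`, `inadequate`; the union
of the last two is *limited* health literacy) are assigned by two rule
sets. The type P rules are score thresholds: excellent > 83.33, sufficient
(66.67, 83.33], problematic (50, 66.67], inadequate <= 50. The type D rules
are *not* a function of the score: they read the response-category
percentages among valid items —

* excellent: "very easy" >= 50% **and** "difficult" + "very difficult" < 8.334%;
* sufficient: "easy" + "very easy" > 83.33%;
* inadequate: "very easy" < 8.334% **and** "difficult" + "very difficult" >= 50%;
* problematic: everyone else,

evaluated in that order. Three choices deserve explanation:

1. **Printed decimals, not exact fractions.** The thresholds are applied
   literally as 83.33 and 8.334. This is deliberate: 10/12 = 83.333% must
   qualify as sufficient (the rule's own gloss is "at least 10 of the 12
   items"), and 1/12 = 8.333% must stay under the "very easy" ceiling for
   inadequate ("one task at the most"). Exact-fraction thresholds would
   break both glosses.
2. **Precedence.** The excellent and sufficient conditions genuinely
   overlap (all-"very easy" satisfies both); excellent is evaluated first.
   The enumeration test over all 455 complete category-count profiles
   confirms that excellent/inadequate and sufficient/inadequate never
   overlap, so the order matters only for the benign overlap.
3. **Denominators under missingness.** Category percentages use the number
   of *valid* items, mirroring the type D score's denominator. Whether the
   original procedure divided by 12 or by the valid count for incomplete
   rows is not documented; over-valid-items keeps the score and level
   consistent with each other.

A consequence worth knowing: two persons with the same type D score can
receive different levels (6 "easy" + 6 "difficult" is inadequate-adjacent
at D = 50, while 6 "very easy" + 6 "difficult" is problematic). This is by
construction, not a bug, and is asserted in the test suite.

## Classical psychometrics

`cronbach_alpha()` is the standard lower bound on internal consistency
(listwise complete cases, sample variances). `polychoric_matrix()`
implements the two-step latent-normal estimator: thresholds from the
inverse-normal of the cumulative category margins, then per-pair maximum
likelihood for the bivariate-normal correlation over the contingency-table
cell probabilities (pairwise-complete observations, correlations capped at
|0.999| so degenerate tables cannot push the optimiser onto the boundary).
On dichotomized items the same machinery yields tetrachorics.
`ordinal_alpha()` applies the standardized-alpha formula to the latent
matrix.

`cfa_single_factor()` fits the one-factor model \(r_{ij} \approx \lambda_i
\lambda_j\) by weighted least squares on the unique correlations — unit
weights (ULS) or inverse approximate asymptotic variances
\(n/(1-r_{ij}^2)^2\) (DWLS, the default). SRMSR is the root mean squared
residual correlation and is exact; the test statistic used for RMSEA, CFI
and TLI is the weighted discrepancy treated as a mean-scaled chi-square
against the zero-correlation baseline. This approximates the full
mean-and-variance-adjusted statistic of categorical-data CFA software, so
those three indices can differ from reference implementations in the
second decimal; all automated checks on them are therefore band-based
(SRMSR <= 0.08, RMSEA <= 0.06, CFI/TLI >= 0.95), never value-matching.

## Item response models

All estimation is written in this package, in plain R.

**Partial Credit Model (MML).** `fit_pcm_mml()` runs an EM algorithm with
Gauss–Hermite quadrature. The node locations are fixed (31 nodes by
default); the normal latent distribution enters through node weights, with
mean fixed at 0 and sd estimated — a fixed-support EM, so the marginal
log-likelihood is non-decreasing at every iteration (asserted in tests).
Item M-steps are 3 x 3 Newton updates with analytic gradients and
Hessians; the sd M-step is a one-dimensional maximisation of the expected
node-occupancy likelihood, carried out in log space so extreme nodes whose
weights underflow cannot poison the objective. Convergence is declared when
the largest parameter change falls below 1e-5 (at most 500 iterations).
Missing responses drop out of the person's likelihood factor. Items with
unobserved categories are collapsed onto their observed ones with a
warning. Standard errors are outer-product-of-gradient (BHHH) estimates.

**Rasch model (CML).** `fit_rm_cml()` maximises the conditional likelihood
given the raw scores, using elementary symmetric functions computed by the
summation algorithm (`esf()`); persons with extreme scores contribute
nothing, persons with distinct missingness patterns form separate blocks.
Difficulties are reported sum-to-zero; their covariance is mapped through
the normalisation so Wald comparisons across subgroup fits are coherent.
Estimation requires well-conditioned data in Fischer's sense;
`well_conditioned_check()` tests it via strong connectivity of the item
digraph (edge i → j when someone solved i but not j) and, on failure,
returns a violating partition read off a sink strongly-connected component.

**Person estimates.** `estimate_persons()` provides Warm's weighted
likelihood estimate (finite for extreme patterns; the score equation gets
the \(I'/2I\) bias-correction term) and the EAP (posterior mean under the
fitted normal). EAP posteriors are far narrower than the latent
distribution, so they are integrated on a finer fixed grid (201 nodes)
than the EM uses; the suite checks agreement with dense-grid integration
to 1e-4. The induced reliabilities are \(1 -
\overline{SE^2}/\mathrm{var}(\hat\theta)\) (WLE) and
\(\mathrm{var}(\hat\theta)/(\mathrm{var}(\hat\theta) +
\overline{\mathrm{var}_{post}})\) (EAP).

**Nominal Categories Model.** `fit_nrm()` frees one slope and intercept
per category (first category anchored, latent sd fixed at 1) and flags an
item's categories as ordered when the estimated slopes increase strictly.
Categories endorsed by fewer than 1% of respondents make this check
unstable, and the item is flagged accordingly rather than trusted.

## The diagnostic battery

All significance decisions in the battery default to alpha = 0.001 — the
level appropriate when dozens of tests run per analysis — while the
descriptive cut-offs are configuration constants: infit outside (0.8, 1.2)
flags an item (with an additional screening note at 1.3), SRMSR 0.08
(0.05 conservative), 5% for the PCA/t-test proportion.

* **Infit** (`infit_stats()`): information-weighted mean-square residual
  with conditional moments at the WLE estimates, t-standardised via
  Wilson–Hilferty. Computing the moments at estimated rather than true
  abilities biases the statistic slightly below 1 for a 12-item
  instrument; the null band used in tests (0.85–1.15) accounts for that,
  and the contrast with constructed misfit (a random-category item
  exceeds 1.2) is what the statistic is for.
* **Q3 family** (`q3_family()`): correlations of standardised residuals;
  aQ3 centres Q3 at the pair mean, MADaQ3 averages |aQ3|. Per-pair
  p-values use a Fisher-z approximation with Holm correction — documented
  as approximate, since the centred statistic is not exactly a
  correlation coefficient.
* **SRMSR** (`srmsr_irt()`): observed versus model-implied item-score
  correlations, the latter integrated over the estimated latent
  distribution on the quadrature grid.
* **PCA/t-test** (`pca_ttest_unidim()`): items split by the sign of their
  residual loading on the first principal component (zero loadings join
  the positive set); per-person WLE estimates from the two subsets are
  compared with \(|t| > 1.96\) (a normal approximation — the procedure's
  description does not fix degrees of freedom), and the proportion of
  significant comparisons is judged against 5% directly or via the lower
  bound of its Agresti–Coull interval.
* **Andersen LR / Wald z / graphical test** (dichotomous): conditional
  LR tests across split criteria (median score, median age, sex,
  education), per-item Wald comparisons of subgroup difficulties under a
  common normalisation, and the subgroup-difficulty scatter with 95%
  radii plus empirical-versus-model ICC data.
* **Facets DIF** (`dif_facets_pcm()`): the PCM extended with an item x
  group interaction (double sum-to-zero; group ability differences are
  absorbed by group-specific latent means), estimated by the same
  fixed-grid EM. Wald standard errors come from the curvature of the
  profile marginal log-likelihood in each interaction parameter — cheap,
  and adequate for flagging at alpha = 0.001.
* **Global local-independence test**
  (`global_local_independence_rm()`): under the Rasch model, conditional
  on both margins every binary matrix is equally likely, so the null
  ensemble is sampled by margin-preserving checkerboard swaps. Burn-in
  and thinning default to 10x and 1x the number of matrix cells — far
  more than the fixed counts that are sometimes quoted, because a chain
  that has not forgotten the observed matrix makes the test
  anti-conservative (the observed statistic is then compared against
  samples clustered around their own mean).

The battery can be replicated on disjoint random subsamples
(`random_subsamples()`), mirroring the practice of re-running item-level
analyses in independent splits of large surveys.

## The synthetic respondent generator

No public data exist for this instrument family, so `simulate_hls()` is a
first-class module, not a test fixture. It draws covariates, builds the
latent trait with a social gradient on the standardized covariates
(defaults: education +0.20, status +0.25, financial deprivation −0.30, age
−0.10, sex −0.05; residual sd set so the marginal trait sd is 1), and
draws responses from the exact PCM kernel. Default item locations run from
−2.1 to −0.3 logits with step spread 1.1, chosen once so the per-item
share of "difficult"/"very difficult" answers spans roughly 8–42% — the
band general-population surveys with this instrument report. Special-HL
scores are generated at target correlations 0.45–0.55 with the trait
(inside the 0.4–0.7 discriminant-validity band); self-perceived health is
an ordinal cut of a latent index with a negative trait coefficient (higher
literacy, better health). The gradient magnitudes themselves are
calibration choices — the source literature reports no effect sizes — and
are documented here once rather than revisited.

Violations are injectable and off by default: DIF as a sum-to-zero step
offset for one group; local dependence as stochastic response copying with
probability kappa (which produces controllable positive residual
correlation); extreme response style as a person-specific symmetric shift
of the two outer steps (inflating both extreme categories without moving
the trait — exactly the phenomenon the type D score is meant to
attenuate); missingness as MCAR masking applied *after* generation, so
changing the missing rate never changes the underlying draws under the
same seed. Because the style shift acts on the generating kernel it is
applied inside the category draw; copying and masking follow it, in that
order.

What the generator does not emulate: country-specific sampling designs,
mode effects beyond a label, non-ignorable missingness, and translation
effects. Tests passing on this population therefore certify the
*machinery* — estimators recover what generated the data, diagnostics
alarm when and only when a violation is present — not any claim about a
particular national survey.

## Validity analyses

`weighted_ols()` minimises the weighted residual sum of squares with
listwise deletion, reports unstandardized b, standardized beta via
weighted sds, and the weighted R²; predictors enter as numeric, sex coded
female = 1. `concurrent_validity_models()` runs the two standard models
(score on the five determinants; health on score plus determinants) for
either score type. `discriminant_check()` flags weighted correlations with
the special-HL scores against the (0.4, 0.7) band.
`shortform_representation()` correlates long-form and embedded short-form
scores, overall and per subdimension. No survey-design variance correction
is applied — no design information exists for synthetic data — so standard
errors are model-based and inferential claims are not the point of these
functions.

## Problem sizes and numerical settings

The test suite and the acceptance script run the estimators at the sizes a
single desk machine handles comfortably while keeping sampling error well
inside the asserted bands: n = 2000 for parameter recovery and the
diagnostic calibrations (400 replications at n = 900 for the Andersen-LR
type-I check), n = 5000 for regression sign/order recovery, 21–31
quadrature nodes. EM tolerance is 1e-5, polychoric ML is bracketed at
|rho| <= 0.999, and all Monte-Carlo procedures take explicit seeds.

## Known limitations

* CFA fit indices beyond SRMSR are approximations (documented above).
* The facets DIF Wald errors use profile curvature, not the full
  information matrix; they are slightly optimistic, which is immaterial at
  alpha = 0.001 with the effect sizes of interest.
* Infit at estimated abilities is mildly biased downward; cut-off-based
  flagging is unaffected.
* The aQ3 p-values are Fisher-z approximations.
* The generator's covariates are sampled independently; real populations
  correlate education with status and deprivation, which would inflate
  collinearity in the validity regressions relative to what is tested
  here.
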