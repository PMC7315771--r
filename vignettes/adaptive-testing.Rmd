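---
title: "Adaptive testing from polytomous item banks: models, screening and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive testing from polytomous item banks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradedCAT)
```

# The measurement model

gradedCAT works with ordinal questionnaire items scored $0,\dots,m-1$ and a
single latent severity trait $\theta$, scaled to mean 0 and SD 1 in the
calibration population. Its default model is Samejima's graded response
model (GRM): item $j$ with discrimination $a_j > 0$ and strictly ordered
thresholds $b_{j1} < \dots < b_{j,m-1}$ has cumulative response curves

$$P^*_{jk}(\theta) = \frac{1}{1 + e^{-a_j(\theta - b_{jk})}},\qquad
P_{jk}(\theta) = P^*_{jk}(\theta) - P^*_{j,k+1}(\theta),$$

with $P^*_{j0} = 1$ and $P^*_{jm} = 0$. The logistic is used without the
historical 1.7 scaling constant: discriminations in the 0.8–2.2 range, as
in the packaged bank, are typical of unscaled-logistic estimates, and the
adaptive algorithm is invariant to the convention as long as bank and
engine agree. Two comparison models are implemented with the same
interface: the generalized partial credit model (item slope plus step
difficulties, adjacent-category logits) and the nominal response model
(per-category slopes and intercepts, the first category anchored at zero
for identifiability).

Fisher information of a polytomous item is

$$I_j(\theta) = \sum_k \frac{\left(\partial P_{jk}/\partial\theta\right)^2}{P_{jk}(\theta)},$$

computed from analytic derivatives per model (and cross-checked in the
test suite against central differences at $10^{-6}$ tolerance). Test
information is the item sum, and the two precision transforms the package
reports everywhere are $SE(\theta) = 1/\sqrt{I(\theta)}$ and, on the
unit-variance scale, $r_{xx}(\theta) = 1 - 1/I(\theta)$; they satisfy
$r = 1 - SE^2$ identically. Information below 1 yields a negative
reliability; the value is returned as-is with a warning rather than
truncated, since truncation would hide a genuinely uninformative test.

# Calibration

`fitMmlEm()` estimates item parameters by marginal maximum likelihood
with a fixed-quadrature EM scheme. The latent trait is integrated over
81 equally spaced nodes on $[-4, 4]$ carrying renormalized standard
Normal weights — fine enough that doubling the node count moves EAP
scores by well under 0.01 on the packaged bank (asserted in the tests),
and consistent with the mean-0/SD-1 scale convention. The E-step
computes each person's posterior mass at every node in log space; the
M-step maximizes each item's expected complete-data log-likelihood by
BFGS (`stats::optim`) on an unconstrained working scale: log slope for
GRM/GPCM, and log threshold *gaps* for the GRM so threshold order holds
by construction instead of by post-hoc re-sorting. The working scale is
clamped (slope $e^{-9}$–$e^{5}$, gaps at least $e^{-12}$) so optimizer
exploration cannot collapse a gap to zero. Because each M-step starts
from the current parameters and only accepts improvements, the marginal
log-likelihood is non-decreasing across cycles; the suite asserts this on
every fit. Convergence is declared at relative log-likelihood change
below $10^{-7}$ or maximum parameter change below $10^{-4}$, with a
500-cycle cap; non-convergence is reported in the result, not thrown.

Missing responses contribute nothing to the likelihood (missing at
random), matching the upstream listwise-deletion preprocessing. Model
comparison (`compareModels()`) fits GRM, GPCM and NRM on identical data
and quadrature and reports $AIC = -2\ell + 2p$ and
$BIC = -2\ell + p\ln N$. When the two criteria disagree the package
selects by BIC and warns: BIC's stronger parsimony penalty is the
conventional arbiter, and the disagreement case is rare enough that a
silent choice would be worse than a visible one.

# Item screening

`runQcPipeline()` reproduces the conventional bank-construction order —
unidimensionality, calibration, item fit, DIF, discrimination — each
stage consuming the previous stage's survivors.

**Unidimensionality.** The inter-item correlation matrix (Pearson on the
raw ordinal codes by default) is eigendecomposed; first-factor loadings
are the leading eigenvector scaled by $\sqrt{\lambda_1}$. Items with
$|loading| < 0.30$ are dropped and the analysis repeated once (screen,
then confirm). The screen passes when $\lambda_1/\lambda_2 \ge 3$ and the
first factor explains at least 20% of total variance. Pearson on raw
codes attenuates latent correlations for coarse scales, so a two-step
polychoric estimate (margin thresholds by inverse-Normal, pairwise
$\rho$ by maximizing the bivariate-Normal cell likelihood with
quadrature) is available via `cor_method = "polychoric"`; it is not the
default because it is $O(p^2)$ numerical integrations and the decision
thresholds were conventionally tuned to Pearson practice.

**Item fit.** `itemFitSX2()` implements the summed-score (Orlando–
Thissen) chi-square for polytomous items: the recursive summed-score
algorithm gives the model-implied conditional category distribution of
each item given the total score, compared with observed frequencies.
Adjacent total-score groups are merged from the extremes inward until
every expected cell reaches 1, and degrees of freedom subtract the
item's parameter count — which presumes the bank was calibrated on these
responses. The suite's null simulations therefore refit before testing;
with known (unestimated) parameters the df convention over-rejects.
Items with $p < 0.05$ are flagged.

**DIF.** Differential item functioning is tested per item by nested
proportional-odds models conditioned on the EAP trait estimate:
`response ~ theta` versus `response ~ theta + group + theta:group`, with
effect size the change in McFadden's pseudo-$R^2$. The flagging
threshold defaults to 0.02, the established boundary below which DIF is
considered negligible; it is configurable. (A threshold of 0.2 — an
order of magnitude larger — would flag essentially nothing anywhere and
would make the "delete items showing DIF" rule vacuous, so 0.02 is the
reading that makes the screen meaningful.) The conditioning estimates
are recomputed from the surviving bank after any removal.

**Discrimination.** Items with $a < 0.8$ are dropped (inclusive floor at
0.8): below that slope an item contributes so little information that
the adaptive selector would never choose it, so it only pads the bank.

# The adaptive engine

A CAT session (`runCAT()`) proceeds: draw a random first item; then
repeat — record the response, update the trait estimate, update the
precision, check the stopping conditions, otherwise administer the most
informative remaining item.

* **Scoring.** Expected a posteriori: posterior mean over the same
  81-node grid, standard Normal prior, likelihoods accumulated in log
  space. With no responses the estimate is the prior mean, so the first
  item of every session is selected (randomly) rather than tailored.
* **Selection.** Maximum Fisher information at the current estimate;
  ties break deterministically to the lowest bank index. For all-GRM
  banks the per-item information vector is evaluated by a vectorized
  padded-array routine (tested equal to the generic per-item path at
  $10^{-12}$).
* **Stopping.** The monitored precision is the information-based
  standard error $1/\sqrt{\sum_{administered} I_j(\hat\theta)}$ — the
  quantity the reliability formulas above are defined on — not the EAP
  posterior SD, which is also recorded per step for diagnostics. The
  check runs only after each response, so the minimum test length is 1,
  and stopping is immediate: no item is given once SE drops below the
  threshold. A test-length cap (default 20 under any SE rule) and bank
  exhaustion are the other two stop reasons; exhaustion takes precedence
  in the bookkeeping when both coincide.
* **Randomness.** Only the first item is random. It is drawn under a
  dedicated seeded RNG whose state is saved and restored, so respondent
  simulation and administration are independent reproducible streams.

# Synthetic respondents and the simulation study

`generateRespondents()` draws $\theta \sim$ Normal(0, 1) — the scale the
bank is calibrated on — and samples complete response vectors by inverse
CDF from each item's category distribution. The generator emulates
model-consistent responding only: no carelessness, response styles,
local dependence, response times or model misfit. Passing simulation
tests therefore demonstrates the algorithmic chain (generation,
calibration, screening, adaptive administration, evaluation) is correct
under the model, not that any real cohort will match the numbers; with
real data the same post-hoc machinery applies unchanged via
`runStudy(responseMatrix, ...)`.

`runStudy()` replays the CAT against each respondent's complete vector
(post-hoc design, so adaptive and full-bank scores share response
realizations), under each stopping rule, and tabulates mean/SD items
used, mean final SE, marginal reliability and the Pearson correlation
with full-bank EAP scores. Marginal reliability aggregates as
$1 - \mathrm{mean}(SE^2)$, the unit-variance-scale form consistent with
the per-person identity; the "mean SE" column averages SE itself, not
$SE^2$. Each respondent's first-item seed derives from the study seed
and the respondent's id (not their row position), which yields three
useful invariants, all asserted in the tests: summaries are invariant to
respondent ordering; trajectories are reproducible; and a looser SE
threshold stops at a prefix of a stricter rule's item sequence, so items
used are per-person monotone in the threshold. The default study size,
1000 respondents against the packaged 68-item bank under rules none /
0.3 / 0.4 / 0.5, runs in well under a minute and gives Monte-Carlo error
on mean items used of about 0.08.

# Screening evaluation

`screeningMetrics()` computes sensitivity, specificity and the Youden
index at an inclusive cutpoint, and AUC by the rank (Mann–Whitney)
formulation with ties counted one half — tested against exhaustive pair
counting and `wilcox.test`. `classifyByCriterion()` dichotomizes a
criterion-questionnaire total at an inclusive cutoff (default 75, a
conventional case threshold for the criterion scale the packaged bank
was validated against). `optimalCutpoint()` maximizes Youden over the
observed scores with ties to the lowest cutpoint. `diagnosisCurve()`
fits a logistic regression of diagnosis on the test score and pairs it
with empirical percentile ranks, the two ingredients of a
score-interpretation chart; logistic is the default curve because the
fitted object is interpretable (the score at probability one half is
$-\beta_0/\beta_1$) and monotone by construction.

# Degenerate inputs and numerical guards

Category probabilities are floored at $10^{-300}$ inside logs;
posterior underflow raises an explicit error rather than returning NaN.
Items observed in a single category refuse calibration by name. Constant
items make the EFA correlation matrix singular and are reported by name.
S-X² tables too sparse to test yield df 0 and a missing p-value with a
warning, not a flag. Respondents with missing answers in post-hoc CAT
cause the item to be skipped in selection with a warning. Bounded
grids clip extreme trait estimates at $\pm 4$; simulated respondents
beyond the grid still generate valid responses but are scored at the
boundary.

# Known limitations

Unidimensional models only — no testlet, bifactor or multidimensional
extensions; no exposure control or content balancing in the selector
(the source design uses none); no standard errors on calibrated item
parameters; polychoric EFA is pairwise-ML, not full-information; the
criterion-validity and sensitivity/specificity numbers of any particular
published instrument depend on that study's real cohort and criterion
scores, which are not reproducible from a synthetic population — only
their computation machinery and orderings are testable here.
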