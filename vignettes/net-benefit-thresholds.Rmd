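---
title: "Net-benefit decision thresholds: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Net-benefit decision thresholds: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbthreshold)
```

## The decision problem

A probabilistic classifier for screening emits a score $s_i \in [0,1]$ per
subject; acting on it requires a threshold $t$, with $s_i \ge t$ read as
"pathology". In population screening the positive class is rare (about 2.9%
in large mammography programmes) and the asymmetry of error costs is
extreme: a missed cancer (FN) is far costlier than a recall (FP). Threshold
rules that optimize *balance* — the Youden index
$J(t) = Se(t) + Sp(t) - 1$, or the point nearest the $(0,1)$ ROC corner —
ignore that asymmetry. Decision-curve analysis encodes it through the
threshold probability $p_t = L/(L+P)$ and the net benefit
$NB(p_t) = TP/n - FP/n \cdot p_t/(1-p_t)$, but requires explicit losses
$L$ and profits $P$, which are rarely available for an AI service.

## The NetBenefit0/NetBenefit1 construction

This package's central object splits the confusion matrix into its two
complementary halves and scores each with the odds weight
$w(p) = p/(1-p)$:

$$NB_0(t) = \frac{TP(t)}{n} - \frac{TN(t)}{n}\,w(p_0), \qquad
  NB_1(t) = \frac{FP(t)}{n} - \frac{FN(t)}{n}\,w(p_1).$$

$NB_0$ aggregates the correct recognitions, $NB_1$ the two error types.
Both are swept over one common threshold axis, and the chosen operating
point $t^\*$ is the $x$-coordinate of their intersection: below $t^\*$ the
error curve dominates, above it the penalty on correct-negative mass
dominates, and the crossing is read as the point of maximum overall
benefit.

**The $p_0 = p_1 = t$ reading.** The weight probabilities could in
principle be fixed externally from a loss profile (both are accepted as
arguments, `p0` and `p1`, and then held constant along the sweep). The
package's default ties both to the sweep threshold itself, for two reasons:
no loss profile needs to be specified, and the two curves then live on one
axis, which is what makes "the" intersection well defined. This is a design
choice, not a mathematical necessity, and it has a consequence worth
stating precisely.

**When does an intersection exist?** Write $\Delta(t) = TP(t) - FP(t)$,
$m = N_{neg} - N_{pos}$, and $w = t/(1-t)$. Using
$TN - FN = \Delta + m$,

$$n\,[NB_0(t) - NB_1(t)] = \Delta(t)\,(1 - w(t)) - w(t)\,m.$$

Since $\Delta \le N_{pos}$, a root with $t < 1/2$ requires
$t/(1-2t) < N_{pos}/m$ — i.e. roughly $t$ below the prevalence when the
pathology class is rare — and for $t > 1/2$ both terms are negative
whenever $\Delta > 0$. Hence **for raw counts no intersection exists on
heavily imbalanced cohorts** (at 2.9% prevalence, for any realistic
classifier); crossings appear once the classes are not far from balance,
and the first crossing then sits well below the Youden point, which is what
gives the method its sensitivity-favouring character. The selector
therefore raises an explicit "no intersection" error rather than
extrapolating.

**Equal-class weighting.** For rare-pathology cohorts the package offers
`weights = "balanced"`: each class's counts are rescaled to half the cohort
($TP \to \tfrac{n}{2}\,Se$, $TN \to \tfrac{n}{2}\,Sp$, etc.), the
deterministic analogue of subsampling to equal class sizes. Then $m = 0$,
the difference reduces to $\Delta(t)(1-w)/n$, and the crossing is pinned at
$t^\* = 1/2$ whenever $J(1/2) > 0$ — a degenerate but well-defined rule.
Reported metrics are always evaluated on the *full* cohort regardless of
the weighting used to find the threshold. Balancing is off by default: it
changes the question being asked, and the analysis above makes its effect
transparent.

## Numerical choices

* **Decision rule.** `score >= t` is positive, so $t = 0$ is the
  all-positive corner and every observed score is an attainable cut-off; a
  strict `>` variant is a switch. Published evaluations rarely state which
  convention they use; with continuous scores the two differ only on tied
  values.
* **Candidate thresholds.** ROC sweeps use the unique observed scores plus
  an `Inf` sentinel — exact on finite data. Net-benefit curves use 1,001
  evenly spaced points on $[0, 0.999]$ united with the cohort's unique
  scores; $\varepsilon = 10^{-3}$ keeps clear of the $w(t)$ singularity at
  $t = 1$, where both curves diverge to $-\infty$ for non-empty classes.
* **Root finding.** Counts are step functions, so $D = NB_0 - NB_1$ is
  piecewise smooth with jumps at observed scores. Crossings are strict sign
  changes between consecutive non-zero grid values (an exact zero flanked
  by opposite signs is itself a root; plateaus of zeros at the tails, which
  occur when both classes saturate, are not). The root is linearly
  interpolated inside its bracketing interval; since the grid contains
  every observed score, no count change can hide inside a bracket.
* **Multiple crossings.** All are reported; the smallest-$t$ one is
  returned (most sensitivity-preserving) with a warning. Sampling noise in
  the score tails can produce a spurious high-$t$ crossing, which this rule
  also sidesteps.
* **Tie-breaks.** Among equal criterion values the selectors prefer the
  highest sensitivity, then the smallest threshold — deterministic and
  screening-oriented. AUC is the trapezoidal area, identical to
  Mann–Whitney pair counting with half credit for ties.
* **McNemar.** Exact two-sided binomial on $(b, b+c, 1/2)$ when
  $b + c < 25$, else continuity-corrected
  $\chi^2 = (\max(0, |b-c|-1))^2/(b+c)$ with 1 df; $b+c = 0$ gives $p = 1$.
  Both variants are callable explicitly; the suite verifies they agree to
  within 0.01 at the boundary for moderate $|b-c|$.
* **Reporting.** Report tables round metrics to 2 decimals (full precision
  is kept in the selection objects); cross-model aggregates print whole
  percents with round-half-away-from-zero; p-values display at 4
  significant figures with a "< 0.0001" floor. No multiplicity correction
  is applied, and the report states how many tests it ran.
* **Degenerate inputs.** Undefined ratios (a cohort with one class) yield
  `NaN` plus a warning in metrics, and documented errors in ROC/selector
  code. BI-RADS 0 records are excluded with an exclusion count attached to
  the cohort, never silently dropped; missing or out-of-range scores are
  hard errors, never imputed.

## The synthetic generator

`generate_cohort()` draws labels Bernoulli(prevalence) (or fixes the count
exactly), then class-conditional scores, under one seed in a fixed draw
order; the ambient RNG state is restored afterwards. The
`binormal_logistic` model draws a latent Gaussian per class and maps it
through `plogis`; the map is monotone, so the ROC is that of the binormal
model and the analytic AUC
$\Phi\!\big((\mu_1-\mu_0)/\sqrt{\sigma_0^2+\sigma_1^2}\big)$ stays exact —
which is what lets tests check the generator against closed forms. A
`beta_pair` model is available for score distributions with mass near the
boundaries.

`preset_service_profiles()` provides three regimes calibrated once, under
equal variances, through the published (Youden threshold, Se, Sp) operating
points of three commercial mammography AI services: latent Youden point
$x_y = \mathrm{qlogis}(t_y)$, $\mu_1 = x_y + \Phi^{-1}(Se)$,
$\mu_0 = x_y - \Phi^{-1}(Sp)$, at 2.9% prevalence (analytic AUCs 0.77,
0.79, 0.87). They emulate operating regimes — overlap, score location,
rarity — not the services themselves: real AI scores are not
logit-Gaussian, exhibit calibration drift across versions, and the
published points do not identify a distribution (indeed the third service's
published rows are mutually inconsistent with any fixed score distribution:
its specificity would have to fall as the threshold rises). Passing tests
on these cohorts therefore demonstrates correctness of the machinery and
the direction of the Youden-vs-net-benefit trade-off, not clinical
performance of any product.

## Validation problem sizes

The test suite checks: selector-vs-exhaustive-search equivalence on 100
random cohorts of up to 200 records; AUC against pair counting and against
an independent ROC implementation; net-benefit boundary identities
($NB_0(0)$ = prevalence, $NB_1(0)$ = 1 − prevalence) and root bracketing;
the intersection against a $10^5$-point brute-force root on fixed-seed
cohorts of 20,000 records; McNemar branches against binomial-sum and
closed-form oracles; generator AUC convergence and Youden-threshold
recovery (within 0.02 of the analytic optimum) at $10^5$ records; and the
directional property — higher sensitivity, lower specificity, significant
McNemar difference at the intersection versus the Youden point — across
seeds on near-balanced validation cohorts, where the intersection exists
for raw counts.

## Known limitations

* Under the common-axis reading the intersection does not exist for raw
  counts at screening prevalence (derivation above); under equal-class
  weighting it exists but degenerates to $t^\* = 1/2$. The
  sensitivity-favouring behaviour of the rule is therefore demonstrated on
  near-balanced cohorts; on rare-pathology cohorts the fixed-sensitivity
  selector is the transparent alternative, and fixed `p0`/`p1` from an
  explicit loss profile are accepted for users who have one.
* No confidence intervals on ROC, AUC or net-benefit curves are provided.
* With cohorts of tens of thousands of records McNemar p-values saturate
  below $10^{-4}$ for any non-trivial disagreement; effect sizes (the
  Se/Sp differences) carry the practical meaning, and the reports print
  both.
* One score and one label per record is assumed; collapsing multi-view or
  multi-breast studies to a per-patient score is upstream of this package,
  as is any image handling or report NLP.
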