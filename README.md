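# nbthreshold

Decision-threshold selection and paired evaluation for probabilistic binary
classifiers in screening settings with strong class imbalance — the typical
situation of an AI reader in population mammography, where roughly 3% of
examinations carry a pathology and a missed cancer is far costlier than a
false alarm.

## The problem and the method

A classifier that outputs a "pathology probability" in [0, 1] still needs a
decision threshold *t* before it can act. The classical choices optimize
balance: the **Youden index** J(t) = Se(t) + Sp(t) − 1, the point closest to
the (0, 1) corner of the ROC curve, or a fixed sensitivity floor.
Decision-curve analysis instead scores a threshold probability
p<sub>t</sub> = L/(L+P) (losses from treating the healthy over profits from
treating the sick) with the **net benefit**

    NB(p_t) = TP/n − FP/n · p_t/(1 − p_t).

This package implements all of those, plus a net-benefit *curve pair* built
from the two complementary halves of the confusion matrix, with weight
w(p) = p/(1−p):

    NetBenefit0(t) = TP(t)/n − TN(t)/n · w(p0)     (correct recognitions)
    NetBenefit1(t) = FP(t)/n − FN(t)/n · w(p1)     (the two error types)

Both curves are swept over a common threshold axis (by default
p0 = p1 = t), and the **intersection** of NetBenefit0 and NetBenefit1 is
taken as the operating threshold: the point where the balance tips between
rewarding correct classifications and penalizing errors. On cohorts where
the intersection exists it sits *below* the Youden point, so it trades
specificity for sensitivity — the direction screening wants.

Two facts about this construction are worth knowing up front (derivation in
the methods vignette):

* With raw counts, NB0(t) − NB1(t) = [(TP−FP)(1−w) − w(N₀−N₁)]/n, so an
  intersection can only exist when the classes are not far from balance.
  For rare-pathology cohorts the package supports an equal-class weighting
  (`weights = "balanced"`), under which the crossing is pinned at t = 1/2.
* Counts are step functions of t, so the root is located by a strict sign
  change on the grid and refined by linear interpolation — reproducible
  bit-for-bit, no iterative solver.

The evaluation harness compares strategies the way multi-reader screening
studies do: per-strategy confusion matrices and Se/Sp/Acc against ground
truth, McNemar paired tests (exact binomial below 25 discordant pairs,
continuity-corrected χ² above), and cross-model mean/min/max aggregates. A
seedable synthetic-cohort generator (binormal-logistic or Beta score models,
2.9% default prevalence presets) makes everything testable without clinical
data.

## Worked example

```r
library(nbthreshold)

spec <- synthetic_spec(20000, prevalence = 0.45,
                       params = list(mu0 = -1.25, mu1 = 1.25,
                                     sigma0 = 1, sigma1 = 1), seed = 1)
coh <- generate_cohort(spec)
compare_strategies(coh)
```

```
Warning message:
multiple NB0/NB1 crossings at t = 0.1145, 0.433; returning the smallest

Strategy comparison on 20000 records (prevalence 0.4485)
        strategy threshold  se   sp  acc
          youden    0.4940 0.9 0.89 0.90
 nb_intersection    0.1145 1.0 0.21 0.57
  youden vs ground truth: p < 0.0001
  nb_intersection vs ground truth: p < 0.0001
  nb_intersection vs youden (reference): p < 0.0001
  (3 McNemar tests performed; no multiplicity correction applied)
```

The Youden threshold (0.49) balances sensitivity and specificity at 0.90;
the net-benefit intersection (0.11) pushes sensitivity to 1.00 at the price
of specificity, and the McNemar test confirms the two strategies classify
significantly differently. `plot_roc_curve()` and `plot_nb_curves()` draw
the corresponding figures; `run_simulate()` / `run_analyze()` /
`run_summarize()` (or the `inst/cli/nbthreshold.R` script) wrap the same
pipeline for the shell.

The package also ships, under `inst/extdata/`, the published per-service
operating points of three commercial mammography AI services (seven service
versions, 663,606 screening examinations): at their Youden thresholds mean
sensitivity is 64% with mean specificity 80%; at the net-benefit
intersection thresholds mean sensitivity rises to 87% (max 99%) while mean
specificity falls to 49% (min 48%).

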