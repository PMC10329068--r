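---
title: "Methods: graded-response CAT for the AAQ item bank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graded-response CAT for the AAQ item bank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaqcat)
```

## The measurement model

The Animated Activity Questionnaire (AAQ) is a 17-item, almost non-verbal
measure of activity limitation for people with hip or knee osteoarthritis:
each item shows short animations of an avatar performing a daily activity and
the respondent picks the one matching their own performance. Responses are
ordered category codes `1..m` (m = 4, 5 or 6 per item), higher categories
meaning more limitation.

`aaqcat` models these responses with Samejima's graded response model (GRM).
For item $i$ with slope $a_i > 0$ and strictly ordered thresholds
$b_{i1} < \dots < b_{i,m-1}$, the cumulative response curves are logistic in
the latent trait $\theta$:

$$P^*_{ik}(\theta) = \frac{1}{1 + e^{-a_i(\theta - b_{ik})}},
\qquad P_{ik}(\theta) = P^*_{i,k-1}(\theta) - P^*_{ik}(\theta),$$

with $P^*_{i0} = 1$ and $P^*_{im} = 0$. The logistic metric is used without
the historical 1.7 scaling constant, matching the parameterization of the
software family in which banks like the bundled one are usually calibrated;
the bundled slopes (1.29–3.45) are on this metric. The latent trait is
anchored to a standard normal distribution — mean 0, SD 1 in the calibration
population, higher $\theta$ meaning more limitation.

Two reporting metrics sit on top of $\theta$. The *original* score is the
linear 0–100 transform of the raw sum score $s \in [S_{\min}, S_{\max}]$
(17 to 85 for the AAQ), reversed so that 100 means no limitation:
$100\,(S_{\max} - s)/(S_{\max} - S_{\min})$. The model never prints this
formula's provenance anywhere because it is the only linear map that sends
the all-lowest pattern to 100 and the all-highest to 0, which is how the
instrument's published score range behaves. The *model-based* score maps an
estimated $\theta$ through the test characteristic curve
$E[S\,|\,\theta] = \sum_i \sum_k k\,P_{ik}(\theta)$ (strictly increasing)
and then the same 0–100 transform, so both metrics are directly comparable.

## Scoring: EAP on a fixed quadrature

All person scoring is expected a posteriori (EAP): the posterior mean of
$\theta$ under the N(0,1) prior, with the posterior SD as the standard
error. Posteriors are evaluated on a fixed grid of equally spaced nodes with
normal-density weights.

The default grid is **61 nodes on $[-6, 6]$**. The bounds matter more than
the node count: the all-highest response pattern has its posterior mean near
$\theta = 4.1$, so a grid truncated at $+4$ (a common CAT-engine default)
clips that posterior and inflates the extreme score by more than a scale
point — with the wide grid the two extreme full patterns score 98.6 and 2.3
on the 0–100 metric, reproducing the published score-range endpoints of the
full measure. An internal check against ten-times-finer integration keeps
the discretization error of the default grid below $10^{-3}$ in both
$\hat\theta$ and its SE (equally spaced rules are spectrally accurate for
integrands that decay like a Gaussian). With no responses the posterior
equals the prior ($\hat\theta = 0$, SE $= 1.00$ up to grid truncation).

EAP is the only estimator offered — interim and final, adaptive and
non-adaptive — which keeps CAT trajectories and full-bank scores on exactly
the same scale.

## Calibration: MML by EM

`grm()` estimates banks by marginal maximum likelihood. The E-step computes
each respondent's posterior over the quadrature nodes; the M-step refits
each item against its expected category-by-node counts by quasi-Newton
(BFGS) search on an unconstrained parameterization — log slope, first
threshold, log threshold spacings — so threshold ordering holds by
construction rather than by projection. Convergence is declared when no
parameter moves by more than `tol` ($10^{-4}$ by default) in a cycle, with a
500-cycle cap; the marginal log-likelihood trace is retained and is
non-decreasing (each M-step fully optimizes its item, so the procedure is an
ECM). Missing responses are ignorable: they drop out of the likelihood.
Identification comes from the fixed N(0,1) prior; no post-hoc rescaling to
the sample is applied, so externally supplied parameter tables remain
directly usable. Every category of every item must be observed at least
once — otherwise `collapse_categories()` first, then refit, which is also
the intended workflow when the modal-category diagnostic reports disordered
thresholds (on model-simulated data, trait estimates before and after a
top-category collapse correlate above 0.999).

On three-binary-item toy data the EM solution matches an independent direct
maximization of the marginal likelihood (adaptive quadrature over the eight
response patterns) to about $2 \times 10^{-5}$; simulating 2000 respondents
from the bundled bank and recalibrating recovers slopes and central
thresholds ($|b| < 3$) with RMSE well under 0.1.

## Adaptive administration

A CAT session starts at $\hat\theta = 0$ (the prior mean), repeatedly
selects the unadministered item with maximum Fisher information

$$I_i(\theta) = \sum_k \frac{P_{ik}'(\theta)^2}{P_{ik}(\theta)}, \qquad
P_{ik}' = a_i\!\left[P^*_{i,k-1}(1 - P^*_{i,k-1}) - P^*_{ik}(1 - P^*_{ik})\right],$$

(ties broken by bank order), elicits the response, re-estimates $\theta$ by
EAP on the administered items, and checks the stopping rule *after* each
response: stop when SE $\le 0.3$ (once `min_items` is reached), when the
item cap is hit, or when the bank is exhausted. The studied configurations
are caps of 17, 10 and 5 items at the 0.3 threshold. No minimum test length
is enforced (`min_items = 1`): with this bank the SE criterion cannot be met
in fewer than four items, so the observed minimum of 4 emerges rather than
being imposed. No exposure control or content balancing is applied; the
agreement between all CAT versions and full-bank scores is the empirical
justification.

Post-hoc simulation replays this loop against stored complete patterns.
Simulee mode draws a complete pattern from the GRM at a true $\theta$ when
the provider is constructed (seeded) and then replays it, so both modes
share one code path and post-hoc determinism is exact.

## The validation battery

The assumption checks operate on raw response matrices and a calibrated
bank:

* **Mokken scalability / monotonicity.** Pairwise
  $H_{ij} = \mathrm{cov}(X_i, X_j)/\mathrm{cov}_{\max}(X_i, X_j)$ with the
  maximum taken over couplings preserving both margins (the comonotonic
  coupling, equivalently sorting both margins and pairing). Monotonicity
  counts decreases of item-step proportions across rest-score groups
  (default group size $n/10$ capped at 50, decreases under 0.03 ignored).
  Group-level sampling noise at size-50 groups makes small violation counts
  common even for model-consistent data; the scale-level criterion is
  $H > 0.50$.
* **Local independence.** Q3-style residual correlations
  $e_{ri} = x_{ri} - E[X_i \mid \hat\theta_r]$ with full-pattern EAP
  matching, flagged at $|r| > 0.20$. This replaces factor-analytic residual
  correlations with an IRT-native proxy probing the same concern.
* **Item fit (S-X²).** Orlando–Thissen: observed versus model-predicted
  item-category frequencies conditional on the raw summed score, with the
  conditional predictions built from the generalized Lord–Wingersky
  recursion over the remaining items. Adjacent score groups are merged
  until every expected cell reaches 1 and at least 80% reach 5; sparse
  categories pool into neighbors. Degrees of freedom are independent cells
  (cells minus score groups) minus the item's parameter count — appropriate
  when the bank was estimated from the same data; with *known* true
  parameters this df is conservative by construction and the statistic
  mildly over-rejects, which is why the package's own size check simulates
  the full calibrate-then-test pipeline. The misfit flag is $p < 0.003$
  (Bonferroni-style for 17 items).
* **DIF.** Per item, nested proportional-odds models (`MASS::polr`):
  response on matching $\theta$ alone versus adding group and
  group-by-$\theta$ terms; effect size is McFadden's pseudo-$R^2$ change
  against the intercept-only model, flagged at 2%. Matching uses the
  single-pass full-bank EAP without iterative purification — deterministic,
  and sufficient for the flag criterion, but expect slightly diluted effect
  sizes when a large fraction of items has DIF.
* **Disordered thresholds.** A category that is never modal anywhere on
  $\theta \in [-6, 6]$ (0.01 steps) indicates thresholds spaced more
  tightly than the item's discrimination can separate. On the bundled bank
  this flags four items (AAQ_02, AAQ_03, AAQ_04, AAQ_17), matching the
  count reported for the instrument, though the published detection was a
  visual check of category curves and need not coincide item-for-item.

## The synthetic cohort

`generate_cohort()` draws $n$ true traits from N(0,1) — the latent
calibration of the bank — and complete response patterns from the GRM. The
default $n = 1408$ matches the size of the calibration study, so simulated
test-length and agreement statistics are comparable in magnitude to the
published ones. What the generator does *not* emulate: the real sample's
skew (original scores averaged 78/100, i.e. a less-limited population than
N(0,1) implies at the item locations), country/language structure,
real-item misfit, and missingness. Passing simulation checks therefore
demonstrates internal consistency of the engine under its own model, not
field validity; the published real-data quantities (external criterion
correlations, factor-analytic fit) are out of scope here. Conditional
test-length and precision profiles bin respondents by estimated-score
deciles; with a skewed real sample those profiles would shift along the
score axis.

Problem sizes used by the test suite and the reproduction script — 1408
respondents for cohort-level checks, 2000 for parameter recovery, 8
replicates for the item-fit size study — were chosen as the smallest sizes
at which the corresponding statistics are stable to well within their
tolerance bands.

## Numerical choices and edge cases

* Probabilities underflowing to exactly zero in deep tails contribute zero
  to information sums rather than NaN.
* `simulate_responses` clamps the top cumulative probability to 1 so
  rounding cannot generate an out-of-range category.
* Threshold ordering in calibration is enforced by the log-spacing
  parameterization; starting values come from marginal cumulative
  proportions with a minimum spacing of 0.05.
* MFI ties (exactly equal information) resolve to the earlier bank
  position, making sessions fully deterministic.
* A stopping-rule boundary effect is worth knowing: respondents whose trait
  sits exactly where test information crosses the SE-rule equivalent
  ($I \approx 1/0.3^2 - 1$, counting the prior) can end a capped session a
  hair above the threshold; cohort-level checks of the "information covers
  the rule" property should expect a small boundary fraction rather than
  exact universality.

## Known limitations

* The bundled parameters are printed to three decimals; quantities computed
  from them inherit that rounding. The minimum test information over
  $\theta \in [-1, 4]$ evaluates to 9.33 (at $\theta = 4$), slightly under
  the round "10 between $-1$ and 4" reliability reading commonly quoted for
  the instrument from its information plot.
* One-factor GRM only: no multidimensionality, no guessing, no
  partial-credit or nominal variants.
* DIF handles one binary contrast per scan; multi-group comparisons are
  sequential.
* The engine administers items; it does not render the instrument's
  animations or manage data collection.
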