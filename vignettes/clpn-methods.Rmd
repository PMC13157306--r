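---
title: "Methods: cross-lagged panel networks for Internet use and depressive symptoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-lagged panel networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`clpnet` estimates a cross-lagged panel network (CLPN) over `p = 15` items
measured on the same participants at two waves: ten CES-D depressive-symptom
items (`De1`–`De10`, ordinal 0–3) and five Internet-use-purpose indicators
(`In1`–`In5`, binary). Each wave-2 item is regressed on *all* wave-1 items
with an L1-penalized (LASSO) linear model on standardized variables:

$$ z_j^{(2)} = \sum_{i=1}^{p} \beta_{ij}\, z_i^{(1)} + \varepsilon_j, \qquad
\hat\beta_{\cdot j} = \arg\min_\beta \tfrac{1}{2n}\lVert z_j^{(2)} - Z^{(1)}\beta\rVert^2
 + \lambda_j \lVert\beta\rVert_1 . $$

The fifteen fitted coefficient vectors form the columns of a directed
adjacency matrix `B`, with `B[i, j]` the standardized effect of item `i` at
wave 1 on item `j` at wave 2. The diagonal collects autoregressive effects
(an item predicting itself), the off-diagonal the cross-lagged effects the
analysis is about. Because every regression conditions on all wave-1 items,
an edge expresses a *unique* temporal association, not a marginal
correlation.

Assumptions worth keeping in mind: linearity on the standardized coded
scale (binary and ordinal items enter the same Gaussian-loss family, which
is what makes the fifteen regressions comparable on one matrix); two waves
only, so no attempt to separate stable between-person differences from
within-person change; and missingness that is ignorable given the observed
items (MAR).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 1 | elastic-net mixing; 1 is the pure LASSO, values < 1 add an L2 share |
| `k` | 10 | cross-validation folds for selecting each outcome's `lambda_j` |
| lambda grid | 100 values | log-spaced from `lambda_max` (smallest penalty nulling all coefficients) down to `0.001 lambda_max` |
| selection rule | CV-minimum | `lambda_j` minimizes the k-fold mean squared prediction error (no one-standard-error rule) |
| `m`, `iterations` | 5, 10 | imputed datasets and chained-equation sweeps per chain |
| `display_threshold` | 0.05 | minimum `abs(beta)` for an edge to be drawn; a visualization device only |
| CS settings | grid 0.05–0.75, r ≥ 0.7, prob 0.95 | case-dropping stability convention |
| bootstrap `B` | 1000 | replicates (tests and examples use 200–500 for speed) |

Fold assignments are plain random splits, drawn independently per outcome
from the master seed. The per-outcome `lambda_j` are recorded in the
network object and echoed into the run manifest.

## Imputation and pooling

Missing responses are multiply imputed by chained equations, written in the
package: every item column of both waves (plus complete covariates) enters
each conditional model; columns are visited in order of increasing
missingness; ordinal items use predictive-mean matching with five donors
(proportional odds optional via `ordinal_method = "polr"`), binary items a
logistic draw with a PMM fallback when the fit degenerates (the sub-1%
purpose indicators can separate). The PMM variant matches on OLS
predictions without a Bayesian parameter draw; between-chain variability
comes from random initialization and donor sampling. Since only the point
estimate of the network is of interest, the `m` per-imputation networks are
combined by the element-wise mean (the point-estimation step of Rubin's
rules); no between-imputation variance is propagated, deliberately.
Covariates deemed MCAR (by default `education`) are handled by listwise
deletion before imputation rather than imputed.

## Centrality

Three expected-influence indices summarize each node of the signed,
*unfiltered* pooled network (the display threshold never feeds analysis):

* **Out-EI**: sum of a node's outgoing cross-lagged edges — its capacity to
  predict other items two years on.
* **In-EI**: sum of incoming edges — how predictable the item is from the
  earlier state of the system.
* **Bridge-EI**: sum of *outgoing* edges that cross between the internet
  and depressive communities. The outgoing direction was chosen because
  bridge influence in temporal networks is usually read as a node's effect
  on the other construct; the incoming variant is available via
  `direction = "in"`.

All indices ignore the autoregressive diagonal. They are implemented as
ordered element-wise accumulation, so results are bit-reproducible and
testable against brute-force loops with zero tolerance.

## Stability

* **CS-coefficient** (case-dropping bootstrap): subsamples without
  replacement at drop proportions 0.05–0.75; CS is the largest proportion
  at which 95% of replicates still correlate at least 0.7 with the
  full-sample centralities. The `B` replicates are allocated evenly across
  the grid, so total cost is ~`B` network re-estimations regardless of grid
  size. Note a mechanical floor: at a 5% drop the subsample shares 95% of
  its cases with the full sample, so even structureless data can clear the
  first one or two grid steps; "unstable" therefore shows up as CS near 0,
  not exactly 0, and interpretation should use the conventional 0.25 / 0.5
  benchmarks.
* **Edge CIs**: nonparametric bootstrap over participants, percentile
  intervals (not bias-corrected — the simplest convention consistent with
  percentile reporting). Re-imputation inside replicates is not performed:
  replicates resample a completed dataset, keeping desk-scale runtime.
* **Difference tests**: for each pair of edges or centralities, the
  percentile interval of the bootstrap distribution of their difference;
  significant when it excludes zero.

Degenerate cases follow explicit conventions: if both the subsample and
full-sample centrality vectors are constant the correlation counts as 1 (a
constant estimator is perfectly stable); if exactly one is constant it
counts as 0; a subsample on which estimation fails (e.g. a rare purpose
item with no endorsements left) is redrawn up to five times and otherwise
counts against stability.

## The synthetic generator

Real data of this kind (a two-wave survey of ~9,000 older adults) are
access-restricted, so the package carries a generative twin used by every
test. It is linear-Gaussian in a latent layer with threshold observation:
wave-1 latents are `N(0, Sigma1)` with exchangeable within-community
correlation (0.35 among depressive, 0.30 among internet items, 0.05
across); wave-2 latents follow `t(B_true) z1` plus Gaussian noise with
residual SDs calibrated so every wave-2 latent has unit variance (which
lets one set of thresholds serve both waves); observed codes arise by
cutting each latent at per-item thresholds. This design keeps latent
correlations analytically checkable — with identity `Sigma1`,
`cor(z1_i, z2_j) = B_true[i, j]` exactly — while reproducing the mixed
binary/ordinal measurement.

Default calibration encodes the study conditions: endorsement rates per
item and wave match the published frequency table of the cohort (purposes
between 0.5% and 15%, depressive items 21–69%, reverse-worded items
complemented onto the scored scale); cross-lagged effects are sparse
(default 12 nonzeros) with magnitudes 0.05–0.20, so the largest planted
effects sit near 0.19 like the strongest reported edges; autoregressive
effects draw from 0.15–0.35; missingness is MAR for depressive items
(rates spanning 0.10–0.27, driven by a shared logistic function of age and
education so their missingness indicators correlate) and independent at
0.10 for purpose items. The `charls_like` preset uses n = 9290; the `desk`
preset n = 5000. Small-n fixtures override the purpose endorsements to
10–15% (`endorsement` argument), because at n = 500 a 0.5% item is expected
to have fewer than three endorsements and the column degenerates.

What the generator does *not* emulate: survey weights and sampling design,
attrition between waves, the joint distribution of purpose endorsements
across waves (only per-wave margins are matched), and any nonlinearity in
the true dynamics. Passing tests therefore demonstrate correct recovery of
a linear latent process observed through thresholds — not that real panel
data satisfy those assumptions.

A known measurement consequence shows up in recovery experiments: an
indicator endorsed by 0.5% of the sample carries a correlation of only
about 0.2 with its own latent variable, so latent effects of 0.15–0.30
attenuate to observed-scale effects of 0.03–0.06. The LASSO occasionally
zeroes such edges even at n = 5000; recovery rates in the mid-90s rather
than 100% are expected behavior on rare binary items, which is why
recovery is assessed pooled over replicate datasets.

## Numerical choices

* The penalized fits run a covariance-update coordinate descent (compiled)
  on the Gram sufficient statistics `X'X/n`, `X'y/n`, with warm starts down
  the lambda path, convergence at max coordinate change < 1e-9, and CV
  statistics obtained by fold-Gram subtraction. For p = 15 this makes one
  network estimate ~0.1 s, which is what keeps hundreds of bootstrap
  re-estimations tractable; the path agrees with glmnet to ~1e-6 (checked
  in the test suite) and collapses to the closed-form OLS and
  soft-threshold solutions at the boundary cases.
* Ties in the CV curve resolve to the larger (sparser) lambda at machine
  precision.
* Standardization uses the sample SD (divisor n − 1); a zero-variance
  column is an error naming the degenerate node, not a silent drop.
* Imputed codes are returned as integers; observed cells are never
  modified (asserted cell-wise in tests).
* All randomness derives from one master seed through tagged substreams;
  seeded internals save and restore the RNG state, so an enclosing
  bootstrap's draws do not depend on how many times the estimator ran.

## Open design points, resolved

* The literature describes the penalty both as elastic net and as the
  standard LASSO; the default is `alpha = 1` with the mixing parameter
  exposed.
* Whether the reverse-worded CES-D items (5, 8) enter the network raw or
  reverse-scored is ambiguous in the field; the default reverse-scores
  them so every depressive node points in the depression direction, with
  `use_reverse = FALSE` to switch. The choice only flips the signs of the
  affected rows and columns.
* Demographic covariates are not network nodes and are excluded from the
  regressions by default, consistent with a 15 × 15 matrix.
* Problem sizes used by the automated checks — n = 2000–10000 for
  regression properties, B = 200 case-dropping and B = 500 edge-bootstrap
  replicates — were chosen as the smallest scales at which the respective
  Monte-Carlo errors are negligible relative to the assertions.

## Limitations

Two waves cannot identify within-person dynamics separately from stable
confounding; edges are predictive, not causal. The Gaussian loss on rare
binary outcomes is a linear-probability approximation whose coefficients
attenuate with endorsement rate, so cross-item comparisons of edge
magnitude involving the rarest purposes understate latent associations.
CS-coefficients inherit the granularity of the drop grid (0.05). The
chained-equation imputation assumes MAR given the 30 item columns and
covariates; MNAR sensitivity analysis is out of scope.
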