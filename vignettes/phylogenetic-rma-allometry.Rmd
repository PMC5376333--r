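---
title: "Phylogenetic RMA allometry: models, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic RMA allometry: models, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylorma)
```

## The problem

How do the dimensions of reproductive anatomy scale with body size across a
clade?  For cetaceans, the traits of interest are vaginal length (VL),
cumulative vaginal fold length (VFL, the summed lengths of the transverse
protrusions of the vaginal wall into the lumen), and total body length (BL).
On log10 axes an allometric relation `log y = log a + b log x` is a straight
line whose slope `b` is the scaling exponent: for two linear measurements,
isometry predicts `b = 1`, and a significantly larger exponent (positive
allometry) means the trait grows disproportionately with body size.

Two statistical complications shape the package. First, both axes are
measured traits, so ordinary least squares — which assumes an error-free
predictor — systematically flattens the slope; the reduced major axis (RMA,
also called standardized major axis) line, whose slope is the ratio of the
two standard deviations, treats the axes symmetrically.  Second, species are
not independent samples: closely related species resemble each other because
they share evolutionary history.  The package therefore fits the RMA line
from *evolutionary* variances and covariances estimated on a phylogeny,
with the strength of phylogenetic correlation itself estimated from the
data via Pagel's lambda.

## The model

Let `C` be the n-by-n phylogenetic covariance matrix of the n species under
Brownian motion: entry (i, j) is the branch length shared by the root-to-tip
paths of species i and j, and the diagonal holds root-to-tip distances
(`vcv_matrix()`).  Pagel's lambda rescales the off-diagonal entries,
`C(lambda) = lambda * C` off the diagonal with the diagonal kept
(`lambda_transform()`): lambda = 1 is full Brownian covariance, lambda = 0
is phylogenetic independence.  The search domain is fixed to [0, 1]; values
above 1 have no interpretation on this scale and can destroy positive
definiteness.

Given the two log10 traits as columns of an n-by-2 matrix `X`, the model is
matrix-normal: `vec(X)` is Gaussian with mean `1 * a` and covariance
`R (x) C(lambda)` (Kronecker product), where `a` is the pair of GLS
phylogenetic means (`gls_mean()`, the generalized-least-squares root-state
estimate `(1'C^-1 1)^-1 1'C^-1 X`) and `R` is the 2-by-2 evolutionary rate
matrix.  Profiling `R` out at its ML value `R_ML = E'C^-1 E / n` (with `E`
the residuals from the GLS means) gives the log-likelihood implemented in
`profile_loglik()`:

    l(lambda) = -1/2 [ n m log(2 pi) + n log|R_ML| + m log|C(lambda)| + n m ]

with m = 2 traits.  `estimate_lambda()` maximizes this over [0, 1].

From the fitted quantities, the RMA line is

* slope: `beta1 = sign(R_xy) * sqrt(R_yy / R_xx)`
* intercept: `beta0 = a_y - beta1 * a_x`
* squared evolutionary correlation: `r2 = R_xy^2 / (R_xx R_yy)`

(`rma_line()`).  Slope, intercept, and `r2` do not depend on the divisor
used for `R`; the implementation uses n - 1.

Inference on the slope uses the standard SMA machinery on the log scale:

* Isometry test (`slope_test()`): `T = |ln beta1 - ln h| / sqrt((1 - r2)/df)`
  against a t distribution, two-sided, with `h` the predicted exponent.
* Confidence interval (`slope_ci()`): with
  `B = F(1 - alpha; 1, df) (1 - r2)/df`, the bounds are
  `beta1 (sqrt(B + 1) -/+ sqrt(B))`; the interval always contains `beta1`
  and its endpoints multiply to `beta1^2`.
* Phylogenetic signal (`lambda_lrt()`): `Delta = 2 (l(lambda_hat) - l(0))`
  against chi-squared with 1 df.

`phyl_rma()` orchestrates all of the above and returns the full result
bundle; `run_study()` chains the data pipeline and the three regressions of
the study design (VL on BL, VFL on BL, and fold-length residuals on
vaginal-length residuals).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `h` | 1 | predicted exponent; 1 is isometry for length-on-length |
| `lambda` | estimated | fix Pagel's lambda instead of ML estimation |
| `df` | `"n-2"` | degrees of freedom for slope test and CI; also `"n-1"`, `"clarke"`, or a number |
| `alpha` | 0.05 | CI level (95%) |
| `r2_ss` | `"ordinary"` | sums of squares for R2; `"gls"` weights by `C^-1` |
| `units` | `"mm"` | convert all lengths to mm before log10; `"native"` keeps cm for body and vaginal length |
| `residual_method` | `"rma"` | non-phylogenetic line producing the residuals for the third regression; also `"ols"` |
| `boundary_lrt` | `FALSE` | 50:50 chi2(0)/chi2(1) mixture reference for the lambda LRT |

Three of these deserve comment, because the underlying methodological
choice is genuinely open:

**Degrees of freedom.**  The classical SMA slope test uses n - 2.  Widely
used phylogenetic RMA software instead refers the statistic to Clarke's
(1980) approximation `df = 2 + (n - 2)/(1 + r2/2)` while keeping n - 2
inside the statistic; `df = "clarke"` reproduces that behavior exactly
(verified against phytools in the test suite).  The default stays at the
classical n - 2; results report n and df so readers can tell which
convention produced them.

**R-squared.**  `R2 = 1 - SS_res / SS_tot` is reported for the RMA line's
vertical residuals.  Because an RMA line does not minimize vertical
residuals, this value can be negative, and it is generally lower than the
squared evolutionary correlation also reported.  Whether the sums of squares
should be phylogenetically weighted is a convention choice; both are
available (`r2_ss`), ordinary is the default.

**Residual method.**  The third regression first removes body size from
both traits using a *non-phylogenetic* line.  The package defaults to an RMA
line for those residuals, consistent with the RMA philosophy used
throughout; OLS is selectable, in which case the residuals average exactly
zero.

**Units.**  Intercepts of log-log fits depend on measurement units; slopes,
correlations, lambda, and every test statistic do not.  The default converts
all lengths to millimetres before log10 so that the intercepts of the three
regressions share a unit.

## Data cleaning rules

Specimen tables record per-fold length lists in mm.  `clean_folds()`
implements the morphometric protocol:

* a vaginal fold is any fold of at least 0.5 mm — shorter entries are
  measurement noise and are dropped;
* folds of at least 0.5 mm but under 1 mm are rounded up to 1 mm before
  summing into the cumulative fold length;
* only folds of at least 1 mm enter the fold *count* (sub-millimetre folds
  are included in lengths but excluded from counts).

The function is idempotent on its own output, and the loader
(`load_specimens()`) applies it per specimen, warning when a supplied
cumulative value contradicts the fold list by more than 0.5 mm (the list
wins).

## What the synthetic generator emulates

`sim_config()` / `sim_allometric_specimens()` generate data with exactly the
structure the estimator assumes:

* **Tree**: a Yule (pure-birth) tree.  The simulator waits an Exp(k b) time
  while k lineages exist and adds a final Exp(n b) wait after the n-th
  speciation, so the expected depth is `sum_{k=2..n} 1/(b k)` — an identity
  the test suite checks against 1,000 simulated trees.
* **Species means**: log10 body length evolves as lambda-BM around a root
  of 3.4 (about 2.5 m); the responses are `intercept + slope * log10(BL)`
  plus their own lambda-BM deviations.  Default generating values: VL slope
  1.4 and intercept -2.45; VFL slope 2.17 and intercept -5.85 (log10-mm
  scale); lambda 0.7.
* **Rates**: body-size rate 0.05 per unit branch length (spanning roughly an
  order of magnitude of body length across a clade-depth tree, as in
  cetaceans), residual-axis rates 1e-4.  The residual rates are deliberately
  small relative to the size axis: the SMA slope estimates the ratio of
  total standard deviations, which equals the generating exponent only when
  scatter off the allometric axis is negligible.  Keeping the residual rate
  at 0.2% of the size rate makes the generating exponent the population RMA
  slope to within 0.1% and keeps the isometry test at its nominal level,
  which is what the calibration experiments require.
* **Specimens**: 1–5 per species with multiplicative lognormal noise
  (cv = 0.1 by default, mean-one correction applied), mirroring repeated
  carcass measurements; each specimen's cumulative fold length is split
  into 1–7 folds with exponential proportions, and each fold is replaced by
  a sub-millimetre value with probability 0.1 so that the cleaning rules are
  exercised by every generated table.
* **The packaged fixture** (`make_fixture()`): 20 species, 59 specimens,
  fabricated cetacean-like binomials, plus a manifest with the generating
  parameters, recovery tolerances, and file digests.  It is byte-identical
  for a given seed.

What the generator does **not** emulate: the high residual scatter of real
morphometric data (real R2 values near 0.2–0.4 rather than the generator's
~0.95), sampling biases of stranding networks, maturity structure with
allometric consequences, measurement error correlated within observers, and
non-ultrametric trees.  Passing recovery tests on generated data therefore
demonstrates correctness of the estimator under its own assumptions, not
robustness to their violation.

## Numerical choices

* All covariance solves go through Cholesky factorization; a failed
  factorization is reported as a singular-tree problem (duplicated tips or
  zero-length terminal branches), not a cryptic LAPACK error.
* Lambda optimization: a 21-point grid pre-scan locates the basin, Brent
  optimization (tolerance 1e-8) refines it within the bracketing grid
  interval, and both endpoints are evaluated explicitly so boundary maxima
  are exact.
* On a star phylogeny the likelihood does not depend on lambda; the
  estimate is then reported as 0 with `lambda_identifiable = FALSE` rather
  than an arbitrary interior point.
* The LRT statistic is clipped at zero (the optimum can fall a rounding
  error below the lambda = 0 endpoint).
* A zero evolutionary covariance makes the RMA slope sign undefined; the
  positive sign is taken with a warning (log-scale morphometric slopes are
  positive in practice).
* Degenerate inputs (a constant trait, r2 = 1, zero total sum of squares,
  nonpositive values before log10) raise errors or flagged degenerate
  results naming the offending trait or species.

## Problem sizes used by the test suite

The simulation-based checks run at sizes chosen to balance Monte-Carlo
error against runtime: parameter recovery uses 200-tip Yule trees with 200
replicates per lambda value (0, 0.5, 1); the two level-calibration
experiments use 500 replicates at 100 species; CI coverage uses 500
replicates at 50 species; distributional checks on the generator use 2,000
replicates on small fixed trees.  The whole suite completes in about two
minutes on one core.

## Known limitations

* **Lambda is weakly identified in small clades.**  At 20 species the
  sampling distribution of the lambda ML estimate has a standard deviation
  of roughly 0.3 and piles up at both boundaries; the packaged fixture's
  manifest documents a correspondingly wide recovery tolerance.  Slopes, by
  contrast, are recovered sharply at that size.
* **RMA estimates a standard-deviation ratio.**  Under a generative model
  with substantial variance off the allometric axis, the population RMA
  slope exceeds the structural exponent, and the isometry test inherits
  that bias.  This is a property of the method, not of the implementation.
* Only bivariate fits, Brownian-motion-derived correlation structures, and
  lambda in [0, 1] are supported; there is no measurement-error model and
  no OU alternative.
* Non-ultrametric trees are accepted (with a warning) and handled by the
  same formulas, but the equivalence between lambda = 0 and the ordinary
  equal-weight SMA fit holds only for ultrametric trees.
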