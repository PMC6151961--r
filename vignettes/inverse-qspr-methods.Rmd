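---
title: "Inverse QSPR screening with GA-PLS: models, diagnostics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse QSPR screening with GA-PLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsinvert)
```

## The problem

Target-based virtual screening asks: given a regression model that maps a
molecule's descriptors **x** to its drug properties **y**, what descriptor
vector would an *ideal* candidate have, and which molecules in a candidate
library come closest to it?  `plsinvert` implements this workflow for a
two-property model -- chromatographic lipophilicity (log *k*~w~, the
extrapolated retention factor at 0 % organic modifier) and inhibitory
activity (log *K*~i~, *K*~i~ in nM) -- of the kind used for sulphonamide
inhibitors of carbonic anhydrase IX, a hypoxia-associated tumour target.
The pipeline is: descriptor pre-selection, Kennard--Stone splitting,
GA-driven descriptor subset selection with a PLS model inside,
applicability-domain diagnostics, constrained inversion of the fitted
model toward reference property values, and distance-based library
ranking, optionally fused with docking ranks.

## Models and statistics

### Lipophilicity extrapolation

Isocratic retention follows `log k = log kw + S * phi` in the
organic-modifier fraction `phi`; `fit_logkw()` is the ordinary
least-squares line, and log *k*~w~ is its intercept.  Translating gradient
runs into isocratic points is out of scope; the input is a
`retention_series` of (phi, log k) pairs.

### Pre-selection filters

Three filters run in a fixed order (`filter_descriptors()`):

1. **RSD filter** -- descriptors with relative standard deviation
   `100 * sd/|mean|` below 5 % (near-constant) are removed; all-zero
   columns go with them; a zero mean with positive spread leaves RSD
   undefined and the descriptor is kept.  A flag inverts the rule because
   the removal direction is a convention, not a theorem.
2. **Correlation filter** -- for each descriptor pair with |Pearson r| >
   0.8, the member whose best |r| against the two responses is lower is
   dropped; pairs are visited in descending |r|; ties keep the
   earlier column, for determinism.
3. **Zero filter** -- continuous descriptors containing any exact zero are
   removed; binary and integer descriptors are exempt, since zeros are
   legitimate values there.  This reading is the only one under which the
   binary/integer exemption makes sense.

### PLS core

`fit_pls()` is NIPALS PLS2 on autoscaled X and Y, deflating X only.  The
inner loop (w from the Y-side latent vector, scores t = Ew, Y-loadings c)
is a power iteration whose fixed point is the dominant eigenvector of the
2 x 2 matrix (E'Y)'(E'Y); we solve that eigenproblem exactly instead of
iterating, which is algebraically the same component but immune to the
slow convergence of power iterations when the two eigenvalues nearly tie.
Scores are mutually orthogonal; at full rank predictions coincide with
ordinary least squares (a test asserts this to 1e-8).  The model stores
`Rstar = W (P'W)^-1` so that scores of new compounds are `t = Rstar' x`,
plus the training-score covariance **S** needed by the T^2 constraint of
the inversion.  The number of components A is chosen by 7-fold
cross-validation (`cross_validate()`): seeded shuffle, contiguous blocks,
per-A root-mean-square CV error summed over the two responses, smallest A
on ties.  Fold construction is not prescribed by any convention we could
adopt verbatim, so the seeded-shuffle design was chosen for
reproducibility.

Error metrics (`pls_metrics()`): RMSEE/RMSEP are
`sqrt(mean((pred - obsd)^2))` per response; MRE is
`100 * mean(|pred - obsd| / |obsd|)`, with observed zeros excluded (with a
warning) because the ratio is undefined there.

### GA descriptor selection

`run_ga()` evolves binary membership chromosomes over the filtered pool.
The fitness of a subset (size `n_S`) pools estimation and prediction
errors per response,

\[
\eta_j = \sqrt{\frac{(n_T - n_S - 1)\,\mathrm{RMSEE}_j^2 +
  n_P\,\mathrm{RMSEP}_j^2}{n_T + n_P - n_S - 1}}, \qquad
\eta = \sqrt{\eta_1^2 + \eta_2^2},
\]

with `n_T` training and `n_P` external-validation compounds; RMSEP is
computed on the external split, matching the degrees-of-freedom weights.
The square roots keep `eta` in property units.  Each evaluated subset gets
its own A by 7-fold CV.  Design choices that depart from a plain textbook
GA, each adopted after the plain version demonstrably stalled on planted
synthetic data:

* **Cardinality by repair, not penalty** -- offspring are repaired by
  random add/drop into `[n_select_min, n_select_max]`, so every evaluated
  subset is feasible.
* **Swap mutation** -- each selected gene is exchanged with a random
  unselected one with probability `mutation_rate`.  A per-gene bit-flip at
  the conventional 0.2 rate flips about p/5 genes per child and destroys
  convergence on pools of dozens to hundreds of descriptors; swaps
  preserve cardinality and give a proper local move.
* **Memetic refinement** (`local_search = TRUE`) -- the final GA subset is
  polished by first-improvement local search over single swaps, drops and
  adds until a local optimum.  Fitness values are cached per subset, so
  the refinement costs only the new evaluations.
* Elitism of 1; tournament selection (size 2) by default; scattered,
  single-point and two-point crossover available; `ga_grid_search()`
  enumerates hyper-parameter grids with per-cell derived seeds.

### Applicability domain

* **Leverage** `h = 1/n + x'(Xc'Xc)^-1 x` in the centered, autoscaled
  training space, with warning threshold `h* = 3(k+1)/n`.  The +1/n
  intercept convention makes training leverages sum to k+1, consistent
  with that threshold.
* **Williams rule**: in-domain means |standardized residual| <= 3 for both
  responses and `h <= h*`; standardized residuals are raw residuals over
  the per-response training RMSEE.
* **Hotelling T^2** `t' S^-1 t` with the F-based limit
  `A(n-1)/(n-A) * F_{1-alpha}(A, n-A)`.
* **DModX** `sqrt(sum(e^2)/(p-A)) / s0` with
  `s0 = sqrt(sum(E_train^2)/((n-A-1)(p-A)))` and critical value
  `sqrt(F_{1-alpha}(p-A, (n-A-1)(p-A)))`.  This is the classical
  F-approximation; commercial implementations apply additional empirical
  degrees-of-freedom corrections, so printed limits from such software
  are treated as reference points, not targets.  Two caveats the tests
  make explicit: the F limits are exact only up to covariance-estimation
  error of order 1/n (the Monte-Carlo checks therefore use n = 200
  training samples), and the PLS residual operator is an *oblique*
  projector, so real off-plane noise exceeds the limit more often than
  alpha (about 7--9 % in our simulations at alpha = 5 %); the coverage
  check simulates residuals in the orthogonal complement of the loading
  space, which is the regime the formula assumes.

### Model inversion

`build_inversion_problem()` + `invert_model()` solve

\[
x^\* = \arg\min\; (\widehat{\log k_w} - \log k_{w,\mathrm{ref}})^2 +
  (\widehat{\log K_i} - \log K_{i,\mathrm{ref}})^2
\]

subject to `t' S^-1 t <= c1` (scores inside the T^2 ellipsoid at
`c1 = t2_critical(A, n, alpha)`), a reconstruction-residual bound
`||x_s - P t||^2 <= c2` with `c2 = s0^2 (p - A) * dmodx_crit(alpha)^2`
(the DModX limit converted to a squared-residual bound through the
training normalization; a flag switches to the unsquared norm, since the
printed notation of such constraints is often ambiguous), box bounds from
the training min/max, and lattice constraints for integer and binary
descriptors.  Scores of a candidate are `t = Rstar' x_s`; reading the
score equation as a projection (rather than a literal left-multiplication
by the p x A loading matrix, which is dimensionally impossible) follows
the latent-variable model-inversion literature.

The solver is a mixed-integer GA: binary tournament selection, scattered
crossover (fraction 0.8), mutation rate 0.2 with a step size that shrinks
over generations, elitism 2, feasibility-first ranking (any feasible
individual beats any infeasible one; infeasible ones are ordered by total
violation).  The initial population contains the training compounds --
every in-domain training compound is feasible by construction, so the
solver never starts from an empty feasible set.  Two refinements:

* an L-BFGS-B polish of the continuous genes from the best feasible
  individual (constraints as quadratic penalties, feasibility re-checked);
* the returned solution is **model-consistent**: the continuous
  coordinates are projected onto the loading plane (`x_s = P t`), which
  leaves scores, predictions and T^2 unchanged and drops the
  reconstruction residual to its minimum.  The objective is flat in
  residual directions, so without this step the solution would carry an
  arbitrary residual component within the c2 ball.

When A is smaller than the number of constrained responses the problem is
rank-deficient and a warning is issued; full null-space enumeration is out
of scope.

### Screening and rank fusion

`screen_library()` filters candidates by leverage admissibility
(`h <= h*`), computes Euclidean distances to x\* in raw descriptor units
(raw units reproduce the worked example's printed distance of 0.044; a
`scaling` argument switches to autoscaled distances), and ranks them
(distance ties broken by ligand id).  Docking input -- either a composite
score or GlideScore/Prime-Energy components combined as
`IFDScore = 1.0 * GlideScore + 0.05 * PrimeEnergy` -- adds a docking rank
and the fused final rank: the arithmetic mean of the two ranks rounded
half up, the only rounding rule consistent with all rows of the bundled
worked example (3.5 -> 4, 8.5 -> 9, ...).

## The synthetic generator

`generate_synthetic()` plants a low-rank latent structure
`X = T P' + E`, `Y = T C' + F` with seeded reproducibility: `latent_dim`
standard-normal scores; `n_informative` descriptors loaded on them; the
remaining descriptors independent noise; a subset of informative columns
dichotomized at the median to emulate binary fingerprint bits (selected
descriptor sets in real campaigns typically contain a few); responses
labelled logkw/logKi.  The default shape (45 compounds, 300 candidate
descriptors, 4 latent factors, noise sd 0.1) mirrors a small sulphonamide
QSPR campaign after pre-filtering.

Two constructions guarantee identifiability, without which recovery tests
measure luck rather than algorithms:

* `P_true` is a randomly rotated harmonic tight frame: orthogonal columns
  (condition number <= 1.5, every latent factor recoverable from the
  informative block) and exactly equal row norms (every informative
  descriptor carries the same signal strength; none degenerates into a
  noise-dominated column after autoscaling).
* `C_true` has orthogonal rows, so both properties are stably determined
  by the scores.

What the generator does *not* emulate: real descriptor distributions
(heavy tails, counts, block correlation), descriptor semantics, non-linear
structure--property relationships, and heteroscedastic measurement error.
Passing recovery tests therefore demonstrate correctness of the
algorithms under the stated latent-variable model, not predictive validity
on real chemistry.

## Test problem sizes and numerical choices

The validation suite uses problem sizes chosen to make the statistical
properties sharp at desk scale: GA recovery uses 45 compounds x 50
descriptors with 5 planted informative descriptors and
`latent_dim = n_informative = 5` -- with fewer latent factors than planted
descriptors any latent-spanning subset predicts equally well and
"contains all planted descriptors" would not be the optimum -- over 20
seeds with a 24 x 12 GA plus refinement.  Inversion round trips use
45 x 8 descriptors with 2 latent factors (two responses then pin both
score directions) over 10 seeds.  Monte-Carlo coverage of the T^2 and
DModX limits uses 10,000 draws against training size 200.  Degenerate
inputs are handled explicitly: zero-variance columns are rejected by
`autoscale()` with the column named; an exactly low-rank training block
(s0 = 0) makes DModX fall back to unnormalized residual distances; NIPALS
stops with an error when the residual X/Y covariance vanishes (or
truncates, inside cross-validation); singular X'X in the leverage falls
back to a pseudo-inverse with a warning.

## Known limitations

* RMSEP inside the GA fitness uses the external validation set, which is
  also the set reported for the final model; a nested split would be
  needed for fully unbiased error quotation.
* The DModX critical value is the plain F-approximation (see above).
* Distances for screening are computed in raw descriptor units by
  default; when descriptor scales differ wildly the `scaling` option is
  the better choice.
* The inversion returns a single model-consistent solution; families of
  equivalent solutions (null spaces beyond the residual directions) are
  flagged only by a warning when A < 2.
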