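---
title: "Multi-matrix variation partitioning: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-matrix variation partitioning: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuvarp)
```

## The problem

Classical variation partitioning asks how much of one community matrix is
explained, uniquely and jointly, by a few predictor matrices.  Communities
rarely come alone: a native assemblage coexists with an alien one, and both
respond to -- and predict -- environment and space.  Cumulative variation
partitioning (CUVARP) treats all four matrices symmetrically.  Each matrix
(natives **H**, aliens **A**, environment **E**, space **S**) is summarised
by ordination scores, each in turn is partitioned against the other three,
and the four partitionings are merged into a single variance-unit diagram:
non-overlap regions are residual (unexplained) variation, overlaps are
shared explained variation, and everything sums to the grand total variance
of the four tables.

This vignette records the statistical conventions the package commits to,
why each was chosen where a choice was open, and what the synthetic
validation data can and cannot certify.

## Components: Gower, PCoA, db-MEM

Community, environment and trait tables mix counts, ordinals, factors and
quantitative variables, so dissimilarity is Gower's coefficient: per column
a normalised difference (quantitative and ordinal: absolute difference over
the column range; factor and binary: 0/1 disagreement), combined as a
weighted mean over the columns comparable for the pair.  Conventions worth
stating explicitly:

* **Ordinals** are treated as integer ranks range-normalised like
  quantitative variables.  The Podani ordinal correction is *not* applied;
  whether other software's Gower variant normalises ordinals identically is
  unknowable from the outside, so the convention is recorded in each
  distance object's metadata rather than guessed around.
* **Missing values** use pairwise deletion with weight renormalisation
  (Gower's original delta).  A pair of rows with no comparable column is a
  hard error, never a silent zero.
* **Counts** passed to Gower are ordinary quantitative columns,
  range-scaled per species.

Principal coordinates use the Gower double-centering
$G = -\tfrac12 J D^2 J$ and keep axes whose eigenvalue exceeds
$10^{-8} \times \max|\lambda|$.  Under this relative tolerance the
"positive" and "non-zero" retention policies coincide: semimetric noise is
dropped either way, and no Lingoes/Cailliez correction is applied by
default.  Eigenvector signs are fixed (largest-magnitude loading positive)
so that runs are reproducible to the byte.  Scores are scaled by
$\sqrt{\lambda}$, which makes score distances reproduce any
Euclidean-embeddable input and weights downstream trace statistics by axis
importance.

Space enters through distance-based Moran eigenvector maps: Euclidean
distances, truncation at threshold $t$, distances beyond $t$ replaced by
$4t$ (the classical db-MEM constant), PCoA, positive axes kept.  The
automatic $t$ is the largest edge of the minimum spanning tree -- the
smallest truncation that keeps the site graph connected, which on a
one-dimensional transect is the maximum nearest-neighbour gap.  Coordinates
are not detrended by default (a flag exists) because detrending is a
modelling decision the analyst should make knowingly.

## RDA, adjusted R² and partial fractions

Redundancy analysis is multivariate least squares of the centred (never
standardised) response on the predictors, via rank-revealing QR: collinear
predictors reduce the effective rank $m$ instead of erroring, which matters
because users feed raw environmental tables, not just orthogonal PCoA
scores.  Explained variance is the trace ratio, and
$$F = \frac{R^2/m}{(1-R^2)/(n-m-q-1)}$$
with $q$ the covariate rank.  Adjusted explained variance uses Ezekiel's
formula $1-(1-R^2)(n-1)/(n-m-1)$ -- the only scale on which partitioning
fractions are additive.  Two commitments follow:

* Partial (conditional) adjusted fractions are **never** obtained by
  plugging $m+q$ into Ezekiel; they are differences of unconditioned
  adjusted R²s (Peres–Neto convention).  This is what makes the 7-fraction
  inclusion–exclusion close exactly, and the package verifies internally
  that unique fractions from partial models agree with the linear-system
  solution to $10^{-12}$.
* Negative adjusted fractions are preserved everywhere except at render
  time, where the diagram layer may floor them with an explicit flag.

## Permutation inference

Monte Carlo tests permute rows of the reduced-model residuals
(Freedman–Lane) and refit; without covariates this is raw-row permutation
of the centred response.  The p-value is $(\#\{F^* \ge F\} + 1)/(n_{perm}+1)$,
with 999 permutations and $\alpha = 0.05$ as defaults.  Restricted schemes
mirror hierarchical field designs: free; within-block; series (a single
uniform cyclic shift per block, mirror optional and off by default, because
a time series has one defensible orbit and reflection is a stronger
assumption); and split-plot, which exchanges whole blocks.  Split-plot
preserves each block's internal order by default -- the conservative
reading of a whole-plot randomisation -- and can additionally cyclic-shift
within blocks (`shiftWithin`) when both levels are deemed exchangeable; the
choice is echoed in every design summary string so logs are
self-describing.  When a design's orbit has no more distinct arrangements
than the requested permutation count, the orbit is enumerated and the
p-value is exact (identity included).

## Forward selection and its double stopping rule

Selection is greedy: at each step every remaining candidate is tested by a
partial permutation test conditioning on the current model, the step's
p-values are FDR-adjusted (Benjamini–Hochberg) *within the step's candidate
set* -- the granularity the multiple-testing correction most defensibly
applies to -- and the largest adjusted-R² gain among passing candidates
enters, ties broken by column order.

The second stopping criterion compares the cumulative adjusted R² with the
adjusted R² of the full all-candidate model.  Implemented literally
("stop strictly above the ceiling"), the rule has a known pathology: with
one strong predictor among noise candidates, the one-variable model's
adjusted R² often *exceeds* the noise-penalised full model's, and the
entire signal would be rejected at step one (the reference implementation
`vegan::ordiR2step` empirically shows the same behaviour).  The package
therefore commits to: (1) the first significant candidate is retained even
when it alone attains the ceiling, and (2) selection stops as soon as the
cumulative adjusted R² *reaches* the ceiling, so a final candidate that
merely reconstructs the full model never enters.  This keeps the guard
against chance accumulation while never letting it veto the signal it
exists to protect.

## The consensus selection of axes

The selection step of the pipeline runs forward selection for every ordered
pair of roles (predictor role's axes against the other role's full score
table) and retains, for each role, the union of axes selected in at least
one analysis where that role served as predictor.  The published procedure
is interactive; this union rule is the package's automated, deterministic
stand-in.  A role whose union is empty falls back to axis 1 with a logged
warning so the reciprocal partitioning always has four non-empty tables --
a weakly predictive component then shows up honestly as a large residual
region rather than crashing the run.  `maxAxes` can cap the candidate set
(leading axes first) to bound cost on wide tables.

## Assembling the diagram

For each role $X$ with total variance $T_X$ (sum of column variances of the
*selected*-axes table, divisor $n-1$; totals are computed on the selected
tables, not the full PCoA tables, because the residual parenthesis of the
method refers to the selected axes):

* singleton region $\{X\}$ = residual fraction of $X$'s partitioning
  $\times\, T_X$;
* region for a subset $T$ with $\ge 2$ members: each member $X \in T$,
  taken as response, contributes its fraction keyed by the *other* members
  of $T$, times $T_X$.  E.g. region $\{H,E\}$ = H's unique-E $\times T_H$
  plus E's unique-H $\times T_E$; the full region $\{H,A,E,S\}$ sums the
  four triple-shared fractions.

Because each response's fractions and residual sum to one, the fifteen
regions sum exactly to the grand total; the package enforces this closure
to $10^{-9}$ and carries negative contributions through unclamped.  This
region mapping is the package's formalisation of a diagram the method
describes only verbally; it reproduces the diagram's stated features
(non-overlap = unexplained; overlaps = shared; regions sum to the grand
total).

The **average** (AVARP) variant replaces the variance-unit sum by the mean,
over a region's member responses, of the fraction of that response's own
total, reported as percent.  Those averages intentionally do not sum to
anything -- they answer "how large is this region for a typical response",
not "how much variance is here" -- so closure is only asserted for the
cumulative variant.  With community-weighted-mean trait tables in place of
the two community matrices this yields the CWM-AVARP diagram; sites where
a community has zero total abundance have no defined CWM and are dropped
with a warning.

## Diversity measures

Shannon entropy uses natural logarithms; Pielou evenness is $H/\ln S$ and
is reported *missing* for monocultures (0/0), never zero.  Rao quadratic
entropy sums $d_{ij} p_i p_j$ over ordered pairs with plain (not squared)
Euclidean distances in trait-PCoA space; the ordered-pair convention makes
the equal-distance closed form $c\,(1-\sum p_i^2)$ exact, which the tests
exploit.  Binary occurrence tables are accepted as 0/1 abundances.

## The synthetic riverscape

The generator emulates the study system the method was built for: a
one-dimensional river transect (20 sites by default), a mixed environment
table (habitat factor R/L/C, Impact 0–7 and Flow 1–5 ordinals, quantitative
distance-to-dam in metres), Poisson count communities (22 native, 6 alien
species), and 11 mixed-type traits.  Latent site scores are built from
*orthonormal variance channels* -- a purely non-spatial environmental
channel, a purely spatial channel and a spatially structured shared
channel -- weighted by the square roots of the designed shares, plus
matched Gaussian noise.  Defaults: native shares (env, space, shared,
noise) = (0.30, 0.20, 0.10, 0.40); alien shares (0.10, 0.05, 0.05, 0.80),
i.e. a doubled noise share, encoding the aliens' weaker dependence on the
measured predictors.  Spatial channels are drawn from the span of the
*leading six* MEM axes: real communities track broad-scale spatial
structure, and a signal smeared over the full fine-scale spectrum would be
undetectable by any axis-wise selection.

Because the channels are exactly orthogonal and unit-variance, the designed
shares are the population R² fractions, and recovery is certified for the
Gaussian latent model: at 200 sites the mean recovered fractions sit within
±0.05 of design over 50 seeds.  The count and binary links distort the
latent scale, so recovery under them is qualitative only.  The generator
does not emulate species interactions, zero inflation beyond the Poisson
link, observation error in the environment, or temporal dynamics -- passing
tests certify the *statistical machinery*, not ecological realism.

## Numerical choices and problem sizes

* Relative eigenvalue tolerance $10^{-8}$; trace-R² clipped into $[0,1]$
  against rounding overshoot; a residualised total below rounding noise is
  reported as "constant response" rather than a garbage ratio.
* All stochastic entry points require an explicit seed; sub-seeds are
  derived deterministically (and kept below $2^{31}$), so identical
  configurations give byte-identical JSON artifacts.
* The test suite exercises the pipeline at 30–100 sites, recovery at 200
  sites over 50 seeds, type-I error at 500 replicates of 199 permutations,
  and forward selection at 100 replicates -- sizes chosen to give tight
  binomial bands while keeping a full run in well under a minute.

## Known limitations

Consensus selection needs tens of sites for useful power (at 30 sites the
FDR-guarded tests rarely pass and roles fall back to axis 1).  The ceiling
semantics above are a documented commitment, not the only defensible one.
The chi-squared comparison of explained-variance classes assumes the
class definition (unique, unique, shared, residual) is meaningful for both
distributions compared; the classes are configurable because the canonical
set is a convention.  Proportional-area rendering of the diagram is
delegated to external Euler renderers via the JSON region spec; the
built-in SVG is a labelled, non-proportional sketch.
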