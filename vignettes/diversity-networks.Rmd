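---
title: "Methods: neural-network estimation of alpha, beta, and gamma diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neural-network estimation of alpha, beta, and gamma diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divnn)
```

This vignette documents the models and procedures implemented in `divnn`,
the assumptions behind them, the choices made where the design was
genuinely open, and the limits of what the test suite demonstrates.

## Diversity labels from vegetation plots

The unit of observation is a vegetation plot: a surveyed area of known
size (typically 50–10,000 m²) with a complete inventory of vascular-plant
species. Species names are compared as normalized strings (trimmed,
whitespace-collapsed, case-folded); taxonomic standardization is assumed
to have happened upstream, and an accepted-name checklist is the only
name authority the package consults.

For a focal plot *j*, the neighbourhood is its *N* nearest plots by
Euclidean distance in equal-area projected metres. Three labels are
derived per plot:

* **alpha** — the cardinality of the focal species set;
* **gamma** — the cardinality of the union of species sets over the focal
  plot *and* its *N* neighbours;
* **beta** — the multiple-site Sørensen dissimilarity
  $\beta_{sor} = \dfrac{A+B}{2\left(\sum_i S_i - S_T\right)+A+B}$, with
  $A=\sum_i \min(b_{ij}, b_{ji})$ and $B=\sum_i \max(b_{ij}, b_{ji})$,
  where the pairs run between each neighbour $i$ and the focal site
  $j=N+1$, $b_{ij}$/$b_{ji}$ count species found only on one side of a
  pair, $S_i$ is the richness of site $i$ (the sum covers all $N+1$
  sites), and $S_T$ is the union richness.

Three of these conventions deserve comment because alternatives exist:

* **The focal site participates in $\sum_i S_i$ and in the union.** Only
  this reading reduces $\beta_{sor}$ with a single neighbour exactly to
  the classical pairwise Sørensen dissimilarity
  $1 - 2a/(S_1+S_2)$, anchoring the index in the familiar family; the
  reduction is asserted by tests against an independent implementation
  (`vegan`'s binary Bray–Curtis).
* **Pairs are neighbour-vs-focal only**, not all pairs among the $N+1$
  sites. The focal-pair form is what the neighbourhood construction
  calls for — it measures differentiation *relative to the focal plot* —
  and is cheaper ($O(N)$ rather than $O(N^2)$ pairs).
* **Gamma includes the focal plot's species.** A neighbourhood richness
  that excluded its own centre would be hard to interpret and could fall
  below alpha; including the focal plot guarantees `gamma >= alpha`,
  which the test suite enforces as an invariant.

The **radius** is the distance to the *N*th neighbour — the smallest
focal-centred circle containing the whole neighbourhood. We use the
focal-centred reading rather than the minimal enclosing circle of the
neighbour point set because the neighbourhood is defined from the focal
plot outward; the radius is exported as a model feature so networks can
learn how gamma grows with the area it is computed over. Distance ties
are broken by ascending plot id so results are fully deterministic.

`beta_sor` is undefined (denominator zero) only when every site is empty;
this is an error. Training plots are expected to hold at least one
species.

## Features

All spatial computation uses a spherical Lambert cylindrical equal-area
projection (radius 6,371,007.2 m, standard parallel −30°). The spherical
form keeps forward and inverse transforms closed-form and makes the
equal-area property exactly testable; continental-scale shape distortion
is irrelevant here because only distances (neighbour search) and areas
(window counts, grid cells) enter the analysis.

The feature table mirrors the standard macroecological predictor stack:

| group | features |
|---|---|
| position | longitude, latitude (projected metres) |
| sampling effort | occurrence records, and distinct species, in a 10 × 10 km window |
| anthropogenic | human footprint |
| topo-climatic | elevation, bio01–bio19 |
| scale | plot size (m²), neighbourhood radius (m) |

`full27` is all of the above; `subset8` keeps position, human footprint,
elevation, bio01, bio12, and the two scale features; `subset6` drops the
coordinates from `subset8` (useful when a model should not be able to
memorize geography).

Occurrence records pass a conservative filter before counting: non-fossil,
human-observation basis, no geospatial issue flags (any flag excludes the
record — the strictest reading), binomial names only (exactly two
whitespace-separated tokens), and an exact normalized match against the
checklist. Window membership is half-open on the maximum edges,
`[c − s/2, c + s/2)`, so tiled windows never double-count a point.
Raster values are nearest-cell (point-in-cell) lookups with no
interpolation, matching the semantics of ~1-km categorical-and-continuous
GIS layers; nodata propagates as `NA`.

Features are min–max rescaled to [0, 1] with parameters fitted on the
**training rows only** and stored with the model. Prediction-grid values
are normalized with the same training parameters — the only choice
consistent with treating the scaler as part of the fitted model — and are
deliberately *not* clipped: values outside [0, 1] signal extrapolation,
and their count is reported (`n_out_of_range`, also logged by the CLI).
A feature constant on the fit rows maps to 0.

Rasters are exchanged as ESRI ASCII grids (plain-text header plus cell
values), the package's raster interchange format; reprojection of
third-party rasters into the equal-area grid is the caller's concern.

## Network architecture and training

Each metric gets its own regression network: fully connected, ReLU hidden
activations, optional dropout after every hidden layer, and a softplus
output $\log(1+e^x)$ that keeps predictions strictly positive without an
upper bound. Labels are rescaled into roughly [0, 1] before training —
alpha × 1/100, gamma × 1/800, beta unchanged — and predictions are
divided by the same factor on the way out.

Training minimizes the mean absolute error of the scaled labels with
minibatches of 40. Aspects the protocol leaves open are fixed as follows
(and recorded in each run's manifest):

* **Optimizer** — Adam with step size 10⁻³ and default moment parameters
  (0.9/0.999), the de-facto standard for small MLP regression;
* **Initialization** — seeded uniform fan-in scaling,
  $W \sim U(\pm 1/\sqrt{n_\text{in}})$, zero biases: simple and fully
  reproducible;
* **Evaluation semantics** — validation loss is computed every epoch with
  dropout disabled (inverted dropout during training, identity at
  evaluation), so a dropout-free model's evaluation equals its training
  forward pass;
* **Determinism** — initialization, batch shuffling, and dropout masks
  all flow from the configuration seed; identical seeds give bitwise
  identical loss curves, which the tests assert.

The 60/20/20 split draws a uniformly seeded permutation and cuts
`floor(0.2 n)` test and validation sets, leaving the remainder (about
60%) for training; 7,896 instances give 1,579/1,579/4,738.

## Model selection, epoch choice, and the production ensemble

The selection grid crosses the three feature sets with four architectures
(30; 30,5; 30,15,5; 30,20,10,5 hidden nodes) and three dropout rates
(0, 0.1, 0.3) — 36 configurations. Each candidate trains with a
per-candidate seed, its weights are snapshotted at the validation-loss
minimum, and the configuration with the lowest test-set MAPE wins. MAPE
(`100 · mean(|pred − truth| / truth)`) is computed on the diversity
scale; it is invariant to the label rescaling since it is ratio-based.
Truth values of exactly zero (possible for beta in fully homogeneous
neighbourhoods) are excluded and counted, because the quantity is
undefined there.

The training epoch for production models is the validation argmin rounded
half-up to the nearest multiple of 50, floored at 50, ties toward the
earlier epoch — a deterministic reading of "round to the nearest 50".
Epoch budgets default to 2,000 for alpha/gamma and 1,000 for beta, which
comfortably bracket typical chosen epochs (hundreds to ~1,700).

The production ensemble retrains the winning configuration on **all**
instances — no split — for exactly the chosen epoch, 50 times with seeds
`base_seed + 1 … base_seed + 50`. Stopping at the chosen epoch, rather
than re-validating, is what transfers the overfitting guard from model
testing to production, where no held-out data remain.

## Gridded prediction and uncertainty

Prediction cells are squares (default 10 km) laid from the extent's
lower-left corner; partial cells are excluded, and an optional land mask
drops centroids without data. Grid features equal site features except
that plot size and radius are constants (defaults 500 m² and 5 km):
because both entered training, the fitted species–area relationship lets
the same ensemble predict at user-chosen scales — with a warning whenever
the requested constants leave the training range, since softplus networks
extrapolate without any guarantee.

Per cell, the ensemble yields the member mean, the **population**
standard deviation (divisor *n*: the 50 members are the entire population
of trained models, not a sample), and the coefficient of variation
CV = sd/mean. Cells with CV strictly greater than the median CV over all
cells of the run are masked as high-uncertainty; ties at the median stay
unmasked, so the retained cells are exactly those "smaller than or at the
median". With all-distinct CVs this masks half the cells. Cells with mean
exactly 0 would make CV undefined; softplus makes this practically
impossible, but such cells are guarded (CV set to 0) and flagged.
Region summaries (e.g. per biome) aggregate unmasked cells only, with the
full per-cell table exported alongside for transparency.

## The synthetic landscape generator

The generator exists so that every stage — labels, features, training,
mapping — can be exercised and tested without external data, on inputs
whose generating process is known. It emulates:

* **environmental rasters** as sums of five random low-frequency
  sinusoids (wavelengths 30–150 km), smooth and spatially autocorrelated
  like bioclimatic layers, rescaled to plausible per-layer ranges;
* **plots** clustered around random centres (Gaussian scatter, sd 2% of
  the extent) with log-uniform areas in 50–10,000 m², matching the
  clustered, size-heterogeneous character of aggregated plot databases;
* **richness** with expectation
  $\mu = 15\,(A/500)^{0.25} e^{s\,(E-0.5)}$ — a power-law species–area
  relationship (exponent 0.25, the canonical island/mainland range) times
  an exponential response to the designated environmental driver $E$
  (bio01, normalized to [0, 1]) with gradient strength $s$ (default 2);
  realized richness is Poisson around $\mu$, truncated to [1, 115];
* **composition** drawn without replacement with probabilities from
  per-species Gaussian spatial kernels, so nearby plots share species and
  beta diversity is neither 0 nor 1;
* **occurrences** placed by rejection sampling against an independent
  smooth field with intensity $\propto e^{b\,f(x,y)}$ (bias $b$, default
  1.5), reproducing the spatially uneven sampling effort of real
  occurrence archives, with a small fraction of fossil, flagged,
  non-binomial, and unmatched-name records to exercise the filter;
* **a checklist** of all pool names plus 10% never-used noise names.

Defaults (400 plots, 400-species pool, 100 × 100 km extent, 1-km rasters,
5,000 occurrences) were chosen once as a realistic desk-scale landscape.
The generator does **not** emulate phylogenetic or trait structure,
observational error in plot inventories, synonym-level name noise, or
realistic covariance among the 21 environmental layers (each is an
independent field). Tests passing on these landscapes therefore
demonstrate that the machinery recovers a known signal under the stated
assumptions — not that any particular accuracy will hold on real data,
where feature collinearity and label noise are harsher.

## Numerical choices and degenerate inputs

* Softplus is evaluated as `max(x, 0) + log1p(exp(-|x|))` to avoid
  overflow.
* A non-finite training loss aborts with a diagnostic rather than
  continuing silently.
* `epochs = 0` is a valid request and returns the initialized network
  with an empty history.
* An empty neighbourhood, an all-empty βsor instance, fewer than *N*
  other plots, a point outside a raster's extent, a degenerate extent,
  and an empty checklist are all errors that name the offending object.
* Scaled features may leave [0, 1] on new data by design (see above);
  label round-trips through scaling are exact to machine precision.

## Problem sizes in the test suite

The automated tests run the full protocol at reduced sizes chosen as the
smallest instances on which each property is meaningful: oracle suites
use 1,000 random βsor instances and 100-plot neighbour searches; the
signal-recovery check uses a 500-plot landscape with a strong gradient
(*s* = 3), *N* = 10, a two-architecture search capped at 300 epochs, and
a 5-member ensemble, asserting that the selected gamma model beats the
constant-mean baseline on held-out plots and that all predictions are
positive. The `scripts/acceptance.R` script re-runs the same computations
from scratch and records every quantity with its problem size.

## Known limitations

* Training is plain R matrix arithmetic: ample for networks of tens of
  nodes and ~10⁴ instances, not for substantially larger problems.
* Neighbour search is exhaustive (O(n²) over plots); fine up to a few
  thousand plots.
* The multiple-site Sørensen here is the focal-pair neighbourhood form;
  it is not the all-pairs index used in beta-diversity partitioning
  studies, and no turnover/nestedness decomposition is provided.
* Name matching is exact post-normalization; no fuzzy matching or synonym
  resolution.
* Prediction quality outside the convex hull of the training features is
  unknowable from within the package; the out-of-range counter and the
  CV mask are reported exactly so users can see where they are
  extrapolating.
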