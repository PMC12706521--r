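---
title: "Spatial phylogenetics on gridded communities: models, nulls, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial phylogenetics on gridded communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylogrid)
```

phylogrid implements a complete spatial-phylogenetics workflow for gridded
presence–absence data: diversity and endemism metrics per grid cell, null
models and CANAPE endemism classification, beta-diversity regionalization,
climate-change velocity, and spatially explicit regression. This vignette
explains the models behind each stage, the tunable parameters that matter,
the numerical choices, and what validation on synthetic data does and does
not establish.

## The data model

Everything operates on a planar, equal-area grid (`grid_spec()`): square
cells of side `cell_size` kilometres, row-major cell ids starting at 0 with
the origin in the lower-left corner. Cells are half-open intervals
`[left, right) × [bottom, top)`, so occurrence points on shared edges are
assigned unambiguously. No geographic projection is handled: inputs are
expected in a projected, equal-area coordinate system, which is the
appropriate footing for range-size-weighted metrics.

A `community_matrix` is a binary cells × species occupancy matrix built
either from range polygons (`rasterize_ranges()`: presence wherever the
polygon overlaps a cell with nonzero area — a deliberate choice over
cell-centre containment, since expert range maps are drawn to cover
habitat, not cell centroids; the rule matters mainly for narrow ranges at
coarse grids and is therefore documented as a sensitivity knob) or from
occurrence records (`points_to_matrix()`: presence where at least one
record falls in the cell). Species columns that end up empty are retained
and reported, but are excluded from endemism weights, where an undefined
1/0 would otherwise appear.

## Diversity and endemism metrics

For a cell with species set $S$ on a rooted tree with branch lengths
$L_b$:

* **SR** — species richness, $|S|$.
* **WE** — weighted endemism, $\sum_{i \in S} 1/r_i$, with $r_i$ the
  number of cells species $i$ occupies. Summed over all cells WE equals
  the number of occurring species, a conservation law the tests verify
  exactly.
* **PD** — Faith's phylogenetic diversity: the summed length of all
  branches whose descendant tips intersect $S$, i.e. the rooted spanning
  subtree *including the path to the root*. The rooted convention makes
  single-species cells carry their full root-to-tip path and is the
  standard in the endemism-classification literature.
* **PE** — Rosauer's phylogenetic endemism: as PD but each branch length
  is divided by the branch range $R_b$, the number of cells holding at
  least one of its descendants. PE ≤ PD cell-wise, and summed over cells
  PE equals the total length of occupied branches (each branch
  contributes $L_b/R_b$ in exactly $R_b$ cells).
* **RPD / RPE** — the ratio of PD (PE) on the observed tree to the same
  quantity on a *comparison tree*: identical topology with every branch
  set to the mean branch length. Preserving total tree length (rather
  than setting unit branches) makes the ratios dimensionless and centred
  near 1; values above 1 flag concentrations of longer-than-average (old)
  branches. The convention is a genuine design choice — the ratio's
  interpretation, not its significance rank under the null, depends on
  it, because the null test compares like with like.
* **TILD** — time-integrated lineage diversity: $\int \ln N(t)\,dt$ where
  $N(t)$ is the lineage-through-time curve of the cell's subtree. We
  integrate from the subtree's *own* root — the MRCA of the resident
  species — to the present, in natural log. The cited construction is
  summarized tersely in the literature, so both the integration origin
  and the log base were open; the MRCA origin makes single-species cells
  exactly 0 and the metric independent of how much stem history lies
  above the local radiation. $N(t)$ is piecewise constant, so the
  integral is evaluated as an exact finite sum over inter-node intervals,
  not by quadrature. Requires an ultrametric tree.

On a star phylogeny with unit branch lengths PD reduces to SR and PE to
WE, which ties the phylogenetic family to the taxonomic one; the test
suite asserts this to 1e-12.

Matrix-level nestedness is summarized by NODF, delegated to
`vegan::nestednodf` in its standard (fill-ordered, unweighted)
formulation: pairs of rows or columns contribute their percent overlap
only when their marginal totals strictly decrease, which makes the value
invariant to the arrangement of the input matrix. High NODF warns that
fixed-fixed randomizations will mix slowly — the motivation for the
convergence diagnostic below.

## Null models and CANAPE

Significance is assessed against randomized communities:

* **swap** — samples 2×2 submatrices uniformly and swaps checkerboard
  patterns, preserving row and column totals. `n_itr` counts *successful*
  swaps; skipped non-checkerboard proposals do not count. This convention
  (the alternative counts proposals) changes what a given `n_itr` means
  for mixing, so it is part of the function contract. A subtle
  consequence, verified by enumeration on tiny matrices: counting
  successes turns the sampler into the jump chain of the uniform-proposal
  walk, whose long-run distribution weights each reachable matrix by its
  number of checkerboard units. On classes where those counts are equal
  the law is uniform; in realistic matrices the bias is the same one the
  classic swap literature discusses. Curveball (below) is the uniform
  alternative.
* **curveball** — draws two rows and randomly redistributes the species
  unique to each ("trades"), also fixed-fixed. Trades that happen to be
  no-ops still count as iterations, which keeps self-loops in the chain
  and makes its stationary distribution uniform over the reachable class.
* **r0** — keeps row totals (cell richness) but redistributes each row
  over species equiprobably, destroying range-size structure; useful as a
  contrast when nestedness makes fixed-fixed chains mix poorly.

`convergence_diagnostic()` reruns chains at increasing `n_itr` and
reports the mean proportion of matrix entries identical to the original;
the smallest `n_itr` within 0.01 of the final plateau is suggested. For
production runs on real data the literature-standard settings are large
(on the order of 10^5–10^6 replicates and 10^3 iterations at a 25-km
grid); the package defaults are deliberately small and should be raised
via the exposed arguments for publication-grade runs.

`null_test()` re-randomizes *from the observed matrix* each replicate
(independent draws, not a thinned chain), recomputes PD, RPD, PE on the
observed tree, PE on the comparison tree, and RPE, and accumulates tail
counts. p-values use the +1 Monte-Carlo correction,
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{\text{reps}} + 1)$, so
they are never exactly zero, and "significant at $\alpha$" means
$p \le \alpha$ — attainable exactly with 199 replicates at
$\alpha = 0.05$. One caveat worth knowing: on very small matrices the
fixed-marginal class is itself small, many null replicates tie exactly
with the observed statistic, and the attainable p-values truncate well
above $\alpha$ — the test becomes conservative by discreteness rather
than calibrated. The validation suite therefore checks type-I
calibration at a community size (12 cells × 30 species) where the null
distribution of PD is effectively continuous.

`canape_classify()` then applies the categorical analysis of neo- and
paleo-endemism: a cell is a candidate when the PE numerator or the
comparison-tree denominator is significantly *high* (one-tailed
$\alpha$); candidates split on the RPE ratio two-tailed at $\alpha$
($\alpha/2$ per tail) into paleo (high — long range-restricted branches),
neo (low — short range-restricted branches), or mixed (both components
high, ratio unremarkable); mixed cells significant in both components at
the stricter $\alpha = 0.01$ are super endemism centres. Cells empty in
the observed matrix are excluded. The categories are invariant to
rescaling all branch lengths, which the tests check by direct comparison.

## Beta diversity and regionalization

`phylosor()` computes Sørensen-type similarity on spanning-branch
lengths, $2A/(2A + B + C)$; `phylo_beta_pair()` returns the Baselga
decomposition of the matching dissimilarity into turnover
($\beta_{sim} = \min(B,C)/(A + \min(B,C))$, insensitive to richness
differences) and nestedness-resultant remainder. On a star tree these
collapse to the classical taxonomic Sørensen and Simpson indices.

Regionalization (`kmeans_regions()`, `regionalize()`) runs Lloyd's
K-means on the rows of the dissimilarity matrix — each cell described by
its dissimilarity profile to all others — rather than on an ordination
embedding; a principal-coordinate embedding is a reasonable alternative
but adds a truncation choice, and the profile representation preserves
all pairwise information. Restarts are run individually and a start
whose cluster empties is abandoned (its WSS cannot be compared), keeping
the best of the remainder; 25 restarts by default. The number of regions
is chosen by the elbow of the WSS curve; since "the elbow" is a visual
rule, it is automated as the argmax of the discrete second difference
of WSS over interior K, ties broken toward smaller K, and the full curve
is returned for inspection.

## Climate-change velocity

`climate_velocity()` implements gradient-based velocity: the per-cell
temporal trend (OLS slope of the full time series against years — all
time steps, not endpoints, so century-scale noise averages out) divided
by the spatial gradient of the time-mean field (central differences on
the 3×3 neighbourhood, one-sided at edges), in km per year. The absolute
slope is used — speed, not signed velocity — because layers for
different variables are subsequently combined additively. Cells where
the gradient falls below `gradient_floor` (default 1e-6 units/km) use
the floor instead, preventing division blow-up on flat fields; every
floored cell is flagged in an audit mask. Velocity is invariant to
affine unit changes applied jointly in space and time (the scale cancels
in the ratio). `normalize_and_combine()` min-max rescales each layer to
0–1 over non-missing cells — "normalizing to a 0–1 scale" pins min-max
uniquely — and sums, bounding the result in \[0, 2\]; 0 marks the most
climatically stable cell.

## Spatial regression

`screen_predictors()` enforces the common |r| < 0.5 collinearity rule
greedily: while any pair exceeds the threshold, the predictor with the
largest mean absolute correlation is dropped. The greedy rule is a
package choice — the screening literature typically says only that
correlated variables were removed — and both the drop order and the full
correlation matrix are returned so the decision is auditable.

`build_weights()` builds distance-band neighbours (0 < d ≤ d_max) with
row-standardized weights by default (each neighbour 1/degree, the
standard "W" coding; binary "B" is available). The neighbourhood radius
is chosen from `correlogram()`: Moran's I in equal-width distance
classes up to half the maximum pairwise distance, with the upper edge of
the last class before the first non-significant one reported as the
suggested cutoff.

`morans_i()` uses the classical statistic with expectation $-1/(n-1)$
and the normality-assumption variance. `fit_sar()` fits simultaneous
autoregressive models by maximum likelihood: the error model
$y = X\beta + u,\ u = \lambda W u + \varepsilon$ and the lag model
$y = \rho W y + X\beta + \varepsilon$. For a candidate spatial parameter
the model reduces to OLS on filtered data, so $\beta$ and $\sigma^2$ are
profiled out and a line search maximizes the concentrated likelihood
over the admissible interval $(1/\min e_i,\ 1/\max e_i)$, with the
Jacobian $\ln|I - \lambda W|$ computed once from the eigenvalues of $W$
(real for row-standardized symmetric-neighbour weights; the eigenvalue
route agrees with the dense determinant to 1e-8 in the tests, and can be
precomputed and passed in when many models share a weight matrix).
Islands receive zero weight rows and contribute non-spatially. AIC
counts coefficients + error variance (+ the spatial parameter where
present), so `model_select()` ranks OLS and SAR fits on a common
footing, ties broken toward fewer parameters.

## The synthetic-data module

Because the real inputs of a study of this kind (expert range maps,
occurrence archives, paleoclimate series) are large and not
redistributable, every stage is validated on synthetic data with known
ground truth:

* `simulate_phylogeny()` — forward Yule process: with $k$ lineages the
  next speciation waits $\text{Exp}(k\lambda)$; the simulation stops
  after the wait following the $n$-th speciation, giving expected root
  age $\sum_{k=2}^{n} 1/(k\lambda)$, the closed form the Monte-Carlo
  test checks against.
* `simulate_ranges()` — each species occupies a disk-shaped block grown
  cell-by-cell from a random centre (ties by distance then cell index)
  to a negative-binomially drawn size: the simplest contiguous geometry
  that still gives full control of the range-size distribution. Hotspot
  scenarios confine the species on the longest (paleo) or shortest (neo)
  20% of terminal branches — or both (mixed) — to a designated block
  with small ranges.
* `simulate_climate_series()` — linear space–time fields plus optional
  Gaussian noise, at 100-year steps ending at the present. The real
  counterpart is a deterministic raster series; noise exists purely to
  exercise the estimators.
* `simulate_sar_response()` — exact SAR-error draws via
  $(I - \lambda W)u = \varepsilon$.

The reference endemism scenario (`hotspot_scenario()`) is a 10 × 10 grid
of 25-km cells, 100 species, background ranges of 12 cells on average,
and a 3 × 3 hotspot confining the 20 longest-branch species to ranges of
4 cells on average. The sizes were chosen to mirror a regional avifauna
in miniature: enough endemics that every hotspot cell hosts several —
an endemism *centre*, not scattered single occurrences — because a
hotspot cell that no endemic happens to occupy carries no signal for any
method to find. Null runs in the validation suite use 199–499
replicates and 100–1000 iterations; these are statistically adequate at
these matrix sizes (the convergence diagnostic plateaus far below them)
while keeping the full suite fast.

What passing on synthetic data shows: the metrics equal their
definitions (verified against independent brute-force oracles), the
conservation laws hold, the null machinery is calibrated (type-I error
at nominal level under structureless data), planted endemism structure
of the kind the classifier targets is recovered, and the estimators
(velocity, SAR) recover known parameters. What it does not show:
robustness to the things real data add — range maps drawn at coarser
resolution than the grid, taxonomic mismatches between tree and
occurrence data, spatially structured sampling effort, non-contiguous
ranges, and climate fields whose gradients vary over orders of
magnitude. Those must be assessed on the real inputs.

## Degenerate inputs and numerical conventions

Empty cells: PD, PE and TILD are 0; RPD/RPE and pairwise beta values are
flagged missing rather than invented; CANAPE excludes them. Zero-length
branches are rejected with guidance (collapse them first) since every
metric reads branch lengths as durations. Node ages within 1e-12 of the
present are snapped to zero so that floating-point tip ages cannot
create spurious zero-lineage intervals in TILD. Constant velocity
layers normalize to all-zero with a warning (there is no variation to
rescale). Matrices with no checkerboard cannot be swap-randomized; the
input is returned with a warning and every null replicate equals the
observed matrix, making all p-values 1 — conservative by construction.

## Known limitations

* Dense matrix algebra throughout: grids beyond ~10^4 cells will want
  sparse weights and a sparse branch-incidence representation.
* The swap sampler inherits the success-counting bias discussed above;
  for strict uniformity over the null class use curveball.
* TILD is defined only for ultrametric trees.
* K-means regionalization operates on dissimilarity profiles; very large
  grids would be better served by clustering a low-rank embedding.
* The CLI reads polygons and grids from plain-text formats only
  (vertex CSV, ESRI ASCII); binary GIS formats are out of scope.
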