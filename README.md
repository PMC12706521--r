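# phylogrid

Spatial phylogenetics for gridded communities.

Biogeographers studying regional faunas — say, the forest birds of a
peninsula — ask where diversity concentrates, whether centres of endemism
harbour old lineages or recent radiations, how communities turn over
across the landscape, and which environmental factors (contemporary
climate, topography, long-term climatic stability) explain the patterns.
phylogrid packages that entire workflow for R users working with a
phylogeny, species ranges or occurrence records, and gridded environmental
layers.

## What it computes

For a binary cells × species matrix on a planar equal-area grid and a
rooted phylogeny with branch lengths $L_b$:

- **Species richness** SR and **weighted endemism**
  $\mathrm{WE} = \sum_{i=1}^{s} 1/r_i$ (inverse range sizes of resident
  species);
- **Faith's phylogenetic diversity** PD (total spanning-subtree branch
  length, rooted convention) and **Rosauer's phylogenetic endemism**
  $\mathrm{PE} = \sum_b L_b / R_b$ over spanning branches, with $R_b$ the
  number of cells occupied by the branch's descendants;
- **Relative PD / PE** against a comparison tree with equalized branch
  lengths, and **time-integrated lineage diversity** (the integral of the
  log lineage-through-time curve of each cell's subtree);
- **Null models** — swap and curveball (fixed-fixed) and r0
  (fixed-equiprobable) randomizations with convergence diagnostics, tail
  ranks with the +1 Monte-Carlo correction, and **CANAPE** classification
  of endemism centres into neo / paleo / mixed / super;
- **Phylogenetic beta diversity** — PhyloSor similarity and the Baselga
  turnover/nestedness decomposition — with K-means regionalization and
  automated elbow selection of the number of regions;
- **Climate-change velocity** (temporal trend ÷ spatial gradient, km/yr)
  from gridded time series, with 0–1 normalization and multi-variable
  combination;
- **Environmental-correlate models** — collinearity screening, Moran's I
  correlograms, distance-band spatial weights, and maximum-likelihood SAR
  error/lag models ranked by AIC;
- A **synthetic-data module** (pure-birth phylogenies, contiguous ranges
  with plantable neo/paleo endemism hotspots, climate fields and SAR
  responses with known ground truth) so every stage can be validated
  without any external download.

## Worked example

Simulate the package's reference study system — a 10 × 10 grid of 25-km
cells, 100 species, and a 3 × 3 paleo-endemism hotspot confining the 20
longest-branch species — then compute the metric table and classify
endemism centres:

```r
library(phylogrid)

spec <- hotspot_scenario("paleo", seed = 1)
sc   <- simulate_scenario(spec)
sc$cm
#> community matrix: 100 cells x 100 species, 976 presences
#> grid: 10 x 10 cells of 25 km, origin (0, 0)

head(round(diversity_metrics(sc$cm, sc$tree), 3))
#>   cell_id     x    y sr    we     pd    pe   rpd   rpe  tild
#> 1       0  12.5 12.5 12 1.887 29.492 3.081 1.245 2.236 7.017
#> 2       1  37.5 12.5 16 3.076 37.244 4.986 1.243 2.441 7.659
#> 3       2  62.5 12.5 17 2.468 37.338 3.659 1.088 1.870 7.447
#> 4       3  87.5 12.5 11 0.826 23.065 0.666 0.734 0.657 5.972
#> 5       4 112.5 12.5  9 0.604 20.110 0.572 0.743 0.694 5.621
#> 6       5 137.5 12.5  7 0.521 17.893 0.510 0.771 0.725 5.441

nr <- null_test(sc$cm, sc$tree, "swap", n_reps = 499, n_itr = 1000, seed = 2)
cl <- canape_classify(nr)
table(cl$category)
#> not_significant             neo           paleo           mixed           super
#>              91               0               7               1               0
```

The first three cells sit inside the hotspot: note their high PE and RPE
well above 1 (concentrations of long, range-restricted branches), versus
RPE below 1 just outside. The classifier recovers 8 of the 9 planted
hotspot cells as paleo/mixed endemism centres and flags no background
cell.

A thin command-line front end over the same functions ships in
`inst/cli/phylogrid.R`, with subcommands `simulate`, `diversity`,
`canape`, `beta`, `velocity` and `correlates` operating on plain-text
files (community CSV, Newick, ESRI ASCII rasters).

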