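---
title: "Delimiting floristic districts with phylogenetic diversity metrics"
author: "phylofloristics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting floristic districts with phylogenetic diversity metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylofloristics)
```

## The problem

Tropical tree inventories sample a region with a network of one-hectare
plots in which every stem above 10 cm diameter is counted and identified.
Bioregionalization asks which plots belong together: which parts of the
region share not only a species pool but, through the phylogeny of that
pool, a common evolutionary history. This package implements an analysis
chain for that question, built for hyperdiverse Amazonian forests (tens of
plots, a regional pool of well over a thousand species on a dated
supertree) but applicable to any (tree, community matrix, coordinates)
triple. It computes per-plot alpha diversity, pairwise taxonomic and
phylogenetic beta diversity with null-model expectations, phylogenetic
endemism and evolutionary distinctiveness, ordination and permutation
inference for district delimitation, and loess-interpolated map surfaces.

## Data model

A phylogeny is a standard `ape` `"phylo"` object; branch lengths are ages
in Myr when the tree is dated. A community matrix is a plain integer
matrix, plots in rows and species in columns. `align_tree_community()`
reconciles the two (species missing from the tree are dropped and
reported, tips missing from the matrix are pruned), mirroring the usual
workflow where unnamed morphospecies are removed first
(`filter_morphospecies()`).

## Metrics

**Fisher's alpha.** Species richness S and abundance N of a plot are
linked through the log-series model by S = α·ln(1 + N/α).
`fisher_alpha()` inverts this relation by bracketed root-finding
(bisection bracket [1e-6, 1e8], Newton polish to |residual| < 1e-9); the
left-hand side is strictly increasing in α, so the bracket is safe.

**Faith's PD** is the total branch length of the minimum spanning path
connecting a plot's species to the root (`faith_pd()`, built on
`spanning_edges()`).

**ses.MPD.** The mean pairwise patristic distance of a plot is compared
with its distribution over randomizations of the presence/absence matrix
by the independent-swap algorithm, which flips 2x2 checkerboard
submatrices and therefore preserves species occurrence frequencies and
plot richness exactly. Each null replicate is an independent chain of
10 x (number of occurrences) successful swaps started from the observed
matrix — a standard mixing heuristic that keeps replicates exchangeable
and reproducible under a seed. The standardized effect size uses the
sample (n-1) standard deviation of the null. Classification follows the
convention in which values beyond +1.96 are labelled clustering and below
-1.96 overdispersion; because this is the reverse of common NRI usage
(observed MPD *below* the null indicates co-occurring close relatives),
`ses_mpd(convention = "standard")` inverts the labels, and the clustered
signal in clade-restricted communities appears in the negative tail.

**Beta diversity.** Taxonomic dissimilarity is 1 - Sorenson
(incidence-based); phylogenetic dissimilarity is 1 - PhyloSorenson, in
which shared species counts are replaced by the branch length shared
between the two plots' spanning paths. `null_phylosor()` randomizes the
whole matrix once per replicate (all pairs share a replicate, preserving
the joint structure of the draw) and returns the expected dissimilarity,
the observed-minus-expected deviation, and per-pair rank quantiles.
An abundance-based Bray-Curtis matrix is available as a clearly labelled
extra; the core indices are incidence-based.

**Endemism.** Weighted phylogenetic endemism divides every branch on a
plot's spanning path by the range of the clade it subtends (number of
occupied plots, or of 0.5 degree grid cells via `unit = "grid"`); ranges
default to plot units. Abundance-weighted evolutionary distinctiveness
(AED) apportions each branch equally among the individuals descending
from it, so that the abundance-weighted sum of AED over a plot's species
reconstructs the plot's Faith PD exactly — the package's primary
correctness oracle for this family. The per-individual division follows
the metric's source; a per-species variant sits behind
`aed(per_species = TRUE)`. IAC compares abundances with the expectation
that individuals split evenly (1/d for a d-way polytomy) at every node of
the plot-pruned tree and reports the mean absolute deviation per internal
node; it is computed per plot by default.

**BLADJ dating.** `bladj_date()` fixes calibrated internal nodes at their
ages, then assigns every undated node an age by even spacing between its
nearest dated ancestor and nearest dated descendant. Nodes are processed
root-ward (preorder), so interpolation always happens below an
already-dated parent, which makes the procedure idempotent and the
resulting branch lengths non-negative; the nearest dated descendant is
the one reachable in the fewest edges, ties resolved toward the older
age. Polytomies are allowed everywhere — the supertrees this is meant for
are unresolved.

## Inference

**NMDS** minimizes Kruskal's stress-1 with monotone regression (primary
tie treatment), delegating the inner optimization to `vegan::monoMDS` and
taking the best of `n_starts` configurations: the first start is
classical metric scaling, the rest random. Random starts are drawn in a
single seeded sequence, so the best stress is non-increasing in
`n_starts`. Two dimensions and many random starts reproduce the usual
ordination protocol for this analysis.

**MRPP** uses the group-size weights C_g = n_g/N (the most common
choice). The permutation p-value always carries the +1 correction so it
is never zero; `exact = TRUE` enumerates all distinct relabellings for
small instances, which is how the tests pin the permutation machinery to
a brute-force oracle. A = 1 - delta_obs/delta_exp is the chance-corrected
effect size. **Mantel** correlates lower triangles and permutes the
second matrix, one-tailed; it has the same exact mode.

## Spatial surfaces

The map grid is anchored at integer multiples of the cell size (0.5
degrees by default, about 55 km), cells half-open and indexed by
`floor(coordinate/cell_size)`. Per-plot metrics — typically the mean
dissimilarity of each plot to all others (`mean_row_dissimilarity()`),
WPE, IAC, or an AED summary — are interpolated by loess (span 0.75,
degree 2, tricube weights) evaluated at cell centres, with distances in
raw degrees: the study windows this targets span a few degrees, where
planar distortion is tolerable. Cells outside the convex hull of the
plots are still predicted, because the method's purpose is to fill
unsampled areas, but carry an `extrapolated` flag so maps can be read
honestly. Rank-deficient local designs fall back from degree 2 to degree
1 to a constant surface, recorded in a `fallback` attribute.

## The synthetic landscape

`simulate_bundle()` provides fixtures with known truth for every stage.
Defaults mirror a realistic study design: 62 one-hectare plots, a
1,687-species regional pool on a pure-birth tree rescaled to root age
100, three latitudinally coherent districts inside a 3 x 5.5 degree
window, 600 stems per plot, and per-plot Fisher's alpha 100 — a typical
value for hyperdiverse western Amazonian terra firme forest (the target
alpha and plot size are the one place realism was chosen rather than
derived; everything else follows the stated design).

Abundances are log-series: the parameter x solves N = α·x/(1-x), species
counts are drawn from P(n) ∝ x^n/n until N stems accumulate, and the last
species is trimmed to land exactly on N. District structure enters
through composition only: each species in a plot comes from the
district's preferred deep clade with probability β (default 0.9) and from
the whole pool otherwise, so β = 0 is exactly uniform sampling and the
district labels carry no signal — the null calibration the tests check.
Preferred clades are found by cutting the tree at the shallowest level
that yields at least three subtrees; because pure-birth root splits are
often very unbalanced, the cut deepens until the third-largest clade can
hold 1.2 x the expected plot richness, so the bias is not silently capped
by clade size.

What the generator does *not* emulate: soils and habitat mosaics (terra
firme vs white sand), spatial autocorrelation within districts beyond the
banding, distance decay, detection error, or speciation processes. A
passing recovery test therefore shows the chain detects clade-structured
compositional signal at realistic sizes — not that real Amazonian
districts are this clean.

## Numerical choices and problem sizes

Permutation p-values are never reported as zero (+1 correction).
Dissimilarity values are clipped to [0,1] against floating-point fuzz and
diagonals set to exactly zero. The swap kernel is compiled (Rcpp) because
a single full-scale null model needs on the order of 10^7 successful
swaps; it gives up with a warning after a bounded run of consecutive
failures, which is how matrices with no checkerboard (e.g. all-ones) are
detected. The test suite exercises the full 62 x 1,687 design once
(199-replicate MRPP, 99-replicate nulls, 20 NMDS starts) and pins the
metric layer to brute-force oracles on exhaustive subsets of small random
trees; unit fixtures use 100-300 species pools so that the whole suite
runs in a few minutes.

## Known limitations

Ties in the NMDS monotone regression use the primary treatment only.
MRPP requires at least two plots per group, so k-medoids-derived labels
(used only when no grouping is supplied, and flagged as derived) can fail
on weakly structured data. Great-circle distances are not used anywhere;
very wide study windows would need a projection step upstream. The
independent-swap null conditions on observed margins — it cannot speak to
processes that change richness or occupancy themselves.
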