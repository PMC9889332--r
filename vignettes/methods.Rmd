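---
title: "Methods: tri-facet diversity, hull geometry, and the homogenization scenario"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tri-facet diversity, hull geometry, and the homogenization scenario}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divfacets)
```

## The problem

Land conversion can raise *local* (alpha) diversity while making
communities more similar to one another, so that turnover (beta) and
regional pooled (gamma) diversity fall. Detecting this biotic
homogenization requires measuring all three scales, and doing so in three
facets at once — taxonomic, functional and phylogenetic — because the
facets can respond differently. `divfacets` implements that design for
presence/absence community data with habitat labels, a mixed-type species
trait table, and a rooted, branch-length phylogeny; a separate grid module
locates regions whose diversity is unshared with the rest of a continental
grid.

## Models and estimators

### Functional trait space

Species dissimilarity uses **Gower's coefficient** with pairwise deletion:
traits contribute only where both species have values
($\delta_{ijt}$ indicator), continuous and ordinal traits as
$|x_i-x_j|/\mathrm{range}_t$, categorical and binary traits as a 0/1
mismatch. Two deliberate choices: ordinal traits use integer level codes
under the simple Gower variant (not Podani's tie correction — the simple
variant is the default in the standard implementations and nothing in the
design depends on the distinction); missing values are never imputed. A
trait that is constant across species carries no information and is
dropped with a warning.

The common 3-D space is **non-metric multidimensional scaling**: each
start alternates pool-adjacent-violators isotonic regression of the
configuration distances on the dissimilarity ranks (Kruskal's primary tie
treatment: tied dissimilarities may receive unequal fitted values) with a
SMACOF/Guttman configuration update; a step that increases stress-1 is
rejected and ends the start. Because stress-1 is invariant to uniform
rescaling of the configuration, the Guttman iteration can let the
configuration scale drift; we pin the scale after every update (mean
configuration distance = mean input dissimilarity), which leaves the
stress sequence untouched but keeps hull volumes on an interpretable
scale. The best configuration over `n_starts` (default 20; start 1 is the
classical-scaling solution, the rest uniform random) is centred, rotated
to principal axes and sign-fixed, so output orientation is deterministic,
and the reported stress is recomputed from the returned coordinates —
`stress1(coords, dm)` reproduces it exactly. The embedding is fitted
**once** on the full species pool and reused by every site-level
computation; it is never re-fitted per site.

Defaults `n_starts = 20`, `max_iter = 300`, `tol = 1e-7` make the
42-species problem deterministic in practice. The achieved stress for the
default synthetic data is about 0.19–0.20 — ordinary for squeezing 11
mixed traits into three dimensions, and a reminder that FRic values are
ordination-dependent: comparisons are meaningful within one embedding,
not across embeddings.

### Convex-hull functional richness and functional beta

FRic is the volume of the convex hull of a species set's coordinates,
computed by an incremental 3-D hull (initial tetrahedron, horizon repair
per point). Sets with fewer than $k+1$ species or affinely degenerate
geometry return `NaN`, not 0: "no volume" and "undefined" must not be
conflated, and with realistic site richness (minimum ~4 species) defined
hulls are the norm. Undefined functional beta pairs propagate `NaN` and
are dropped from summaries with a reported count.

Functional beta needs the volume of the intersection of two hulls. The
implementation enumerates the candidate vertices of the intersection
polytope — vertices of one hull inside the other, plus edge-of-one ×
facet-of-the-other crossing points — and then applies the divergence
theorem: every facet of the intersection lies on a facet plane of A or B,
so each plane's on-plane candidates form a polygon whose area comes from a
*2-D* convex hull, and $V = \tfrac13\sum_i d_i\,\mathrm{area}_i$. The 2-D
route was chosen after finding that re-hulling the heavily coplanar
candidate cloud in 3-D is numerically fragile; it also removes the need
for an interior-point linear program (a Chebyshev-centre LP was the
obvious alternative): an empty candidate set *is* the infeasibility
certificate, giving volume 0 for disjoint or merely touching hulls.
Identity ($V(A\cap A)=V(A)$) holds to machine precision and random pairs
agree with Monte-Carlo membership sampling well within 1%.

### Phylogenetic diversity

Faith's PD is **rooted** by default: the summed length of the union of
root-to-tip paths, so a single species contributes its full root path.
The MRCA-based variant (`include_root = FALSE`) is exposed because the
convention is often left unstated in applied work. Phylogenetic beta is
PhyloSor, $1 - 2\,BL_{shared}/(PD_A + PD_B)$, with shared length measured
on the same rooted path sets; grid-cell branch occupancy uses the same
convention. Species missing from a source tree are attached by
`graft_species`: the closest relative's terminal branch of length $L$ is
split at `fraction`·$L$ below the tip with an equal-length pendant edge.
"At the tip of the branch" is genuinely ambiguous; the default
`fraction = 0.5` keeps a positive pendant edge (so grafted species
contribute PD) and is configurable for sensitivity analysis.

### Regional machinery

Subsampled gamma draws, within each habitat, the requested number of
sites uniformly without replacement (e.g. 7 forest + 8 savannah to match
15 farmland sites), pools species and evaluates the facet's gamma; draws
are independent and duplicate combinations are allowed — with thousands of
possible combinations, exclusion is immaterial. Exact species-accumulation
curves use analytic sample-based rarefaction,
$S(k)=\sum_s [1 - \binom{n-n_s}{k}/\binom{n}{k}]$, with a permutation mode
for spread. Habitat contrasts default to **Welch's** two-sided t-test
(robust to unequal variances between unbalanced groups; the Student
variant is available because published analyses often do not say which
was used) with type-7 medians/IQRs. Applying t-tests to pairwise beta
values ignores their non-independence; the package reproduces that
practice but warns, and offers `permutation_contrast` (site-label
permutation of the full dissimilarity matrix) as the sounder alternative.
If an elevation filter leaves fewer sites than a requested subsample
size, the pipeline caps the draw at the available count and logs it.

### Grid complementarity

The complementarity of a cell is implemented as **richness-corrected
weighted endemism**: $we/S$ with $we=\sum_s 1/occ_s$, and $pe/PD$ with
$pe=\sum_b L_b/occ_b$ over the cell's occupied branches. The verbal
definition it implements — the contribution of a cell relative to the
diversity found in the cell, high when a large share of the cell's
species/branches occur almost nowhere else — pins down this construction
up to the correction; the uncorrected $we$ and $pe$ are emitted alongside
for sensitivity. Both quantities conserve totals ($\sum we$ = number of
occupied species; $\sum pe$ = occupied branch length), which the tests
assert on random and counterfactually edited grids. Empty cells keep
`NaN` complementarity rather than being dropped, preserving grid geometry
for mapping; max-scaling (`scale_to_max`) excludes `NaN`s from the
maximum and propagates them.

## The synthetic world

The generator is a test harness, not an inference target: its defaults
state one fixed scenario and are not tuned to any outcome.

* **Phylogeny**: pure-birth (Yule) with a fixed tip count — simpler than
  birth–death (no extinct-lineage pruning) and sufficient for metric
  testing. Expected total length $(n-1)/\lambda$ anchors a Monte-Carlo
  test.
* **Pools**: 22 forest + 17 savannah species (disjoint), and a 19-species
  farmland pool of which 16 are drawn from the natural pools and 3 are
  farmland-exclusive — 42 community species in total (16 + 3 is the split
  that reconciles a 19-species farmland pool with a 42-species community).
  Farmland's shared species are sampled from the most trait-space-central
  half of the natural species (`centrality_quantile = 0.5`, ranked by
  mean Gower distance), emulating the trait-nestedness of
  disturbance-tolerant communities.
* **Communities**: 11 forest + 11 savannah + 15 farmland sites. Natural
  species occupy contiguous circular windows of
  `round(0.30 * n_sites)` sites at random positions — mean alpha ≈ 6 with
  high spatial turnover. Farmland species occur independently per site
  with probability $(1-h)\,p_f + h$ ($p_f = 0.45$, homogenization level
  $h = 0.5$ by default, giving ≈ 0.73 occupancy): locally rich, highly
  similar communities. $h = 1$ forces identical farmland sites (taxonomic
  beta exactly 0); increasing $h$ monotonically lowers expected farmland
  beta. The homogenization level acts on farmland only; natural occupancy
  is held at its stated value.
* **Grid**: a 100-cell one-dimensional continental strip; each species
  gets a contiguous range with lognormal size (meanlog $\log 8$,
  sdlog 1, clipped to the grid with a warning). The natural-pool species
  are hotspot endemics (1–3-cell ranges inside cells 45–47); farmland-pool
  species are widespread (≥ 40% of the grid); 40 additional grid-only
  species fill out the continental fauna.
* **Site elevations** are uniform within per-habitat ranges typical of
  montane East African survey designs (forest 1804–3031 m, savannah
  1287–1642 m, farmland 1292–2348 m), so a 2500 m elevation filter bites
  only forest sites.

What a green test establishes: that the estimators jointly recover the
stated homogenization signature (higher farmland alpha, lower farmland
beta and gamma, all three facets) from data whose generating process is
known. What it does not establish: anything about sampling error in real
surveys (detection is perfect here), spatial autocorrelation beyond the
window construction, abundance structure (the package is
presence/absence only), or trait measurement error.

## Numerical choices and degenerate inputs

* Hull tolerances are relative to the coordinate scale (`1e-10` visibility
  in the incremental hull, `1e-8` half-space feasibility, `1e-7` on-plane
  assignment); candidate vertices are deduplicated on a `1e-11` grid.
* Gower denominators of zero (a species pair sharing no recorded trait)
  are an error, not a silent `NaN`.
* A collapsed NMDS configuration against a non-degenerate dissimilarity
  matrix has stress defined as 1; an all-equal dissimilarity matrix warns
  (rank information is vacuous) and embeds exactly only when
  $n \le k + 1$.
* `compare_groups` refuses two constant equal groups (t undefined) and
  groups of fewer than two finite values.
* Empty species sets: PD returns 0 with a warning; Sørensen returns `NaN`
  with a warning.
* Seeds: every stochastic operation takes an explicit seed and restores
  the caller's RNG state; the pipeline fans one master seed out by fixed
  offsets so adding a stage never changes another stage's stream.

## Known limitations

* Hull geometry is 3-D only (matching the fixed 3-D trait space); other
  embedding dimensions embed fine but FRic requires $k = 3$.
* NMDS from random starts is a local optimizer; with few starts on large
  problems the attained stress can vary slightly across seeds, which is
  why site-level results reuse one embedding.
* The t-contrast on beta values is reproduced as specified despite its
  pseudoreplication; use `permutation_contrast` for inference.
* Acceptance-style checks run the 100-seed homogenization sweep with
  reduced analysis settings (4 NMDS starts, 100 gamma draws) to fit a
  one-CPU time budget; the generator configuration is never reduced.
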