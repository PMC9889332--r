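# divfacets

Tri-facet diversity analysis of habitat-structured species communities:
**taxonomic** (species richness), **functional** (convex-hull richness in a
Gower/NMDS trait space) and **phylogenetic** (Faith's PD) diversity, at
**alpha** (per site), **beta** (pairwise Sørensen dissimilarity) and
**gamma** (pooled, with subsampled site combinations) scales, plus
sample-based rarefaction and a continental grid-cell complementarity
analysis.

The package is aimed at community ecologists comparing natural and
disturbed habitats — the motivating scenario is *biotic homogenization*:
land conversion can **raise** local alpha diversity while species turnover
collapses, so beta and gamma diversity fall across all three facets. The
package measures that signature and ships a synthetic-data generator that
emulates it (habitat species pools, spatially clustered natural
communities, a small, widespread, trait-nested disturbed-habitat pool, and
a continental grid with an endemism hotspot), so every stage is testable
without field data.

## Core statistics

For a species set *S* at one or more pooled sites:

- **Richness** `|S|`.
- **Functional richness (FRic)**: species are placed in a common 3-D trait
  space by Gower distance on mixed trait kinds,
  `d(i,j) = Σ_t w_t δ_ijt d_ijt / Σ_t w_t δ_ijt`, followed by non-metric
  multidimensional scaling (Kruskal stress-1, PAVA isotonic regression +
  SMACOF updates); FRic is the convex-hull volume of *S*'s coordinates.
- **Faith's PD**: total branch length of the union of root-to-tip paths of
  *S* on a rooted phylogeny (an MRCA-based variant is available).
- **Sørensen beta** `(b + c) / (2a + b + c)` with facet-specific shared
  components *a*: shared species (taxonomic), hull-intersection volume
  (functional), shared branch length (phylogenetic, PhyloSor).
- **Complementarity** per grid cell: weighted endemism
  `we = Σ_s 1/occ_s` over the cell's species divided by richness (and the
  branch-length analogue `pe/PD`), i.e. richness-corrected weighted
  endemism in (0, 1].

All geometry (3-D convex hulls, hull intersections via half-space
candidate vertices and divergence-theorem facet areas) is implemented in
the package; no external hull library is required.

## Worked example

```r
library(divfacets)

ds <- simulate_dataset(sim_config(seed = 1))   # 37 sites, 42 species
tt <- trait_table(ds$tt$data[ds$cm$species_ids, ], kinds = ds$tt$kinds)
ts <- nmds_embed(gower_distance(tt), n_starts = 10, seed = 11)
ts
#> trait_space: 42 species in 3 dimensions, stress-1 = 0.1926

a <- alpha_table(ds$cm, ts, ds$phy)
nat <- a$habitat != "farmland"
compare_groups(a$richness[nat], a$richness[!nat], c("natural", "farmland"))
#> contrast natural vs farmland: t = -16.75, df = 34.3, p = 4.4e-18
#>   medians (IQR): natural 5 (2.75) | farmland 14 (2)

subsample_gamma(ds$cm, ts, ds$phy, c(forest = 7, savannah = 8),
                n_draws = 1000, facet = "taxonomic", seed = 3)
#> gamma_summary [forest+savannah, taxonomic]: median 39 (sd 1.34,
#>   range 32-39) over 1000 draws
assemblage_diversity(ds$cm, ts, ds$phy,
                     ds$cm$site_ids[ds$cm$habitat == "farmland"])$richness
#> [1] 19
```

Farmland sites are locally *richer* (median 14 vs 5 species) yet their
pooled gamma richness (19) is far below a size-matched natural subsample
(median 39): the homogenization signature. The same contrast holds for the
functional and phylogenetic facets (see the methods vignette), and the
grid module shows the hotspot cells carrying ~4x the species
complementarity of the background:

```r
sc <- species_complementarity(ds$grid)
mean(sc$comp_s[45:47]); mean(sc$comp_s[-(45:47)], na.rm = TRUE)
#> [1] 0.404
#> [1] 0.090
```

A full run (alpha/beta/gamma/contrasts/accumulation/complementarity CSVs +
manifest) is one call:

```r
paths <- write_dataset(ds, "data")
run_pipeline(pipeline_config(
  community = "data/community.csv", traits = "data/traits.csv",
  traits_schema = "data/traits.schema.json", tree = "data/tree.nwk",
  grid = "data/grid.csv", out_dir = "out", seed = 1))
```

or from the shell: `Rscript inst/cli/divfacets.R simulate --seed 1
--out-dir data` then `... run --data-dir data --out-dir out`.

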