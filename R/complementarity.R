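# Continental grid-cell analysis: per-cell richness and PD, weighted
# species/phylogenetic endemism, and the richness-corrected complementarity
# ratio (we/S, pe/PD) used to locate cells whose diversity is unshared with
# the rest of the grid. Both ratios conserve totals: summed over cells,
# weighted endemism equals the number of occupied species and phylogenetic
# endemism equals the total occupied branch length.

#' Per-cell species richness and Faith PD
#'
#' @param grid a [grid_assemblage()].
#' @param phy rooted `phylo` containing every grid species (graft missing
#'   species first via [graft_species()]).
#' @return data.frame `cell_id`, `richness`, `pd` (0 for empty cells).
#' @export
cell_diversity <- function(grid, phy) {
  missing <- setdiff(grid$species_ids, phy$tip.label)
  if (length(missing))
    stop("grid species missing from tree: ", paste(missing, collapse = ", "))
  tp <- .tree_paths(phy)
  rows <- lapply(grid$cell_ids, function(cid) {
    sp <- grid$species_ids[grid$incidence[cid, ] > 0]
    pd <- if (length(sp)) sum(tp$lengths[.path_union(tp, sp)]) else 0
    data.frame(cell_id = cid, richness = length(sp), pd = pd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Weighted species endemism and species complementarity per cell
#'
#' With occ_s the number of cells containing species s: a cell's weighted
#' endemism is we = sum over its species of 1/occ_s, and its species
#' complementarity is comp_s = we / S. comp_s = 1 iff every species in the
#' cell occurs nowhere else; comp_s = 1/N when every species spans all N
#' occupied cells. Empty cells get NaN.
#'
#' @param grid a [grid_assemblage()].
#' @return data.frame `cell_id`, `richness`, `we`, `comp_s`.
#' @export
species_complementarity <- function(grid) {
  inc <- grid$incidence > 0
  if (sum(inc) == 0) stop("empty grid")
  occ <- colSums(inc)
  w <- ifelse(occ > 0, 1 / pmax(occ, 1), 0)
  we <- as.vector(inc %*% w)
  S <- rowSums(inc)
  comp <- ifelse(S > 0, we / S, NaN)
  data.frame(cell_id = grid$cell_ids, richness = S, we = we, comp_s = comp,
             stringsAsFactors = FALSE)
}

#' Phylogenetic endemism and phylogenetic complementarity per cell
#'
#' Each branch b (length L_b) is "in" a cell when it lies on the rooted
#' root-to-tip path of at least one of the cell's species; with occ_b the
#' number of cells holding b, phylogenetic endemism is
#' pe = sum over the cell's branches of L_b / occ_b, and
#' comp_pd = pe / PD. Empty cells get NaN.
#'
#' @param grid a [grid_assemblage()].
#' @param phy rooted `phylo` containing every grid species.
#' @return data.frame `cell_id`, `pd`, `pe`, `comp_pd`.
#' @export
phylo_complementarity <- function(grid, phy) {
  missing <- setdiff(grid$species_ids, phy$tip.label)
  if (length(missing))
    stop("grid species missing from tree: ", paste(missing, collapse = ", "))
  tp <- .tree_paths(phy)
  ne <- length(tp$lengths)
  cell_edges <- lapply(grid$cell_ids, function(cid) {
    sp <- grid$species_ids[grid$incidence[cid, ] > 0]
    if (!length(sp)) integer(0) else .path_union(tp, sp)
  })
  occ_b <- integer(ne)
  for (e in cell_edges) occ_b[e] <- occ_b[e] + 1L
  pe <- vapply(cell_edges, function(e)
    if (length(e)) sum(tp$lengths[e] / occ_b[e]) else 0, 0)
  pd <- vapply(cell_edges, function(e) sum(tp$lengths[e]), 0)
  comp <- ifelse(pd > 0, pe / pd, NaN)
  data.frame(cell_id = grid$cell_ids, pd = pd, pe = pe, comp_pd = comp,
             stringsAsFactors = FALSE)
}

#' Overwrite the species sets of named grid cells
#'
#' Counterfactual editing of a grid: the named cells' rows are replaced by
#' the given species sets (e.g. replacing a country's cells with its
#' natural-habitat and farmland assemblages); all other cells and the cell
#' count are untouched.
#'
#' @param grid a [grid_assemblage()].
#' @param replacements named list: cell id -> character vector of species.
#' @return the edited `grid_assemblage`.
#' @export
replace_cells <- function(grid, replacements) {
  if (is.null(names(replacements)) || any(!nzchar(names(replacements))))
    stop("replacements must be a named list (cell id -> species set)")
  unknown_cells <- setdiff(names(replacements), grid$cell_ids)
  if (length(unknown_cells))
    stop("unknown cell id(s): ", paste(unknown_cells, collapse = ", "))
  inc <- grid$incidence
  for (cid in names(replacements)) {
    sp <- replacements[[cid]]
    unknown <- setdiff(sp, grid$species_ids)
    if (length(unknown))
      stop("unknown species: ", paste(unknown, collapse = ", "))
    inc[cid, ] <- 0
    inc[cid, sp] <- 1
  }
  grid_assemblage(inc, cell_lonlat = grid$cell_lonlat)
}

#' Scale values relative to their maximum
#'
#' Divides by the maximum finite value so the result lies in `[0, 1]` with
#' the maximum at exactly 1; NaN entries propagate and are excluded from the
#' maximum.
#'
#' @param values numeric vector with at least one positive finite entry.
#' @return rescaled vector.
#' @export
scale_to_max <- function(values) {
  mx <- suppressWarnings(max(values[is.finite(values)]))
  if (!is.finite(mx) || mx <= 0)
    stop("need at least one positive finite value")
  values / mx
}

#' Full per-cell diversity/complementarity table (raw + max-scaled columns)
#'
#' @param grid a [grid_assemblage()].
#' @param phy rooted `phylo`.
#' @return data.frame with `cell_id`, `richness`, `pd`, `we`, `pe`,
#'   `comp_s`, `comp_pd` and `*_scaled` variants of each numeric column.
#' @export
cell_table <- function(grid, phy) {
  sc <- species_complementarity(grid)
  pc <- phylo_complementarity(grid, phy)
  out <- data.frame(cell_id = grid$cell_ids, richness = sc$richness,
                    pd = pc$pd, we = sc$we, pe = pc$pe,
                    comp_s = sc$comp_s, comp_pd = pc$comp_pd,
                    stringsAsFactors = FALSE)
  for (col in c("richness", "pd", "we", "pe", "comp_s", "comp_pd")) {
    v <- out[[col]]
    out[[paste0(col, "_scaled")]] <-
      if (any(is.finite(v) & v > 0)) scale_to_max(v) else NaN
  }
  out
}
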