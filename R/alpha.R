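# Per-assemblage diversity: species richness, convex-hull functional
# richness in the NMDS trait space, and Faith's phylogenetic diversity
# (rooted convention by default), plus the terminal-branch grafting rule for
# species missing from the source phylogeny.

# parent lookup and per-tip root-path edge sets for a rooted phylo
.tree_paths <- function(phy) {
  validate_phylogeny(phy)
  ntip <- length(phy$tip.label)
  nnode <- max(phy$edge)
  edge_of_child <- integer(nnode)              # edge index whose child is node
  edge_of_child[phy$edge[, 2]] <- seq_len(nrow(phy$edge))
  parent <- integer(nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- ntip + 1L
  paths <- vector("list", ntip)
  for (t in seq_len(ntip)) {
    node <- t
    e <- integer(0)
    while (node != root) {
      e <- c(e, edge_of_child[node])
      node <- parent[node]
    }
    paths[[t]] <- e
  }
  names(paths) <- phy$tip.label
  list(paths = paths, lengths = phy$edge.length, root = root,
       edge_of_child = edge_of_child, parent = parent)
}

# union of root-to-tip path edge indices for a set of tip labels
.path_union <- function(tp, species) {
  unique(unlist(tp$paths[species], use.names = FALSE))
}

#' Species richness of a site
#' @param cm a [community_matrix()].
#' @param site a site id.
#' @return integer count of species present.
#' @export
richness <- function(cm, site) {
  if (!site %in% cm$site_ids) stop("unknown site: ", site)
  sum(cm$incidence[site, ] > 0)
}

#' Functional richness (FRic) of a species set
#'
#' Volume of the convex hull spanned by the species' coordinates in the
#' common trait space. Undefined (NaN, with a warning) when fewer than k+1
#' species are present or the points are affinely degenerate. Only k = 3
#' trait spaces are supported, matching the hull engine.
#'
#' @param ts a `trait_space` from [nmds_embed()].
#' @param species character vector of species ids (subset of `ts$labels`).
#' @return hull volume in trait-space units^3, or NaN when undefined.
#' @export
functional_richness <- function(ts, species) {
  unknown <- setdiff(species, ts$labels)
  if (length(unknown)) stop("unknown species: ", paste(unknown, collapse = ", "))
  if (ts$k != 3L) stop("functional_richness supports 3-D trait spaces only")
  if (length(species) < ts$k + 1L) {
    warning("fewer than k+1 species; functional richness undefined (NaN)")
    return(NaN)
  }
  hull_volume(ts$coords[species, , drop = FALSE])
}

#' Faith's phylogenetic diversity of a species set
#'
#' With `include_root = TRUE` (the default and dominant convention), the sum
#' of branch lengths over the union of root-to-tip paths of the species; a
#' single species then contributes its full root path. With
#' `include_root = FALSE`, only branches descending from the species' most
#' recent common ancestor are counted (0 for a single species).
#'
#' @param phy rooted `phylo` with branch lengths.
#' @param species character vector of tip labels.
#' @param include_root logical; see above.
#' @return summed branch length; 0 (with a warning) for an empty set.
#' @export
faith_pd <- function(phy, species, include_root = TRUE) {
  if (length(species) == 0L) {
    warning("empty species set; PD = 0")
    return(0)
  }
  unknown <- setdiff(species, phy$tip.label)
  if (length(unknown)) stop("unknown tip(s): ", paste(unknown, collapse = ", "))
  tp <- .tree_paths(phy)
  edges <- .path_union(tp, species)
  if (!include_root && length(species) >= 1L) {
    # drop edges shared by every species' root path (root-to-MRCA spine)
    shared <- Reduce(intersect, tp$paths[species])
    edges <- setdiff(edges, shared)
  }
  sum(tp$lengths[edges])
}

#' Graft a missing species onto the terminal branch of its closest relative
#'
#' The sister's terminal branch of length L is split at distance
#' `fraction * L` below the tip; the new species attaches at the split with
#' a pendant branch of the same length, so total tree length grows by
#' exactly `fraction * L`. `fraction = 0.5` keeps a positive pendant edge by
#' default; `fraction = 0` produces a zero-length cherry.
#'
#' @param phy rooted `phylo`.
#' @param new_species label to add (must not already be a tip).
#' @param sister existing tip label to attach next to.
#' @param fraction split point in `[0, 1]` measured from the tip.
#' @return the augmented `phylo`.
#' @export
graft_species <- function(phy, new_species, sister, fraction = 0.5) {
  validate_phylogeny(phy)
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (new_species %in% phy$tip.label)
    stop("tip label already present: ", new_species)
  s <- match(sister, phy$tip.label)
  if (is.na(s)) stop("sister tip not found: ", sister)
  ntip <- length(phy$tip.label)
  edge <- phy$edge
  len <- phy$edge.length
  # shift internal node ids to make room for the new tip id ntip+1
  edge[edge > ntip] <- edge[edge > ntip] + 1L
  new_tip <- ntip + 1L
  new_node <- max(edge) + 1L
  r <- which(edge[, 2] == s)
  L <- len[r]
  p <- edge[r, 1]
  edge[r, ] <- c(p, new_node)
  len[r] <- (1 - fraction) * L
  edge <- rbind(edge, c(new_node, s), c(new_node, new_tip))
  len <- c(len, fraction * L, fraction * L)
  out <- list(edge = edge, edge.length = len,
              tip.label = c(phy$tip.label, new_species),
              Nnode = phy$Nnode + 1L)
  class(out) <- "phylo"
  out <- stats::reorder(out, "cladewise")
  out
}

#' Pooled taxonomic, functional and phylogenetic diversity of a site set
#'
#' Pools the species present at any of the given sites and evaluates all
#' three facets on the pooled set. One site gives alpha diversity; all sites
#' of a habitat class give that habitat's gamma diversity.
#'
#' @param cm a [community_matrix()].
#' @param ts a `trait_space` (or NULL to skip the functional facet).
#' @param phy a `phylo` (or NULL to skip the phylogenetic facet).
#' @param sites character vector of site ids to pool.
#' @param include_root passed to [faith_pd()].
#' @return one-row data.frame: `assemblage_id`, `n_sites`, `richness`,
#'   `fric`, `pd`.
#' @export
assemblage_diversity <- function(cm, ts = NULL, phy = NULL, sites,
                                 include_root = TRUE) {
  if (length(sites) == 0L) stop("empty site list")
  unknown <- setdiff(sites, cm$site_ids)
  if (length(unknown)) stop("unknown site(s): ", paste(unknown, collapse = ", "))
  sub <- cm$incidence[sites, , drop = FALSE]
  species <- cm$species_ids[colSums(sub) > 0]
  fric <- if (is.null(ts)) NA_real_ else
    suppressWarnings(functional_richness(ts, species))
  pd <- if (is.null(phy)) NA_real_ else if (length(species) == 0L) 0 else
    faith_pd(phy, species, include_root = include_root)
  data.frame(assemblage_id = paste(sites, collapse = "+"),
             n_sites = length(sites), richness = length(species),
             fric = fric, pd = pd, stringsAsFactors = FALSE)
}

#' Per-site alpha diversity table for all sites
#' @inheritParams assemblage_diversity
#' @return data.frame with one row per site: `site_id`, `habitat`,
#'   `richness`, `fric`, `pd`.
#' @export
alpha_table <- function(cm, ts = NULL, phy = NULL, include_root = TRUE) {
  rows <- lapply(cm$site_ids, function(s) {
    r <- assemblage_diversity(cm, ts, phy, s, include_root = include_root)
    data.frame(site_id = s, habitat = cm$habitat[match(s, cm$site_ids)],
               richness = r$richness, fric = r$fric, pd = r$pd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
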