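# Pairwise Sorensen dissimilarity in its taxonomic (species-set),
# functional (hull-intersection) and phylogenetic (shared-branch, PhyloSor)
# forms. All three share the (b + c) / (2a + b + c) skeleton: a is the
# shared component, b and c are the components unique to each assemblage.

#' Taxonomic Sorensen dissimilarity between two species sets
#'
#' With a = |A intersect B|, b = |A \ B|, c = |B \ A|:
#' (b + c) / (2a + b + c). 0 for identical, 1 for disjoint sets.
#'
#' @param setA,setB character vectors of species ids.
#' @return dissimilarity in `[0, 1]`; NaN (with warning) if a set is empty.
#' @export
sorensen_taxonomic <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  if (length(setA) == 0L || length(setB) == 0L) {
    warning("empty species set; Sorensen undefined (NaN)")
    return(NaN)
  }
  a <- length(intersect(setA, setB))
  b <- length(setdiff(setA, setB))
  c <- length(setdiff(setB, setA))
  (b + c) / (2 * a + b + c)
}

#' Turnover/nestedness decomposition of taxonomic Sorensen (Baselga)
#'
#' Optional extra: beta_sor = beta_sim (turnover, Simpson) + beta_sne
#' (nestedness-resultant). Provided for the taxonomic facet only.
#'
#' @inheritParams sorensen_taxonomic
#' @return named numeric vector `c(sor, sim, sne)`.
#' @export
sorensen_partition <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  a <- length(intersect(setA, setB))
  b <- length(setdiff(setA, setB))
  c <- length(setdiff(setB, setA))
  sor <- (b + c) / (2 * a + b + c)
  sim <- min(b, c) / (a + min(b, c))
  c(sor = sor, sim = sim, sne = sor - sim)
}

#' Functional Sorensen dissimilarity from convex-hull volumes
#'
#' The shared component a is the volume of the intersection of the two
#' species sets' hulls in the common trait space; b and c are the volumes
#' unique to each hull. Pairs where either hull is undefined (< k+1 species
#' or degenerate geometry) yield NaN.
#'
#' @param ts a `trait_space`.
#' @param setA,setB character vectors of species ids.
#' @return dissimilarity in `[0, 1]`, or NaN when a hull is undefined.
#' @export
sorensen_functional <- function(ts, setA, setB) {
  vA <- suppressWarnings(functional_richness(ts, unique(setA)))
  vB <- suppressWarnings(functional_richness(ts, unique(setB)))
  if (is.nan(vA) || is.nan(vB)) {
    warning("undefined hull; functional Sorensen is NaN")
    return(NaN)
  }
  a <- hull_intersection_volume(ts$coords[unique(setA), , drop = FALSE],
                                ts$coords[unique(setB), , drop = FALSE])
  .sorensen_from_volumes(vA, vB, a)
}

.sorensen_from_volumes <- function(vA, vB, a) {
  a <- min(a, vA, vB)            # clip tiny numerical overshoot
  b <- max(vA - a, 0)
  c <- max(vB - a, 0)
  if (2 * a + b + c == 0) return(0)  # two zero-volume identical hulls
  (b + c) / (2 * a + b + c)
}

#' Phylogenetic Sorensen (PhyloSor) dissimilarity
#'
#' 1 - 2 BL_shared / (PD_A + PD_B), where PD is rooted Faith PD and
#' BL_shared is the total length of branches lying on the root-to-tip paths
#' of both species sets. 0 for identical sets; approaches 1 as the shared
#' branch length shrinks to the root.
#'
#' @param phy rooted `phylo`.
#' @param setA,setB character vectors of tip labels.
#' @return dissimilarity in `[0, 1]`; NaN for an empty set.
#' @export
sorensen_phylogenetic <- function(phy, setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  if (length(setA) == 0L || length(setB) == 0L) {
    warning("empty species set; PhyloSor undefined (NaN)")
    return(NaN)
  }
  unknown <- setdiff(c(setA, setB), phy$tip.label)
  if (length(unknown)) stop("unknown tip(s): ", paste(unknown, collapse = ", "))
  tp <- .tree_paths(phy)
  eA <- .path_union(tp, setA)
  eB <- .path_union(tp, setB)
  pdA <- sum(tp$lengths[eA])
  pdB <- sum(tp$lengths[eB])
  shared <- sum(tp$lengths[intersect(eA, eB)])
  if (pdA + pdB == 0) return(0)
  1 - 2 * shared / (pdA + pdB)
}

#' Pairwise beta-diversity matrix over a set of sites
#'
#' Fills every unordered site pair with the requested facet's Sorensen
#' dissimilarity. Functional pairs with an undefined hull propagate NaN (the
#' number of such pairs is reported via a message). Functional hulls and
#' phylogenetic path sets are precomputed once per site.
#'
#' @param cm a [community_matrix()].
#' @param facet one of `"taxonomic"`, `"functional"`, `"phylogenetic"`.
#' @param ts `trait_space`, required for the functional facet.
#' @param phy `phylo`, required for the phylogenetic facet.
#' @param sites site ids to include (default: all).
#' @return Object of class `beta_matrix`: list with `site_ids`, `facet`, and
#'   symmetric matrix `b`.
#' @export
beta_matrix <- function(cm, facet = c("taxonomic", "functional",
                                      "phylogenetic"),
                        ts = NULL, phy = NULL, sites = NULL) {
  facet <- match.arg(facet)
  if (is.null(sites)) sites <- cm$site_ids
  if (length(sites) < 2L) stop("need at least two sites")
  unknown <- setdiff(sites, cm$site_ids)
  if (length(unknown)) stop("unknown site(s): ", paste(unknown, collapse = ", "))
  n <- length(sites)
  sets <- lapply(sites, function(s) cm$species_ids[cm$incidence[s, ] > 0])
  b <- matrix(0, n, n, dimnames = list(sites, sites))

  if (facet == "taxonomic") {
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      b[i, j] <- b[j, i] <- suppressWarnings(
        sorensen_taxonomic(sets[[i]], sets[[j]]))
  } else if (facet == "phylogenetic") {
    if (is.null(phy)) stop("phylogenetic facet needs a tree")
    tp <- .tree_paths(phy)
    epaths <- lapply(sets, function(s) .path_union(tp, s))
    pds <- vapply(epaths, function(e) sum(tp$lengths[e]), 0)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (length(sets[[i]]) == 0L || length(sets[[j]]) == 0L) {
        b[i, j] <- b[j, i] <- NaN
        next
      }
      shared <- sum(tp$lengths[intersect(epaths[[i]], epaths[[j]])])
      tot <- pds[i] + pds[j]
      b[i, j] <- b[j, i] <- if (tot == 0) 0 else 1 - 2 * shared / tot
    }
  } else {
    if (is.null(ts)) stop("functional facet needs a trait space")
    hulls <- lapply(sets, function(s) {
      if (length(s) < ts$k + 1L) return(NULL)
      convex_hull_3d(ts$coords[s, , drop = FALSE])
    })
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (is.null(hulls[[i]]) || is.null(hulls[[j]])) {
        b[i, j] <- b[j, i] <- NaN
        next
      }
      a <- .hull_pair_intersection(hulls[[i]], hulls[[j]],
                                   ts$coords[sets[[i]], , drop = FALSE],
                                   ts$coords[sets[[j]], , drop = FALSE])
      b[i, j] <- b[j, i] <- .sorensen_from_volumes(hulls[[i]]$volume,
                                                   hulls[[j]]$volume, a)
    }
    nna <- sum(is.nan(b[lower.tri(b)]))
    if (nna > 0)
      message(sprintf("%d functional pair(s) undefined (degenerate hull); NaN",
                      nna))
  }
  structure(list(site_ids = sites, facet = facet, b = b),
            class = "beta_matrix")
}

#' Lower-triangle values of a beta matrix as a long pair table
#' @param bm a `beta_matrix`.
#' @param cm optional `community_matrix` to attach habitat labels.
#' @return data.frame `site_i`, `site_j`, `dissimilarity` (+ habitats).
#' @export
beta_pairs <- function(bm, cm = NULL) {
  n <- length(bm$site_ids)
  idx <- which(lower.tri(bm$b), arr.ind = TRUE)
  out <- data.frame(site_i = bm$site_ids[idx[, 2]],
                    site_j = bm$site_ids[idx[, 1]],
                    facet = bm$facet,
                    dissimilarity = bm$b[idx],
                    stringsAsFactors = FALSE)
  if (!is.null(cm)) {
    out$habitat_i <- cm$habitat[match(out$site_i, cm$site_ids)]
    out$habitat_j <- cm$habitat[match(out$site_j, cm$site_ids)]
  }
  out
}
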