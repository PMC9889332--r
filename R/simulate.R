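# Synthetic-data generator: Yule phylogenies, trait evolution (Brownian /
# Mk), habitat-structured communities with a tunable homogenization level,
# and continental grids with an endemism hotspot. The generator is a test
# harness emulating the structure of the target system (habitat pools,
# farmland homogenization, range-restricted endemics), not an inference
# target fitted to real data.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Default 11-trait schema for the synthetic amphibian trait table
#'
#' Emulates a typical anuran functional-trait set: ecological and
#' life-history categories plus continuous morphometrics (mm) and ordinal
#' webbing scores.
#'
#' @return list of per-trait specs: `name`, `kind`, and kind-specific
#'   options (`levels` for categorical/ordinal/binary, `rate`, `root`).
#' @export
default_trait_schema <- function() {
  list(
    list(name = "microhabitat", kind = "categorical",
         levels = c("aquatic", "terrestrial", "arboreal", "fossorial"),
         rate = 0.4),
    list(name = "calling_site", kind = "categorical",
         levels = c("water", "ground", "vegetation"), rate = 0.4),
    list(name = "breeding_seasonality", kind = "binary",
         levels = c("seasonal", "aseasonal"), rate = 0.3),
    list(name = "egg_site", kind = "categorical",
         levels = c("water", "leaf", "ground", "foam_nest"), rate = 0.4),
    list(name = "egg_type", kind = "categorical",
         levels = c("small_many", "large_few"), rate = 0.3),
    list(name = "tadpole_type", kind = "categorical",
         levels = c("pond", "stream", "direct"), rate = 0.4),
    list(name = "svl", kind = "continuous", rate = 1, root = 40),
    list(name = "head_width", kind = "continuous", rate = 0.5, root = 12),
    list(name = "hindlimb_length", kind = "continuous", rate = 1, root = 60),
    list(name = "webbing", kind = "ordinal", levels = 4, rate = 1, root = 0),
    list(name = "terminal_disks", kind = "binary",
         levels = c("absent", "present"), rate = 0.3)
  )
}

#' Simulation configuration with the package's stated-world defaults
#'
#' Defaults state one fixed survey-like scenario: 22 forest, 17
#' savannah and 19 farmland-pool species (16 of the farmland pool shared
#' with the natural pools, 3 farmland-exclusive); 11 forest + 11 savannah +
#' 15 farmland sites; natural species occupying spatially contiguous site
#' windows (high turnover), farmland species drawn site-independently with
#' occupancy pushed toward 1 by the homogenization level `h`; and a
#' continental grid whose hotspot cells hold the range-restricted natural
#' endemics while farmland species are widespread.
#'
#' @param n_species_forest,n_species_savannah,n_species_farmland pool sizes.
#' @param shared_farmland_fraction fraction of the farmland pool drawn from
#'   the natural pools (trait-space-central species preferred).
#' @param n_sites named vector of per-habitat site counts.
#' @param occupancy_natural,occupancy_farmland baseline per-species
#'   site-occupancy probabilities in `[0, 1]`.
#' @param homogenization_h in `[0, 1]`: farmland occupancy becomes
#'   `(1 - h) * occupancy_farmland + h`.
#' @param centrality_quantile farmland shared species are drawn from the
#'   most trait-space-central natural species up to this quantile.
#' @param trait_schema list of trait specs (see [default_trait_schema()]).
#' @param birth_rate Yule speciation rate for the tree.
#' @param n_species_grid_extra grid-only species added to the tree so the
#'   continental grid is richer than the local community.
#' @param n_cells number of grid cells (1-D continental strip).
#' @param range_size_distribution list(meanlog, sdlog) for lognormal range
#'   sizes in cells.
#' @param hotspot_cells integer indices of the endemism-hotspot cells.
#' @param seed integer master seed; all generators derive sub-seeds from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_species_forest = 22, n_species_savannah = 17,
                       n_species_farmland = 19,
                       shared_farmland_fraction = 16 / 19,
                       n_sites = c(forest = 11, savannah = 11, farmland = 15),
                       occupancy_natural = 0.30, occupancy_farmland = 0.45,
                       homogenization_h = 0.5, centrality_quantile = 0.5,
                       trait_schema = default_trait_schema(),
                       birth_rate = 1, n_species_grid_extra = 40,
                       n_cells = 100,
                       range_size_distribution = list(meanlog = log(8),
                                                      sdlog = 1),
                       hotspot_cells = 45:47, seed = 1) {
  cfg <- list(n_species_forest = n_species_forest,
              n_species_savannah = n_species_savannah,
              n_species_farmland = n_species_farmland,
              shared_farmland_fraction = shared_farmland_fraction,
              n_sites = n_sites, occupancy_natural = occupancy_natural,
              occupancy_farmland = occupancy_farmland,
              homogenization_h = homogenization_h,
              centrality_quantile = centrality_quantile,
              trait_schema = trait_schema, birth_rate = birth_rate,
              n_species_grid_extra = n_species_grid_extra,
              n_cells = n_cells,
              range_size_distribution = range_size_distribution,
              hotspot_cells = hotspot_cells, seed = seed)
  probs <- c(cfg$shared_farmland_fraction, cfg$occupancy_natural,
             cfg$occupancy_farmland, cfg$homogenization_h,
             cfg$centrality_quantile)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  counts <- c(cfg$n_species_forest, cfg$n_species_savannah,
              cfg$n_species_farmland, cfg$n_sites, cfg$n_cells)
  if (any(counts < 1)) stop("counts must be positive")
  if (is.null(names(cfg$n_sites))) stop("n_sites must be named by habitat")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a pure-birth (Yule) phylogeny with a fixed number of tips
#'
#' Forward simulation: starting from two lineages at the root, each epoch
#' with k lineages lasts Exp(k * birth_rate) and ends with a uniformly
#' chosen lineage splitting; after the n-th lineage appears one final
#' Exp(n * birth_rate) epoch brings the tips to the present. Expected total
#' tree length is (n - 1) / birth_rate with variance (n - 1) / birth_rate^2.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate (> 0).
#' @param seed optional integer seed; same seed, same Newick string.
#' @param tip_prefix label prefix (tips are labelled in lineage-creation
#'   order, `sp01`, `sp02`, ...).
#' @return a rooted `phylo` with strictly positive branch lengths (a.s.).
#' @export
simulate_phylogeny <- function(n_tips, birth_rate = 1, seed = NULL,
                               tip_prefix = "sp") {
  if (n_tips < 2) stop("n_tips must be at least 2")
  if (birth_rate <= 0) stop("birth_rate must be positive")
  .with_seed(seed, {
    parent <- c(0L, 1L, 1L)
    blen <- c(NA_real_, 0, 0)
    active <- c(2L, 3L)
    nid <- 3L
    while (length(active) < n_tips) {
      k <- length(active)
      dt <- stats::rexp(1, k * birth_rate)
      blen[active] <- blen[active] + dt
      a <- active[sample.int(k, 1)]
      kids <- nid + 1:2
      nid <- nid + 2L
      parent[kids] <- a
      blen[kids] <- 0
      active <- c(setdiff(active, a), kids)
    }
    dt <- stats::rexp(1, n_tips * birth_rate)
    blen[active] <- blen[active] + dt

    # convert to ape numbering: tips 1..n, root n+1, other internals n+2..
    tips <- sort(active)
    internals <- setdiff(seq_len(nid), tips)  # includes root id 1
    map <- integer(nid)
    map[tips] <- seq_len(n_tips)
    map[internals] <- n_tips + seq_along(internals)
    children <- setdiff(seq_len(nid), 1L)
    edge <- cbind(map[parent[children]], map[children])
    phy <- list(edge = edge, edge.length = blen[children],
                tip.label = sprintf("%s%02d", tip_prefix, seq_len(n_tips)),
                Nnode = n_tips - 1L)
    class(phy) <- "phylo"
    phy <- stats::reorder(phy, "cladewise")
    phy
  })
}

#' Evolve a trait table along a phylogeny
#'
#' Continuous traits evolve by Brownian motion (per-edge normal increments
#' with variance rate * branch length); categorical and binary traits by a
#' symmetric Mk process (per-edge stay probability
#' 1/s + (1 - 1/s) exp(-s * rate * t)); ordinal traits evolve as a latent
#' Brownian trait discretised into the requested number of levels by tip
#' quantiles.
#'
#' @param phy rooted `phylo` with branch lengths.
#' @param trait_schema list of trait specs (see [default_trait_schema()]).
#' @param seed optional integer seed.
#' @return a [trait_table()] with one row per tip.
#' @export
simulate_traits <- function(phy, trait_schema = default_trait_schema(),
                            seed = NULL) {
  validate_phylogeny(phy)
  if (!length(trait_schema)) stop("trait schema must be non-empty")
  ntip <- length(phy$tip.label)
  phy <- stats::reorder(phy, "cladewise")
  nn <- max(phy$edge)
  root <- ntip + 1L

  bm_tips <- function(rate, root_value) {
    val <- rep(NA_real_, nn)
    val[root] <- root_value
    for (r in seq_len(nrow(phy$edge))) {
      p <- phy$edge[r, 1]; ch <- phy$edge[r, 2]
      val[ch] <- val[p] + stats::rnorm(1, sd = sqrt(rate * phy$edge.length[r]))
    }
    val[seq_len(ntip)]
  }
  mk_tips <- function(rate, levels) {
    s <- length(levels)
    st <- rep(NA_integer_, nn)
    st[root] <- sample.int(s, 1)
    for (r in seq_len(nrow(phy$edge))) {
      p <- phy$edge[r, 1]; ch <- phy$edge[r, 2]
      t <- phy$edge.length[r]
      p_same <- 1 / s + (1 - 1 / s) * exp(-s * rate * t)
      st[ch] <- if (stats::runif(1) < p_same) st[p] else {
        others <- setdiff(seq_len(s), st[p])
        others[sample.int(length(others), 1)]
      }
    }
    levels[st[seq_len(ntip)]]
  }

  cols <- list()
  kinds <- character(0)
  .with_seed(seed, {
    for (spec in trait_schema) {
      kind <- spec$kind
      rate <- if (is.null(spec$rate)) 1 else spec$rate
      if (kind == "continuous") {
        cols[[spec$name]] <- bm_tips(rate, if (is.null(spec$root)) 0 else spec$root)
      } else if (kind == "ordinal") {
        lat <- bm_tips(rate, if (is.null(spec$root)) 0 else spec$root)
        L <- if (is.null(spec$levels)) 4L else
          if (is.numeric(spec$levels)) as.integer(spec$levels) else
            length(spec$levels)
        if (length(unique(lat)) == 1L) {
          cols[[spec$name]] <- rep(1L, ntip)  # zero-rate limit
        } else {
          br <- unique(stats::quantile(lat, probs = seq(0, 1, length.out = L + 1)))
          cols[[spec$name]] <- as.integer(cut(lat, breaks = br,
                                              include.lowest = TRUE))
        }
      } else if (kind %in% c("categorical", "binary")) {
        lv <- spec$levels
        if (is.null(lv)) stop("categorical/binary trait needs levels: ",
                              spec$name)
        cols[[spec$name]] <- mk_tips(rate, lv)
      } else {
        stop("unknown trait kind: ", kind)
      }
      kinds[spec$name] <- kind
    }
  })
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  rownames(df) <- phy$tip.label
  trait_table(df, kinds = kinds)
}

# habitat pools from tip labels; farmland pool preferentially trait-central
.assign_pools <- function(cfg, phy, tt = NULL) {
  tips <- phy$tip.label
  nf <- cfg$n_species_forest
  ns <- cfg$n_species_savannah
  n_shared <- round(cfg$shared_farmland_fraction * cfg$n_species_farmland)
  n_excl <- cfg$n_species_farmland - n_shared
  if (nf + ns + n_excl > length(tips))
    stop(sprintf("pools need %d species but tree has %d tips",
                 nf + ns + n_excl, length(tips)))
  forest <- tips[seq_len(nf)]
  savannah <- tips[nf + seq_len(ns)]
  natural <- c(forest, savannah)
  if (!is.null(tt) && n_shared > 0) {
    # centrality = mean Gower distance to all other species (lower = central)
    g <- gower_distance(tt)
    cent <- rowMeans(g$d[natural, , drop = FALSE])
    n_cand <- max(ceiling(cfg$centrality_quantile * length(natural)), n_shared)
    candidates <- natural[order(cent)][seq_len(n_cand)]
    shared <- sample(candidates, n_shared)
  } else {
    shared <- sample(natural, n_shared)
  }
  exclusive <- tips[nf + ns + seq_len(n_excl)]
  list(forest = forest, savannah = savannah,
       farmland = c(shared, exclusive), shared = shared,
       exclusive = exclusive)
}

#' Simulate a habitat-structured community matrix
#'
#' Natural (forest/savannah) species each occupy a contiguous circular
#' window of sites within their habitat, of width
#' `round(occupancy_natural * n_sites)`, at a random position -- giving the
#' intended mean alpha diversity together with high spatial turnover.
#' Farmland species occur independently at every farmland site with
#' probability `(1 - h) * occupancy_farmland + h`, so `h = 1` forces all
#' farmland communities identical (taxonomic beta 0) and expected farmland
#' richness exceeds expected natural richness under the defaults.
#'
#' @param cfg a [sim_config()].
#' @param phy `phylo` whose tips supply the species pools.
#' @param tt optional [trait_table()]; when given, the shared farmland pool
#'   is drawn from the most trait-space-central natural species (emulating
#'   trait nestedness of farmland communities).
#' @param seed optional integer seed (defaults to `cfg$seed + 3`).
#' @return a [community_matrix()] with site elevations.
#' @export
simulate_communities <- function(cfg, phy, tt = NULL, seed = NULL) {
  if (is.null(seed)) seed <- cfg$seed + 3L
  .with_seed(seed, {
    pools <- .assign_pools(cfg, phy, tt)
    hs <- names(cfg$n_sites)
    site_ids <- unlist(lapply(hs, function(h)
      sprintf("%s_%02d", substr(h, 1, 3), seq_len(cfg$n_sites[[h]]))),
      use.names = FALSE)
    habitat <- rep(hs, cfg$n_sites)
    elev_rng <- list(forest = c(1804, 3031), savannah = c(1287, 1642),
                     farmland = c(1292, 2348))
    elevation <- unlist(lapply(hs, function(h) {
      r <- if (h %in% names(elev_rng)) elev_rng[[h]] else c(1000, 2000)
      round(stats::runif(cfg$n_sites[[h]], r[1], r[2]))
    }), use.names = FALSE)
    inc <- matrix(0, length(site_ids), length(phy$tip.label),
                  dimnames = list(site_ids, phy$tip.label))
    for (h in hs) {
      rows <- which(habitat == h)
      nh <- length(rows)
      if (h == "farmland") {
        p_eff <- (1 - cfg$homogenization_h) * cfg$occupancy_farmland +
          cfg$homogenization_h
        draws <- matrix(stats::runif(nh * length(pools$farmland)) < p_eff,
                        nh, length(pools$farmland))
        inc[rows, pools$farmland] <- draws * 1
      } else if (h %in% c("forest", "savannah")) {
        pool <- pools[[h]]
        w <- max(1L, round(cfg$occupancy_natural * nh))
        for (sp in pool) {
          start <- sample.int(nh, 1)
          win <- ((start - 1L + seq_len(w) - 1L) %% nh) + 1L  # circular
          inc[rows[win], sp] <- 1
        }
      }
    }
    community_matrix(inc, habitat = habitat, elevation_m = elevation)
  })
}

#' Simulate a continental grid with an endemism hotspot
#'
#' Each species receives a contiguous range of cells on a 1-D continental
#' strip, with size drawn from the configured lognormal distribution
#' (clipped to the grid with a warning). Species listed in
#' `endemic_species` instead get 1-3-cell ranges placed inside the hotspot
#' cells; species in `widespread_species` get ranges of at least 40% of the
#' grid. Cell centroids are reported as strip coordinates.
#'
#' @param cfg a [sim_config()].
#' @param phy `phylo` whose tips are the grid species.
#' @param endemic_species,widespread_species optional tip-label subsets.
#' @param seed optional integer seed (defaults to `cfg$seed + 4`).
#' @return a [grid_assemblage()].
#' @export
simulate_grid <- function(cfg, phy, endemic_species = NULL,
                          widespread_species = NULL, seed = NULL) {
  if (is.null(seed)) seed <- cfg$seed + 4L
  nc <- cfg$n_cells
  if (nc < 2) stop("n_cells must be at least 2")
  .with_seed(seed, {
    sp <- phy$tip.label
    hot <- cfg$hotspot_cells
    if (length(hot) && (min(hot) < 1 || max(hot) > nc))
      stop("hotspot_cells out of range")
    sizes <- round(stats::rlnorm(length(sp),
                                 cfg$range_size_distribution$meanlog,
                                 cfg$range_size_distribution$sdlog))
    sizes <- pmax(sizes, 1L)
    if (any(sizes > nc)) {
      warning(sum(sizes > nc), " range size(s) exceed the grid; clipped")
      sizes <- pmin(sizes, nc)
    }
    names(sizes) <- sp
    if (!is.null(widespread_species))
      sizes[widespread_species] <- pmax(sizes[widespread_species],
                                        round(0.4 * nc))
    if (!is.null(endemic_species) && length(hot))
      sizes[endemic_species] <- sample(1:3, length(endemic_species),
                                       replace = TRUE)
    inc <- matrix(0, nc, length(sp),
                  dimnames = list(sprintf("cell_%03d", seq_len(nc)), sp))
    for (s in sp) {
      sz <- min(sizes[[s]], nc)
      if (!is.null(endemic_species) && s %in% endemic_species &&
          length(hot)) {
        start <- hot[sample.int(length(hot), 1)]
        cells <- start:min(start + sz - 1L, nc)
      } else {
        start <- sample.int(nc - sz + 1L, 1)
        cells <- start:(start + sz - 1L)
      }
      inc[cells, s] <- 1
    }
    grid_assemblage(inc, cell_lonlat = cbind(lon = seq_len(nc) - 0.5,
                                             lat = rep(0.5, nc)))
  })
}

#' Generate a complete cross-congruent synthetic dataset
#'
#' Tree (community pools plus grid-only species), traits for every tip,
#' habitat-structured communities, and a continental grid in which the
#' natural-pool species are hotspot endemics and the farmland-pool species
#' are widespread. The result always passes [validate_dataset()] with zero
#' errors; `truth` records the generating configuration and pools.
#'
#' @param cfg a [sim_config()].
#' @return list of class `synthetic_dataset`: `cm`, `tt`, `phy`, `grid`,
#'   `truth`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  n_shared <- round(cfg$shared_farmland_fraction * cfg$n_species_farmland)
  n_comm <- cfg$n_species_forest + cfg$n_species_savannah +
    (cfg$n_species_farmland - n_shared)
  n_total <- n_comm + cfg$n_species_grid_extra
  phy <- simulate_phylogeny(n_total, cfg$birth_rate, seed = cfg$seed + 1L)
  tt <- simulate_traits(phy, cfg$trait_schema, seed = cfg$seed + 2L)
  pools <- .with_seed(cfg$seed + 3L, .assign_pools(cfg, phy, tt))
  cm_full <- simulate_communities(cfg, phy, tt, seed = cfg$seed + 3L)
  comm_sp <- unique(c(pools$forest, pools$savannah, pools$farmland))
  cm <- community_matrix(cm_full$incidence[, comm_sp, drop = FALSE],
                         habitat = cm_full$habitat,
                         elevation_m = cm_full$elevation_m)
  grid <- simulate_grid(cfg, phy,
                        endemic_species = c(pools$forest, pools$savannah),
                        widespread_species = pools$farmland,
                        seed = cfg$seed + 4L)
  structure(list(cm = cm, tt = tt, phy = phy, grid = grid,
                 truth = list(config = cfg, pools = pools)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset\n")
  print(x$cm)
  print(x$tt)
  cat(sprintf("phylogeny: %d tips, total length %.3f\n",
              length(x$phy$tip.label), sum(x$phy$edge.length)))
  print(x$grid)
  invisible(x)
}
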