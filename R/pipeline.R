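# End-to-end orchestration: one call reproduces the full analysis (alpha,
# beta, subsampled gamma, contrasts, accumulation, grid complementarity)
# from a config, writing plain CSV outputs plus a JSON manifest. A single
# master seed is fanned out to per-stage sub-seeds by fixed offsets, so
# adding a stage never perturbs earlier stages' randomness.

#' Build a pipeline configuration
#'
#' @param community,traits,traits_schema,tree,grid input file paths
#'   (community/traits/tree required; grid optional).
#' @param replacements optional named list (or JSON path) of grid-cell
#'   replacements for the counterfactual analysis.
#' @param out_dir output directory (created if absent).
#' @param k,n_starts NMDS options.
#' @param n_draws subsampled-gamma draw count.
#' @param group_sizes named habitat -> site count vector for the natural
#'   gamma subsample (default forest 7, savannah 8).
#' @param contrast_groups length-2 list of habitat-label vectors defining
#'   the two contrast groups (default natural = forest+savannah vs
#'   farmland).
#' @param elevation_max optional elevation ceiling applied before analysis.
#' @param seed master integer seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(community, traits, traits_schema, tree,
                            grid = NULL, replacements = NULL,
                            out_dir = ".", k = 3, n_starts = 20,
                            n_draws = 1000,
                            group_sizes = c(forest = 7, savannah = 8),
                            contrast_groups = list(
                              natural = c("forest", "savannah"),
                              farmland = "farmland"),
                            elevation_max = NULL, seed = 1) {
  cfg <- as.list(environment())
  for (f in c("community", "traits", "traits_schema", "tree"))
    if (!file.exists(cfg[[f]])) stop("input file not found: ", cfg[[f]])
  if (!is.null(grid) && !file.exists(grid))
    stop("input file not found: ", grid)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full diversity pipeline
#'
#' Stages: read + validate inputs; (optional) elevation filter; Gower +
#' NMDS trait space; per-site alpha table; within-habitat pairwise beta
#' (all three facets); subsampled natural gamma vs pooled farmland gamma;
#' habitat contrasts (Welch t, medians/IQR) for alpha and beta; exact
#' species-accumulation curves per group; and, when a grid is supplied,
#' the per-cell complementarity table (with optional cell replacement).
#' All outputs are CSV; `manifest.json` records the seed, options and
#' per-stage row counts. Rerunning with the same config and seed reproduces
#' byte-identical outputs. Any stage failure aborts with the stage name and
#' removes partial outputs.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a named list of the output file paths plus the main
#'   in-memory results.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  say <- function(...) if (!quiet) message(sprintf(...))
  emit <- function(df, name) {
    p <- file.path(cfg$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    written <<- c(written, p)
    p
  }
  stage <- "read inputs"
  res <- tryCatch({
    cm <- read_community_csv(cfg$community)
    tt <- read_trait_csv(cfg$traits, cfg$traits_schema)
    phy <- read_newick(cfg$tree)
    grid <- if (is.null(cfg$grid)) NULL else read_grid_csv(cfg$grid)
    .assert_valid(cm, tt, phy, grid)

    if (!is.null(cfg$elevation_max)) {
      stage <- "elevation filter"
      n0 <- length(cm$site_ids)
      cm <- elevation_filter(cm, cfg$elevation_max)
      say("elevation filter <= %s m: %d of %d sites kept",
          cfg$elevation_max, length(cm$site_ids), n0)
    }

    stage <- "trait space"
    ts <- nmds_embed(gower_distance(tt), k = cfg$k,
                     n_starts = cfg$n_starts, seed = cfg$seed + 10L)
    say("NMDS stress-1 = %.4g", ts$stress)
    emit(data.frame(species_id = ts$labels, ts$coords,
                    stress = ts$stress), "space.csv")

    stage <- "alpha"
    alpha <- alpha_table(cm, ts, phy)
    emit(alpha, "alpha.csv")

    stage <- "beta"
    beta <- do.call(rbind, lapply(
      c("taxonomic", "functional", "phylogenetic"), function(f) {
        do.call(rbind, lapply(unique(cm$habitat), function(h) {
          sites <- cm$site_ids[cm$habitat == h]
          if (length(sites) < 2L) return(NULL)
          bm <- suppressMessages(
            beta_matrix(cm, f, ts = ts, phy = phy, sites = sites))
          cbind(beta_pairs(bm), habitat_class = h)
        }))
      }))
    emit(beta, "beta.csv")

    stage <- "gamma"
    gamma_rows <- do.call(rbind, lapply(
      c("taxonomic", "functional", "phylogenetic"), function(f) {
        gs <- cfg$group_sizes[names(cfg$group_sizes) %in% cm$habitat]
        avail <- vapply(names(gs), function(h) sum(cm$habitat == h), 0L)
        if (any(gs > avail)) {
          say("gamma subsample sizes capped at available sites (%s)",
              paste(sprintf("%s=%d", names(gs), pmin(gs, avail)),
                    collapse = ", "))
          gs <- pmin(gs, avail)
        }
        nat <- subsample_gamma(cm, ts, phy, gs, n_draws = cfg$n_draws,
                               facet = f, seed = cfg$seed + 20L)
        farm_sites <- cm$site_ids[cm$habitat == "farmland"]
        farm <- assemblage_diversity(cm, ts, phy, farm_sites)
        farm_g <- switch(f, taxonomic = farm$richness,
                         functional = farm$fric, phylogenetic = farm$pd)
        data.frame(facet = f,
                   habitat_class = c(nat$habitat_class, "farmland"),
                   draws = c(nat$draws, 1),
                   median = c(nat$median, farm_g),
                   sd = c(nat$sd, 0),
                   min = c(nat$min, farm_g), max = c(nat$max, farm_g))
      }))
    emit(gamma_rows, "gamma.csv")

    stage <- "contrasts"
    grp <- function(labels) alpha$site_id[alpha$habitat %in% labels]
    g1 <- grp(cfg$contrast_groups[[1]]); g2 <- grp(cfg$contrast_groups[[2]])
    gl <- names(cfg$contrast_groups)
    contr <- list()
    for (m in c("richness", "fric", "pd")) {
      x <- alpha[[m]][alpha$site_id %in% g1]
      y <- alpha[[m]][alpha$site_id %in% g2]
      ct <- compare_groups(x, y, labels = gl)
      contr[[paste0("alpha_", m)]] <- ct
    }
    for (f in unique(beta$facet)) {
      sel <- beta$facet == f
      inA <- beta$habitat_class[sel] %in% cfg$contrast_groups[[1]]
      inB <- beta$habitat_class[sel] %in% cfg$contrast_groups[[2]]
      ct <- suppressWarnings(compare_groups(
        beta$dissimilarity[sel][inA], beta$dissimilarity[sel][inB],
        labels = gl, values_are_pairwise = TRUE))
      contr[[paste0("beta_", f)]] <- ct
    }
    say("note: beta contrasts use non-independent pairwise values")
    cdf <- do.call(rbind, lapply(names(contr), function(nm) {
      ct <- contr[[nm]]
      data.frame(metric = nm, t = ct$t, df = ct$df, p = ct$p,
                 median_1 = ct$median[1], iqr_1 = ct$iqr[1],
                 median_2 = ct$median[2], iqr_2 = ct$iqr[2])
    }))
    emit(cdf, "contrasts.csv")

    stage <- "accumulation"
    curve <- do.call(rbind, lapply(names(cfg$contrast_groups), function(g) {
      sites <- grp(cfg$contrast_groups[[g]])
      cbind(group = g, accumulation_curve(cm, sites, mode = "exact"))
    }))
    emit(curve, "curve.csv")

    cells <- NULL
    if (!is.null(grid)) {
      stage <- "complementarity"
      repl <- cfg$replacements
      if (is.character(repl) && length(repl) == 1L)
        repl <- jsonlite::read_json(repl, simplifyVector = TRUE)
      if (!is.null(repl)) grid <- replace_cells(grid, repl)
      cells <- cell_table(grid, phy)
      emit(cells, "cells.csv")
    }

    stage <- "manifest"
    manifest <- list(seed = cfg$seed,
                     options = cfg[c("k", "n_starts", "n_draws",
                                     "group_sizes", "elevation_max")],
                     nmds_stress = ts$stress,
                     rows = list(alpha = nrow(alpha), beta = nrow(beta),
                                 gamma = nrow(gamma_rows),
                                 contrasts = nrow(cdf), curve = nrow(curve),
                                 cells = if (is.null(cells)) 0
                                         else nrow(cells)))
    mpath <- file.path(cfg$out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         null = "null")
    written <- c(written, mpath)
    list(files = written, alpha = alpha, beta = beta, gamma = gamma_rows,
         contrasts = contr, curve = curve, cells = cells, trait_space = ts)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

#' Write a synthetic dataset to a directory of standard files
#'
#' Writes `community.csv`, `traits.csv`, `traits.schema.json`, `tree.nwk`,
#' `grid.csv` and `truth.json` -- the on-disk form consumed by
#' [pipeline_config()].
#'
#' @param ds a `synthetic_dataset` from [simulate_dataset()].
#' @param dir output directory.
#' @return invisibly, the named vector of paths.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(community = file.path(dir, "community.csv"),
             traits = file.path(dir, "traits.csv"),
             schema = file.path(dir, "traits.schema.json"),
             tree = file.path(dir, "tree.nwk"),
             grid = file.path(dir, "grid.csv"),
             truth = file.path(dir, "truth.json"))
  write_community_csv(ds$cm, paths[["community"]])
  write_trait_csv(ds$tt, paths[["traits"]], schema_path = paths[["schema"]])
  write_newick(ds$phy, paths[["tree"]])
  write_grid_csv(ds$grid, paths[["grid"]])
  truth <- ds$truth
  truth$config <- unclass(truth$config)
  truth$config$trait_schema <- NULL  # nested specs; schema file carries kinds
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Command-line entry point
#'
#' Minimal subcommand dispatcher used by `inst/cli/divfacets.R`:
#' `simulate --seed S --out-dir DIR`, and
#' `run --data-dir DIR --out-dir DIR [--seed S] [--draws N] [--elevation-max M]`
#' (run expects the file layout written by `simulate`).
#'
#' @param args character vector of command-line arguments.
#' @return invisibly, the result of the subcommand.
#' @export
divfacets_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: divfacets <simulate|run> [options]",
    "  simulate --seed S --out-dir DIR",
    "  run --data-dir DIR --out-dir DIR [--seed S] [--draws N]",
    "      [--elevation-max M]", sep = "\n")
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (!length(i)) return(default)
    args[i[1] + 1L]
  }
  if (cmd == "simulate") {
    seed <- as.integer(opt("--seed", "1"))
    dir <- opt("--out-dir", ".")
    ds <- simulate_dataset(sim_config(seed = seed))
    p <- write_dataset(ds, dir)
    message("wrote ", length(p), " files to ", dir)
    return(invisible(p))
  }
  if (cmd == "run") {
    dd <- opt("--data-dir")
    if (is.null(dd)) stop(usage, call. = FALSE)
    em <- opt("--elevation-max")
    cfg <- pipeline_config(
      community = file.path(dd, "community.csv"),
      traits = file.path(dd, "traits.csv"),
      traits_schema = file.path(dd, "traits.schema.json"),
      tree = file.path(dd, "tree.nwk"),
      grid = if (file.exists(file.path(dd, "grid.csv")))
        file.path(dd, "grid.csv") else NULL,
      out_dir = opt("--out-dir", "."),
      n_draws = as.integer(opt("--draws", "1000")),
      elevation_max = if (is.null(em)) NULL else as.numeric(em),
      seed = as.integer(opt("--seed", "1")))
    return(invisible(run_pipeline(cfg)))
  }
  stop(usage, call. = FALSE)
}
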