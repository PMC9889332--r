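#' Construct a site-by-species community matrix
#'
#' The central container for local assemblage data: a binary site x species
#' incidence matrix with one habitat label per site and optional site
#' elevations. All downstream alpha/beta/gamma operations consume this class.
#'
#' @param incidence numeric matrix of 0/1 with sites in rows and species in
#'   columns; must carry unique row and column names.
#' @param habitat character vector, one label per site; normalised to lower
#'   case. Conventional labels are `"forest"`, `"savannah"`, `"farmland"`;
#'   anything else is kept as `"other"`-style free text.
#' @param elevation_m optional numeric vector of site elevations in metres
#'   above sea level; non-negative where present.
#' @return An object of class `community_matrix`: a list with elements
#'   `incidence`, `site_ids`, `species_ids`, `habitat`, `elevation_m`.
#' @examples
#' m <- matrix(c(1, 0, 1, 1, 0, 1), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("spA", "spB", "spC")))
#' cm <- community_matrix(m, habitat = c("forest", "farmland"))
#' richness(cm, "s1")
#' @export
community_matrix <- function(incidence, habitat, elevation_m = NULL) {
  incidence <- as.matrix(incidence)
  storage.mode(incidence) <- "double"
  if (is.null(rownames(incidence)) || is.null(colnames(incidence)))
    stop("incidence must have site row names and species column names")
  site_ids <- trimws(rownames(incidence))
  species_ids <- trimws(colnames(incidence))
  if (anyDuplicated(site_ids)) stop("duplicate site ids: ",
    paste(unique(site_ids[duplicated(site_ids)]), collapse = ", "))
  if (anyDuplicated(species_ids)) stop("duplicate species ids: ",
    paste(unique(species_ids[duplicated(species_ids)]), collapse = ", "))
  bad <- which(!(incidence %in% c(0, 1)) | is.na(incidence))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(incidence)) + 1
    j <- ((bad[1] - 1) %/% nrow(incidence)) + 1
    stop(sprintf("non-binary incidence value %s at site '%s', species '%s'",
                 format(incidence[bad[1]]), site_ids[i], species_ids[j]))
  }
  habitat <- tolower(trimws(as.character(habitat)))
  if (length(habitat) != nrow(incidence))
    stop("need one habitat label per site")
  if (anyNA(habitat) || any(!nzchar(habitat)))
    stop("habitat label missing for some sites")
  if (!is.null(elevation_m)) {
    elevation_m <- as.numeric(elevation_m)
    if (length(elevation_m) != nrow(incidence))
      stop("need one elevation per site (or NULL)")
    if (any(elevation_m < 0, na.rm = TRUE))
      stop("elevations must be non-negative")
  }
  rownames(incidence) <- site_ids
  colnames(incidence) <- species_ids
  structure(list(incidence = incidence, site_ids = site_ids,
                 species_ids = species_ids, habitat = habitat,
                 elevation_m = elevation_m),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d sites x %d species\n",
              length(x$site_ids), length(x$species_ids)))
  cat("habitats:", paste(sprintf("%s (%d)", names(table(x$habitat)),
                                 table(x$habitat)), collapse = ", "), "\n")
  if (!is.null(x$elevation_m))
    cat(sprintf("elevation: %.0f-%.0f m\n", min(x$elevation_m),
                max(x$elevation_m)))
  invisible(x)
}

#' Construct a species-by-trait table with declared trait kinds
#'
#' @param data data.frame of trait values with one row per species; row names
#'   (or a `species_id` column) give species ids.
#' @param kinds named character vector declaring, for every trait column, one
#'   of `"continuous"`, `"ordinal"`, `"categorical"`, `"binary"`.
#' @param units optional named character vector of units for continuous
#'   traits (e.g. `"mm"` for morphometrics).
#' @return Object of class `trait_table`: list with `species_ids`, `data`,
#'   `kinds`, `units`. Missing values are permitted and later handled by
#'   pairwise deletion inside [gower_distance()].
#' @export
trait_table <- function(data, kinds, units = NULL) {
  data <- as.data.frame(data)
  if ("species_id" %in% names(data)) {
    rownames(data) <- trimws(as.character(data$species_id))
    data$species_id <- NULL
  }
  species_ids <- trimws(rownames(data))
  if (anyDuplicated(species_ids)) stop("duplicate species ids: ",
    paste(unique(species_ids[duplicated(species_ids)]), collapse = ", "))
  if (ncol(data) < 1L) stop("need at least one trait column")
  if (is.null(names(kinds)) || !all(names(data) %in% names(kinds)))
    stop("undeclared trait column(s): ",
         paste(setdiff(names(data), names(kinds)), collapse = ", "))
  absent <- setdiff(names(kinds), names(data))
  if (length(absent))
    stop("schema declares column(s) absent from data: ",
         paste(absent, collapse = ", "))
  ok <- c("continuous", "ordinal", "categorical", "binary")
  if (!all(kinds %in% ok))
    stop("unknown trait kind(s): ", paste(setdiff(kinds, ok), collapse = ", "))
  for (nm in names(data)) {
    k <- kinds[[nm]]
    if (k %in% c("continuous", "ordinal")) {
      v <- suppressWarnings(as.numeric(as.character(data[[nm]])))
      introduced <- which(is.na(v) & !is.na(data[[nm]]) &
                            nzchar(trimws(as.character(data[[nm]]))))
      if (length(introduced))
        stop(sprintf("non-numeric value '%s' in %s trait '%s' (species '%s')",
                     data[[nm]][introduced[1]], k, nm,
                     species_ids[introduced[1]]))
      if (any(is.infinite(v)))
        stop(sprintf("non-finite value in trait '%s'", nm))
      data[[nm]] <- v
    } else {
      data[[nm]] <- as.character(data[[nm]])
      data[[nm]][!nzchar(trimws(ifelse(is.na(data[[nm]]), "",
                                       data[[nm]])))] <- NA_character_
      if (k == "binary" && length(setdiff(unique(stats::na.omit(data[[nm]])),
                                          character(0))) > 2L)
        stop(sprintf("binary trait '%s' has more than two levels", nm))
    }
  }
  nmiss <- sum(is.na(as.matrix(data)))
  if (nmiss > 0)
    warning(sprintf("%d missing trait value(s); Gower will use pairwise deletion",
                    nmiss))
  structure(list(species_ids = species_ids, data = data,
                 kinds = kinds[names(data)], units = units),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("trait_table: %d species x %d traits (%s)\n",
              length(x$species_ids), ncol(x$data),
              paste(sprintf("%s:%s", names(x$kinds), unname(x$kinds)),
                    collapse = ", ")))
  invisible(x)
}

#' Construct a cell-by-species grid assemblage
#'
#' Continental-scale container: binary incidence of species over grid cells
#' (e.g. 1-degree cells), with optional cell centroids for mapping.
#'
#' @param incidence binary cell x species matrix with unique dimnames.
#' @param cell_lonlat optional 2-column matrix of centroid degrees per cell.
#' @return Object of class `grid_assemblage`.
#' @export
grid_assemblage <- function(incidence, cell_lonlat = NULL) {
  incidence <- as.matrix(incidence)
  storage.mode(incidence) <- "double"
  if (is.null(rownames(incidence)) || is.null(colnames(incidence)))
    stop("incidence must have cell row names and species column names")
  cell_ids <- trimws(rownames(incidence))
  species_ids <- trimws(colnames(incidence))
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (anyDuplicated(species_ids)) stop("duplicate species ids")
  if (!all(incidence %in% c(0, 1)))
    stop("grid incidence entries must be 0/1")
  if (!is.null(cell_lonlat)) {
    cell_lonlat <- as.matrix(cell_lonlat)
    if (nrow(cell_lonlat) != nrow(incidence) || ncol(cell_lonlat) != 2L)
      stop("cell_lonlat must be a cells x 2 matrix")
  }
  structure(list(incidence = incidence, cell_ids = cell_ids,
                 species_ids = species_ids, cell_lonlat = cell_lonlat),
            class = "grid_assemblage")
}

#' @export
print.grid_assemblage <- function(x, ...) {
  cat(sprintf("grid_assemblage: %d cells x %d species (%d empty cells)\n",
              length(x$cell_ids), length(x$species_ids),
              sum(rowSums(x$incidence) == 0)))
  invisible(x)
}

# ---- CSV / Newick i/o -------------------------------------------------------

#' Read a community incidence CSV
#'
#' Expected layout: header row; columns `site_id`, `habitat`, optionally
#' `elevation_m`, then one 0/1 column per species. Row and column order are
#' preserved; habitat strings are lower-cased.
#'
#' @param path path to the CSV file.
#' @return A [community_matrix()].
#' @export
read_community_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("site_id", "habitat")
  if (!all(need %in% names(df)))
    stop("community CSV must contain columns site_id and habitat")
  elev <- if ("elevation_m" %in% names(df)) as.numeric(df$elevation_m) else NULL
  spcols <- setdiff(names(df), c("site_id", "habitat", "elevation_m"))
  if (!length(spcols)) stop("community CSV has no species columns")
  inc <- as.matrix(df[, spcols, drop = FALSE])
  suppressWarnings(storage.mode(inc) <- "double")
  rownames(inc) <- df$site_id
  community_matrix(inc, habitat = df$habitat, elevation_m = elev)
}

#' Write a community incidence CSV (inverse of [read_community_csv()])
#' @param cm a `community_matrix`.
#' @param path output path.
#' @export
write_community_csv <- function(cm, path) {
  df <- data.frame(site_id = cm$site_ids, habitat = cm$habitat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(cm$elevation_m)) df$elevation_m <- cm$elevation_m
  df <- cbind(df, as.data.frame(cm$incidence, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trait CSV with a trait-kind schema
#'
#' @param path CSV with a `species_id` column then one column per trait.
#' @param schema either a named character vector of trait kinds or a path to
#'   a JSON sidecar mapping trait name to kind.
#' @return A [trait_table()].
#' @export
read_trait_csv <- function(path, schema) {
  if (is.character(schema) && length(schema) == 1L && file.exists(schema))
    schema <- unlist(jsonlite::read_json(schema, simplifyVector = TRUE))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"species_id" %in% names(df))
    stop("trait CSV must contain a species_id column")
  trait_table(df, kinds = schema)
}

#' Write a trait CSV plus JSON schema sidecar
#' @param tt a `trait_table`.
#' @param path output CSV path.
#' @param schema_path optional path for the JSON kind schema.
#' @export
write_trait_csv <- function(tt, path, schema_path = NULL) {
  df <- cbind(data.frame(species_id = tt$species_ids,
                         stringsAsFactors = FALSE), tt$data)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(schema_path))
    jsonlite::write_json(as.list(tt$kinds), schema_path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a rooted Newick tree with mandatory branch lengths
#'
#' Thin validating wrapper around [ape::read.tree()]: exactly one tree,
#' unique tip labels, rooted, every edge carrying a finite non-negative
#' length (no default imputation). Polytomies are permitted.
#'
#' @param path path to a Newick file (or a literal Newick string via `text`).
#' @param text optional Newick string instead of a file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  phy <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(phy)) stop("could not parse Newick input")
  if (inherits(phy, "multiPhylo")) stop("expected a single tree")
  validate_phylogeny(phy)
  phy
}

#' Validate a phylo object against the package's phylogeny contract
#' @param phy a `phylo` object.
#' @return `phy`, invisibly; errors on violation.
#' @export
validate_phylogeny <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a phylo object")
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip labels")
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths (lengths are required)")
  if (any(!is.finite(phy$edge.length)))
    stop("missing/non-finite branch length on ",
         sum(!is.finite(phy$edge.length)), " edge(s)")
  if (any(phy$edge.length < 0)) stop("negative branch length")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  invisible(phy)
}

#' Write a tree to Newick
#' @param phy a `phylo` object.
#' @param path output path.
#' @export
write_newick <- function(phy, path) {
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read a grid incidence CSV
#'
#' Layout: `cell_id`, optional `lon` and `lat`, then 0/1 species columns.
#' @param path path to CSV.
#' @return A [grid_assemblage()].
#' @export
read_grid_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(df)) stop("grid CSV must contain column cell_id")
  lonlat <- NULL
  if (all(c("lon", "lat") %in% names(df)))
    lonlat <- cbind(lon = as.numeric(df$lon), lat = as.numeric(df$lat))
  spcols <- setdiff(names(df), c("cell_id", "lon", "lat"))
  inc <- as.matrix(df[, spcols, drop = FALSE])
  suppressWarnings(storage.mode(inc) <- "double")
  rownames(inc) <- df$cell_id
  grid_assemblage(inc, cell_lonlat = lonlat)
}

#' Write a grid incidence CSV (inverse of [read_grid_csv()])
#' @param grid a `grid_assemblage`.
#' @param path output path.
#' @export
write_grid_csv <- function(grid, path) {
  df <- data.frame(cell_id = grid$cell_ids, stringsAsFactors = FALSE)
  if (!is.null(grid$cell_lonlat)) {
    df$lon <- grid$cell_lonlat[, 1]
    df$lat <- grid$cell_lonlat[, 2]
  }
  df <- cbind(df, as.data.frame(grid$incidence, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- cross-file congruence --------------------------------------------------

#' Check name congruence across community, traits, tree (and optionally grid)
#'
#' Name matching is exact and case-sensitive after whitespace trimming; a
#' silent fuzzy match would be worse than a hard failure. The report's
#' `errors` element is empty iff the dataset is usable: every community (and
#' grid) species must have a tree tip and a trait row. Unused tips/trait rows
#' and species occurring at zero sites only produce warnings.
#'
#' @param cm a `community_matrix`.
#' @param tt a `trait_table`.
#' @param phy a `phylo`.
#' @param grid optional `grid_assemblage` (its species must be tree tips).
#' @return Object of class `validation_report` with elements `errors`,
#'   `warnings`, `species_missing_from_tree`, `species_missing_from_traits`.
#' @export
validate_dataset <- function(cm, tt, phy, grid = NULL) {
  errors <- character(0)
  warnings <- character(0)
  sp <- cm$species_ids
  miss_tree <- setdiff(sp, phy$tip.label)
  miss_tr <- setdiff(sp, tt$species_ids)
  if (length(miss_tree))
    errors <- c(errors, paste0("community species missing from tree: ",
                               paste(miss_tree, collapse = ", ")))
  if (length(miss_tr))
    errors <- c(errors, paste0("community species missing from traits: ",
                               paste(miss_tr, collapse = ", ")))
  if (!is.null(grid)) {
    gm <- setdiff(grid$species_ids, phy$tip.label)
    if (length(gm)) {
      errors <- c(errors, paste0("grid species missing from tree: ",
                                 paste(gm, collapse = ", ")))
      miss_tree <- union(miss_tree, gm)
    }
  }
  unused_tips <- setdiff(phy$tip.label,
                         union(sp, if (is.null(grid)) character(0)
                               else grid$species_ids))
  if (length(unused_tips))
    warnings <- c(warnings, paste0("tree tips unused by the data: ",
                                   paste(unused_tips, collapse = ", ")))
  unused_tr <- setdiff(tt$species_ids, sp)
  if (length(unused_tr))
    warnings <- c(warnings, paste0("trait rows unused by the community: ",
                                   paste(unused_tr, collapse = ", ")))
  absent <- sp[colSums(cm$incidence) == 0]
  if (length(absent))
    warnings <- c(warnings, paste0("species occurring at zero sites: ",
                                   paste(absent, collapse = ", ")))
  structure(list(errors = errors, warnings = warnings,
                 species_missing_from_tree = miss_tree,
                 species_missing_from_traits = miss_tr),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report: %d error(s), %d warning(s)\n",
              length(x$errors), length(x$warnings)))
  for (e in x$errors) cat("  ERROR:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

# shared precondition for pipeline entry points
.assert_valid <- function(cm, tt, phy, grid = NULL) {
  rep <- validate_dataset(cm, tt, phy, grid)
  if (length(rep$errors))
    stop("dataset failed validation:\n  ", paste(rep$errors, collapse = "\n  "))
  invisible(rep)
}

#' Collapse a raw per-specimen morphometric table to one row per species
#'
#' Helper for raw measurement tables with repeated specimens per species and
#' sex: each continuous trait is collapsed to the mean of sex means, so an
#' unbalanced number of measured males and females does not bias the species
#' value. This aggregation rule is a documented stand-in: field datasets
#' rarely state how sex-dimorphic morphometrics were collapsed.
#'
#' @param df data.frame with columns `species_id`, `sex`, then numeric
#'   measurement columns.
#' @return data.frame with one row per species, species ids as `species_id`.
#' @export
aggregate_sex_means <- function(df) {
  if (!all(c("species_id", "sex") %in% names(df)))
    stop("need species_id and sex columns")
  meas <- setdiff(names(df), c("species_id", "sex"))
  sexm <- stats::aggregate(df[meas],
                           by = list(species_id = df$species_id, sex = df$sex),
                           FUN = mean, na.rm = TRUE)
  out <- stats::aggregate(sexm[meas], by = list(species_id = sexm$species_id),
                          FUN = mean, na.rm = TRUE)
  out
}
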