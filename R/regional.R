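# Habitat-level comparison machinery: subsampled gamma diversity (pooled
# over random site combinations), sample-based species-accumulation curves,
# elevation filtering, Welch contrasts with medians/IQRs, and cross-facet
# OLS correlations.

#' Subsampled gamma diversity over random site combinations
#'
#' Each draw samples, within every habitat listed in `group_sizes`, the
#' requested number of sites uniformly without replacement, pools the species
#' across all drawn sites, and evaluates the requested facet's gamma
#' diversity on the pooled set (e.g. forest = 7, savannah = 8 emulates a
#' 15-site "natural" subsample comparable to 15 farmland sites). Draws are
#' independent; duplicate combinations across draws are permitted.
#'
#' @param cm a [community_matrix()].
#' @param ts `trait_space`, required for `facet = "functional"`.
#' @param phy `phylo`, required for `facet = "phylogenetic"`.
#' @param group_sizes named integer vector, habitat -> number of sites.
#' @param n_draws number of random combinations (default 1000).
#' @param facet one of `"taxonomic"`, `"functional"`, `"phylogenetic"`.
#' @param seed optional integer seed.
#' @return Object of class `gamma_summary`: list with `habitat_class`,
#'   `facet`, `draws`, `median`, `sd`, `min`, `max` and the raw `values`.
#' @export
subsample_gamma <- function(cm, ts = NULL, phy = NULL, group_sizes,
                            n_draws = 1000,
                            facet = c("taxonomic", "functional",
                                      "phylogenetic"),
                            seed = NULL) {
  facet <- match.arg(facet)
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stop("group_sizes must be a named habitat -> count vector")
  pools <- lapply(names(group_sizes), function(h) {
    s <- cm$site_ids[cm$habitat == h]
    if (length(s) < group_sizes[[h]])
      stop(sprintf("habitat '%s' has %d sites, %d requested",
                   h, length(s), group_sizes[[h]]))
    s
  })
  names(pools) <- names(group_sizes)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  tp <- if (facet == "phylogenetic") .tree_paths(phy) else NULL
  values <- vapply(seq_len(n_draws), function(i) {
    sites <- unlist(lapply(names(pools), function(h)
      sample(pools[[h]], group_sizes[[h]])), use.names = FALSE)
    sub <- cm$incidence[sites, , drop = FALSE]
    species <- cm$species_ids[colSums(sub) > 0]
    switch(facet,
      taxonomic = length(species),
      functional = suppressWarnings(functional_richness(ts, species)),
      phylogenetic = sum(tp$lengths[.path_union(tp, species)]))
  }, 0)
  structure(list(habitat_class = paste(names(group_sizes), collapse = "+"),
                 facet = facet, draws = n_draws,
                 median = stats::median(values), sd = stats::sd(values),
                 min = min(values), max = max(values), values = values),
            class = "gamma_summary")
}

#' @export
print.gamma_summary <- function(x, ...) {
  cat(sprintf(
    "gamma_summary [%s, %s]: median %.4g (sd %.3g, range %.4g-%.4g) over %d draws\n",
    x$habitat_class, x$facet, x$median, x$sd, x$min, x$max, x$draws))
  invisible(x)
}

#' Sample-based species-accumulation curve
#'
#' Exact mode is analytic sample-based rarefaction (Mao tau):
#' S(k) = sum_s \[1 - C(n - n_s, k) / C(n, k)\] with n_s the number of sites
#' occupied by species s. Permutation mode averages the cumulative richness
#' over random site orderings and also reports a per-k standard deviation.
#' Both modes end at the pooled richness at k = n.
#'
#' @param cm a [community_matrix()].
#' @param sites site ids to use (default: all).
#' @param mode `"exact"` or `"permutation"`.
#' @param n_perm number of random orderings for permutation mode.
#' @param seed optional integer seed (permutation mode).
#' @return data.frame with columns `k`, `expected_richness`, and `sd`
#'   (NA in exact mode).
#' @export
accumulation_curve <- function(cm, sites = NULL,
                               mode = c("exact", "permutation"),
                               n_perm = 100, seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(sites)) sites <- cm$site_ids
  if (length(sites) < 1L) stop("need at least one site")
  inc <- cm$incidence[sites, , drop = FALSE] > 0
  n <- nrow(inc)
  ns <- colSums(inc)
  ns <- ns[ns > 0]
  ks <- seq_len(n)
  if (mode == "exact") {
    ex <- vapply(ks, function(k) {
      # 1 - C(n-ns, k)/C(n, k), with C(m, k) = 0 when m < k
      p_absent <- ifelse(n - ns >= k,
                         exp(lchoose(n - ns, k) - lchoose(n, k)), 0)
      sum(1 - p_absent)
    }, 0)
    return(data.frame(k = ks, expected_richness = ex, sd = NA_real_))
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  occ <- inc[, colSums(inc) > 0, drop = FALSE]
  acc <- matrix(0, n_perm, n)
  for (p in seq_len(n_perm)) {
    ord <- sample.int(n)
    seen <- apply(occ[ord, , drop = FALSE], 2, cummax)
    if (n == 1L) seen <- matrix(seen, nrow = 1)
    acc[p, ] <- rowSums(seen)
  }
  data.frame(k = ks, expected_richness = colMeans(acc),
             sd = apply(acc, 2, stats::sd))
}

#' Drop sites above an elevation threshold
#'
#' Used to repeat habitat comparisons without high-elevation sites (e.g.
#' forest plots above 2500 m). Species left with zero occurrences are
#' retained in the matrix and flagged by [validate_dataset()].
#'
#' @param cm a [community_matrix()] with elevations.
#' @param max_elevation_m inclusive elevation ceiling in metres.
#' @return the filtered `community_matrix`.
#' @export
elevation_filter <- function(cm, max_elevation_m) {
  if (is.null(cm$elevation_m) || anyNA(cm$elevation_m))
    stop("elevation_filter requires complete site elevations")
  keep <- cm$elevation_m <= max_elevation_m
  if (!any(keep)) stop("threshold removes every site")
  community_matrix(cm$incidence[keep, , drop = FALSE],
                   habitat = cm$habitat[keep],
                   elevation_m = cm$elevation_m[keep])
}

#' Two-group contrast: Welch t-test plus medians and IQRs
#'
#' Default is Welch's two-sided t-test (unequal variances,
#' Welch-Satterthwaite df); set `var_equal = TRUE` for the Student variant.
#' Medians and inter-quartile ranges use linear-interpolation (type-7)
#' quantiles. When applied to pairwise beta values the observations are not
#' independent; a warning notes this (set `values_are_pairwise = TRUE`).
#'
#' @param x,y numeric value vectors for the two groups.
#' @param labels length-2 character vector naming the groups.
#' @param var_equal logical; FALSE (default) = Welch.
#' @param values_are_pairwise logical; emit the non-independence warning.
#' @return Object of class `habitat_contrast`: list with `metric_name`
#'   (NA unless set by the caller), `group_labels`, `t`, `df`, `p`,
#'   `median`, `iqr`, `n`.
#' @export
compare_groups <- function(x, y, labels = c("x", "y"), var_equal = FALSE,
                           values_are_pairwise = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least two finite values")
  if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y))
    stop("both groups constant and equal; t undefined")
  if (values_are_pairwise)
    warning("pairwise dissimilarities are not independent observations; ",
            "treat the t-test as descriptive (see permutation_contrast)")
  tt <- stats::t.test(x, y, var.equal = var_equal,
                      alternative = "two.sided")
  structure(list(metric_name = NA_character_, group_labels = labels,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value,
                 median = stats::setNames(c(stats::median(x),
                                            stats::median(y)), labels),
                 iqr = stats::setNames(c(stats::IQR(x, type = 7),
                                         stats::IQR(y, type = 7)), labels),
                 n = stats::setNames(c(length(x), length(y)), labels)),
            class = "habitat_contrast")
}

#' @export
print.habitat_contrast <- function(x, ...) {
  cat(sprintf("contrast %s vs %s: t = %.4g, df = %.3g, p = %.3g\n",
              x$group_labels[1], x$group_labels[2], x$t, x$df, x$p))
  cat(sprintf("  medians (IQR): %s %.4g (%.4g) | %s %.4g (%.4g)\n",
              x$group_labels[1], x$median[1], x$iqr[1],
              x$group_labels[2], x$median[2], x$iqr[2]))
  invisible(x)
}

#' Permutation alternative for non-independent pairwise beta contrasts
#'
#' Permutes site labels across the two groups, recomputing the difference of
#' group mean dissimilarities from the full pairwise matrix, which respects
#' the dependence structure that the plain t-test on pairs ignores.
#'
#' @param bm a `beta_matrix` covering both groups' sites.
#' @param groups named character vector: site id -> group label (2 groups).
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return list with `observed` difference (group1 - group2 mean within-group
#'   dissimilarity) and two-sided `p`.
#' @export
permutation_contrast <- function(bm, groups, n_perm = 999, seed = NULL) {
  g <- groups[bm$site_ids]
  if (length(unique(g)) != 2L) stop("need exactly two groups")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  lv <- unique(g)
  stat <- function(gg) {
    m1 <- bm$b[gg == lv[1], gg == lv[1]]
    m2 <- bm$b[gg == lv[2], gg == lv[2]]
    mean(m1[lower.tri(m1)], na.rm = TRUE) -
      mean(m2[lower.tri(m2)], na.rm = TRUE)
  }
  obs <- stat(g)
  perm <- vapply(seq_len(n_perm), function(i) stat(sample(g)), 0)
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  list(observed = obs, p = p)
}

#' Simple OLS correlation between two diversity facets
#'
#' Ordinary least-squares regression of `y` on `x`; reports R-squared and
#' the two-sided p-value of the slope.
#'
#' @param x,y paired numeric vectors (>= 3 finite pairs).
#' @return list with `r_squared`, `p`, `slope`, `intercept`, `n`.
#' @export
facet_correlation <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least three paired finite values")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(r_squared = sm$r.squared,
       p = sm$coefficients["x", "Pr(>|t|)"],
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(x))
}
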