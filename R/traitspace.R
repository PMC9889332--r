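# Functional trait space: Gower dissimilarity on mixed trait kinds, then
# non-metric multidimensional scaling into a common k-dimensional space.
# The embedding is computed once on the full species pool and reused by every
# site-level operation, never re-fit per assemblage.

#' Gower distance on a mixed-kind trait table
#'
#' d(i,j) = sum_t w_t delta_ijt d_ijt / sum_t w_t delta_ijt, where delta is 1
#' iff both species have the trait recorded (pairwise deletion, no
#' imputation). Continuous and ordinal traits contribute |x_i - x_j| / range
#' (ordinal on integer level codes, the simple Gower variant rather than
#' Podani's tie correction); categorical and binary traits contribute the
#' 0/1 mismatch indicator. Traits with zero range across species are
#' excluded with a warning.
#'
#' @param tt a [trait_table()].
#' @param weights optional named non-negative per-trait weights (default 1).
#' @return Object of class `dist_matrix`: list with `labels` and symmetric
#'   zero-diagonal matrix `d` with entries in `[0, 1]`.
#' @export
gower_distance <- function(tt, weights = NULL) {
  stopifnot(inherits(tt, "trait_table"))
  n <- length(tt$species_ids)
  if (n < 2L) stop("need at least two species")
  if (is.null(weights)) {
    weights <- rep(1, ncol(tt$data))
    names(weights) <- names(tt$data)
  }
  if (any(weights < 0)) stop("weights must be non-negative")
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (nm in names(tt$data)) {
    w <- if (nm %in% names(weights)) weights[[nm]] else 1
    k <- tt$kinds[[nm]]
    v <- tt$data[[nm]]
    if (k %in% c("continuous", "ordinal")) {
      if (k == "ordinal") {
        lev <- sort(unique(stats::na.omit(v)))
        v <- match(v, lev)  # integer level codes
      }
      rng <- diff(range(v, na.rm = TRUE))
      if (!is.finite(rng) || rng == 0) {
        warning(sprintf("trait '%s' has zero range; excluded from Gower", nm))
        next
      }
      contrib <- abs(outer(v, v, "-")) / rng
    } else {
      contrib <- outer(v, v, "!=") * 1
    }
    avail <- outer(!is.na(v), !is.na(v), "&") * 1
    contrib[avail == 0] <- 0
    num <- num + w * contrib
    den <- den + w * avail
  }
  off <- den == 0 & row(den) != col(den)
  if (any(off)) {
    ij <- which(off, arr.ind = TRUE)[1, ]
    stop(sprintf("species '%s' and '%s' share no recorded traits",
                 tt$species_ids[ij[1]], tt$species_ids[ij[2]]))
  }
  d <- num / pmax(den, 1e-300)
  diag(d) <- 0
  d <- (d + t(d)) / 2
  dimnames(d) <- list(tt$species_ids, tt$species_ids)
  structure(list(labels = tt$species_ids, d = d), class = "dist_matrix")
}

# ---- NMDS -------------------------------------------------------------------

# isotonic (PAVA) fit of configuration distances against the rank order of
# the input dissimilarities; primary tie treatment (tied dissimilarities may
# receive unequal fitted values, in their stable sort order).
.monotone_fit <- function(dvec, dissvec) {
  ord <- order(dissvec)
  fit <- numeric(length(dvec))
  fit[ord] <- stats::isoreg(dvec[ord])$yf
  fit
}

#' Kruskal stress-1 of a configuration against a dissimilarity matrix
#'
#' stress-1 = sqrt( sum (d_ij - dhat_ij)^2 / sum d_ij^2 ), where d are the
#' configuration's Euclidean distances and dhat their best monotone
#' (pool-adjacent-violators) fit to the rank order of the dissimilarities.
#' A collapsed configuration (all distances 0) against a non-degenerate
#' dissimilarity matrix returns 1.
#'
#' @param coords n x k coordinate matrix.
#' @param dm a `dist_matrix` (or plain symmetric matrix).
#' @return stress-1 in `[0, 1]`.
#' @export
stress1 <- function(coords, dm) {
  D <- if (inherits(dm, "dist_matrix")) dm$d else as.matrix(dm)
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("need at least two points")
  if (nrow(coords) != nrow(D)) stop("coords and dissimilarities disagree")
  lt <- lower.tri(D)
  diss <- D[lt]
  dv <- as.matrix(stats::dist(coords))[lt]
  if (sum(dv^2) == 0) {
    if (all(diss == 0)) return(0)
    return(1)
  }
  dhat <- .monotone_fit(dv, diss)
  sqrt(sum((dv - dhat)^2) / sum(dv^2))
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal-style NMDS: each random start alternates (a) PAVA isotonic
#' regression of the configuration distances on the dissimilarity ranks and
#' (b) a SMACOF/Guttman configuration update, until the stress-1 improvement
#' drops below `tol` or `max_iter` is reached (a step that increases stress
#' is rejected and terminates the start). The lowest-stress configuration
#' over all starts is returned, centred at the origin and rotated to its
#' principal axes with a fixed sign convention, so the orientation is
#' deterministic. Start 1 is the classical-scaling (PCoA) configuration; the
#' remaining starts are uniform random.
#'
#' @param dm a `dist_matrix` (e.g. from [gower_distance()]).
#' @param k embedding dimension (default 3).
#' @param n_starts number of initial configurations (default 20).
#' @param max_iter iteration cap per start (default 300).
#' @param tol stress improvement threshold (default 1e-7).
#' @param seed optional integer seed for the random starts.
#' @return Object of class `trait_space`: list with `labels`, n x k `coords`,
#'   achieved `stress`, and `k`.
#' @export
nmds_embed <- function(dm, k = 3, n_starts = 20, max_iter = 300,
                       tol = 1e-7, seed = NULL) {
  D <- if (inherits(dm, "dist_matrix")) dm$d else as.matrix(dm)
  labels <- if (inherits(dm, "dist_matrix")) dm$labels else rownames(D)
  n <- nrow(D)
  if (n <= k) stop("need more points than embedding dimensions (n > k)")
  lt <- lower.tri(D)
  diss <- D[lt]
  if (length(unique(diss)) == 1L)
    warning("all dissimilarities equal; embedding is rank-degenerate")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }

  run_start <- function(X) {
    s_prev <- Inf
    for (it in seq_len(max_iter)) {
      Dx <- as.matrix(stats::dist(X))
      dv <- Dx[lt]
      if (sum(dv^2) == 0) return(list(X = X, stress = if (all(diss == 0)) 0 else 1))
      dhat <- .monotone_fit(dv, diss)
      s <- sqrt(sum((dv - dhat)^2) / sum(dv^2))
      if (s > s_prev) break            # reject worsening step, keep X_prev
      X_keep <- X; s_keep <- s
      if (s_prev - s < tol) break
      s_prev <- s
      # Guttman transform with unit weights
      R <- matrix(0, n, n)
      pos <- Dx > 0
      H <- matrix(0, n, n)
      H[lt] <- dhat
      H <- H + t(H)
      R[pos] <- H[pos] / Dx[pos]
      Bm <- diag(rowSums(R)) - R
      X <- Bm %*% X / n
      # stress-1 is scale-invariant; pin the configuration scale to the
      # dissimilarities so it cannot drift toward 0 across iterations
      mdv <- mean(stats::dist(X))
      if (mdv > 0) X <- X * (mean(diss) / mdv)
    }
    list(X = X_keep, stress = s_keep)
  }

  best <- NULL
  for (st in seq_len(n_starts)) {
    X0 <- if (st == 1L) {
      cs <- suppressWarnings(stats::cmdscale(D, k = k))
      if (ncol(cs) < k) cs <- cbind(cs, matrix(0, n, k - ncol(cs)))
      cs + matrix(stats::rnorm(n * k, sd = 1e-4 * max(diss, 1)), n, k)
    } else {
      matrix(stats::runif(n * k, -0.5, 0.5), n, k)
    }
    res <- run_start(X0)
    if (is.null(best) || res$stress < best$stress) best <- res
  }

  X <- scale(best$X, center = TRUE, scale = FALSE)
  mdv <- mean(stats::dist(X))
  if (mdv > 0 && mean(diss) > 0) X <- X * (mean(diss) / mdv)
  pr <- stats::prcomp(X, center = FALSE)
  X <- pr$x
  if (ncol(X) < k) X <- cbind(X, matrix(0, n, k - ncol(X)))
  X <- X[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {            # sign convention: dominant loading > 0
    i <- which.max(abs(X[, j]))
    if (X[i, j] < 0) X[, j] <- -X[, j]
  }
  rownames(X) <- labels
  colnames(X) <- paste0("axis", seq_len(k))
  structure(list(labels = labels, coords = X,
                 stress = stress1(X, D), k = k),
            class = "trait_space")
}

#' @export
print.trait_space <- function(x, ...) {
  cat(sprintf("trait_space: %d species in %d dimensions, stress-1 = %.4g\n",
              length(x$labels), x$k, x$stress))
  invisible(x)
}

#' Write trait-space coordinates to CSV (stress recorded in a header comment)
#' @param ts a `trait_space`.
#' @param path output path.
#' @export
write_traitspace_csv <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# NMDS k=%d stress1=%.10g", ts$k, ts$stress), con)
  df <- cbind(data.frame(species_id = ts$labels, stringsAsFactors = FALSE),
              as.data.frame(ts$coords))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read trait-space coordinates written by [write_traitspace_csv()]
#' @param path input path.
#' @return a `trait_space` (stress recovered from the header comment).
#' @export
read_traitspace_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  stress <- as.numeric(sub(".*stress1=", "", hdr))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  coords <- as.matrix(df[, -1, drop = FALSE])
  rownames(coords) <- df$species_id
  structure(list(labels = df$species_id, coords = coords, stress = stress,
                 k = ncol(coords)), class = "trait_space")
}
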