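# Shared fixtures and independent oracles, all built in code.

tiny_tree <- function() read_newick(text = "((A:1,B:1):1,C:2);")

cube_pts <- function(scale = 1, shift = c(0, 0, 0)) {
  p <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * scale
  sweep(p, 2, shift, "+")
}

make_ts <- function(coords, labels = rownames(coords)) {
  if (is.null(labels)) labels <- paste0("sp", seq_len(nrow(coords)))
  rownames(coords) <- labels
  structure(list(labels = labels, coords = coords, stress = 0, k = ncol(coords)),
            class = "trait_space")
}

toy_cm <- function(inc, habitat = NULL, elevation = NULL) {
  if (is.null(habitat)) habitat <- rep("forest", nrow(inc))
  community_matrix(inc, habitat = habitat, elevation_m = elevation)
}

# independent Faith-PD oracle: per-tip root paths via ape::nodepath, explicit
# edge-set union over the edge matrix
pd_oracle <- function(phy, species, include_root = TRUE) {
  root <- length(phy$tip.label) + 1L
  key <- paste(phy$edge[, 1], phy$edge[, 2])
  paths <- lapply(species, function(sp) {
    np <- ape::nodepath(phy, from = root, to = match(sp, phy$tip.label))
    paste(np[-length(np)], np[-1])
  })
  edges <- unique(unlist(paths))
  if (!include_root) {
    spine <- Reduce(intersect, paths)
    edges <- setdiff(edges, spine)
  }
  sum(phy$edge.length[match(edges, key)])
}

# brute-force least-squares monotone fit: enumerate every contiguous-block
# partition of the sequence (sorted by dissimilarity) and keep the best
# monotone block-mean fit
pava_oracle <- function(y) {
  n <- length(y)
  best <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    fit <- numeric(n)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      fit[idx] <- mean(y[idx])
    }
    if (is.unsorted(fit)) next
    ss <- sum((y - fit)^2)
    if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
  }
  best$fit
}

stress1_oracle <- function(coords, d) {
  lt <- lower.tri(d)
  dv <- as.matrix(dist(coords))[lt]
  diss <- d[lt]
  ord <- order(diss)
  fit <- numeric(length(dv))
  fit[ord] <- pava_oracle(dv[ord])
  sqrt(sum((dv - fit)^2) / sum(dv^2))
}

# Monte-Carlo hull membership oracle (samples in the hull's bounding box)
mc_hull_volume <- function(pts, n = 4e5) {
  h <- divfacets:::convex_hull_3d(pts)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  P <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
             runif(n, lo[3], hi[3]))
  m <- length(h$offsets)
  inh <- rowSums(P %*% t(h$normals) <=
                   matrix(h$offsets + 1e-12, n, m, byrow = TRUE)) == m
  mean(inh) * prod(hi - lo)
}

mc_intersection_volume <- function(A, B, n = 4e5) {
  hA <- divfacets:::convex_hull_3d(A)
  hB <- divfacets:::convex_hull_3d(B)
  lo <- pmax(apply(A, 2, min), apply(B, 2, min))
  hi <- pmin(apply(A, 2, max), apply(B, 2, max))
  if (any(lo >= hi)) return(0)
  P <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
             runif(n, lo[3], hi[3]))
  inh <- function(h) rowSums(P %*% t(h$normals) <=
      matrix(h$offsets + 1e-12, n, length(h$offsets), byrow = TRUE)) ==
      length(h$offsets)
  mean(inh(hA) & inh(hB)) * prod(hi - lo)
}

write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
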