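# 3-D convex-hull geometry for functional richness and functional beta.
#
# No qhull binding is assumed: the hull is built by an incremental algorithm
# (initial tetrahedron, then per-point horizon repair), and the intersection
# of two hulls is obtained by enumerating candidate vertices of the combined
# half-space system (vectorised Cramer solves over all plane triplets) and
# re-hulling the feasible ones. Point counts here are small (sites hold a
# few dozen species at most), so the O(n^2)/O(m^3) costs are immaterial.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# row-wise cross product of two n x 3 matrices
.cross3m <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

# Incremental 3-D convex hull.
# Returns NULL when the point set is affinely degenerate (rank < 3),
# otherwise list(faces = m x 3 vertex-index matrix, outward-oriented;
# volume; normals = m x 3 unit outward normals; offsets = m vector with
# facet plane n.x <= d; interior = strictly interior point).
convex_hull_3d <- function(pts) {
  pts <- as.matrix(pts)
  if (ncol(pts) != 3L) stop("convex_hull_3d expects n x 3 coordinates")
  n <- nrow(pts)
  if (n < 4L) return(NULL)
  scale <- max(1, max(abs(pts)))
  eps <- 1e-10 * scale

  # initial simplex: spread point, then max-distance, max-area, max-volume
  i1 <- which.max(pts[, 1] - pts[, 2])  # arbitrary but deterministic extreme
  d1 <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d1)
  if (sqrt(d1[i2]) <= eps) return(NULL)
  u <- pts[i2, ] - pts[i1, ]
  crs <- .cross3m(matrix(u, n, 3, byrow = TRUE), sweep(pts, 2, pts[i1, ]))
  a2 <- rowSums(crs^2)
  i3 <- which.max(a2)
  if (sqrt(a2[i3]) <= eps^2 * 1e6) {  # collinear set
    if (max(sqrt(a2)) <= 1e-9 * scale^2) return(NULL)
  }
  nrm <- .cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  if (sqrt(sum(nrm^2)) <= 1e-12 * scale^2) return(NULL)
  h <- abs(sweep(pts, 2, pts[i1, ]) %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(h)
  if (h[i4] <= 1e-9 * scale) return(NULL)  # coplanar set

  o <- colMeans(pts[c(i1, i2, i3, i4), ])  # strictly interior point
  orient <- function(f) {
    nn <- .cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    if (sum(nn * (o - pts[f[1], ])) > 0) f[c(1, 3, 2)] else f
  }
  faces <- rbind(orient(c(i1, i2, i3)), orient(c(i1, i2, i4)),
                 orient(c(i1, i3, i4)), orient(c(i2, i3, i4)))

  face_planes <- function(faces) {
    A <- pts[faces[, 1], , drop = FALSE]
    N <- .cross3m(pts[faces[, 2], , drop = FALSE] - A,
                  pts[faces[, 3], , drop = FALSE] - A)
    len <- sqrt(rowSums(N^2))
    N <- N / len
    list(N = N, d = rowSums(N * A))
  }
  pl <- face_planes(faces)

  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    dist <- drop(pl$N %*% pts[p, ]) - pl$d
    vis <- dist > eps
    if (!any(vis)) next  # interior or on the surface: volume unchanged
    vf <- faces[vis, , drop = FALSE]
    # directed edges of visible faces; horizon = edges whose twin is unseen
    ed <- rbind(vf[, c(1, 2)], vf[, c(2, 3)], vf[, c(3, 1)])
    key <- paste(ed[, 1], ed[, 2])
    twin <- paste(ed[, 2], ed[, 1])
    horizon <- ed[!(twin %in% key), , drop = FALSE]
    newf <- cbind(horizon, p)
    newf <- t(apply(newf, 1, orient))
    faces <- rbind(faces[!vis, , drop = FALSE], newf)
    pl <- face_planes(faces)
  }

  A <- pts[faces[, 1], , drop = FALSE] - matrix(o, nrow(faces), 3, byrow = TRUE)
  B <- pts[faces[, 2], , drop = FALSE] - matrix(o, nrow(faces), 3, byrow = TRUE)
  C <- pts[faces[, 3], , drop = FALSE] - matrix(o, nrow(faces), 3, byrow = TRUE)
  vol <- sum(rowSums(A * .cross3m(B, C))) / 6
  # outward orientation makes every signed tetra non-negative (up to roundoff)
  vol <- abs(vol)
  list(faces = faces, volume = vol, normals = pl$N, offsets = pl$d,
       interior = o, vertices = sort(unique(as.vector(faces))))
}

# deduplicate near-identical facet planes (triangulated faces of one polygon)
.dedupe_planes <- function(N, d, tol = 1e-7) {
  key <- paste(round(N[, 1] / tol), round(N[, 2] / tol),
               round(N[, 3] / tol), round(d / tol))
  keep <- !duplicated(key)
  list(N = N[keep, , drop = FALSE], d = d[keep])
}

#' Volume of the convex hull of a 3-D point cloud
#'
#' Returns `NaN` (with a warning) when the hull is undefined: fewer than 4
#' points or an affinely degenerate (coplanar/collinear) configuration.
#' Degeneracy deliberately yields `NaN` rather than 0 so that "no volume"
#' is never conflated with "undefined".
#'
#' @param pts numeric n x 3 matrix of coordinates.
#' @return hull volume (scalar), or `NaN` for degenerate input.
#' @examples
#' hull_volume(rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1)))  # 1/6
#' @export
hull_volume <- function(pts) {
  pts <- as.matrix(pts)
  h <- convex_hull_3d(pts)
  if (is.null(h)) {
    warning("degenerate hull (fewer than 4 affinely independent points); NaN")
    return(NaN)
  }
  h$volume
}

#' Volume of the intersection of two convex hulls
#'
#' Both point sets must span three dimensions (otherwise `NaN` with a
#' warning). The two hulls' facet half-spaces are pooled; candidate vertices
#' of the intersection polytope are generated from all plane triplets by
#' vectorised Cramer solves, filtered by feasibility against every
#' half-space, and re-hulled. An empty or lower-dimensional feasible set
#' gives volume 0 (disjoint or touching hulls).
#'
#' @param ptsA,ptsB numeric n x 3 coordinate matrices.
#' @return intersection volume; 0 when interiors are disjoint; `NaN` when
#'   either hull is degenerate.
#' @export
hull_intersection_volume <- function(ptsA, ptsB) {
  hA <- convex_hull_3d(as.matrix(ptsA))
  hB <- convex_hull_3d(as.matrix(ptsB))
  if (is.null(hA) || is.null(hB)) {
    warning("degenerate input hull; intersection volume is NaN")
    return(NaN)
  }
  .hull_pair_intersection(hA, hB, as.matrix(ptsA), as.matrix(ptsB))
}

# unique undirected edges of a hull, as a 2-column vertex-index matrix
.hull_edges <- function(h) {
  e <- rbind(h$faces[, 1:2], h$faces[, 2:3], h$faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(paste(e[, 1], e[, 2])), , drop = FALSE]
}

# intersection points of segments (P1 -> P2) with planes (N x = d),
# clipped to the segments; vectorised over all segment/plane combinations
.segment_plane_points <- function(P1, P2, N, d) {
  ne <- nrow(P1); m <- nrow(N)
  ie <- rep(seq_len(ne), times = m)
  ip <- rep(seq_len(m), each = ne)
  dirv <- P2[ie, , drop = FALSE] - P1[ie, , drop = FALSE]
  den <- rowSums(dirv * N[ip, , drop = FALSE])
  num <- d[ip] - rowSums(P1[ie, , drop = FALSE] * N[ip, , drop = FALSE])
  keep <- abs(den) > 1e-12
  t <- num[keep] / den[keep]
  inside <- t >= -1e-9 & t <= 1 + 1e-9
  P1[ie[keep], , drop = FALSE][inside, , drop = FALSE] +
    t[inside] * dirv[keep, , drop = FALSE][inside, , drop = FALSE]
}

# positive area of the 2-D convex hull of points lying on a 3-D plane
.plane_polygon_area <- function(P, n) {
  e <- diag(3)[, which.min(abs(n))]
  u <- .cross3(n, e); u <- u / sqrt(sum(u^2))
  v <- .cross3(n, u)
  s <- drop(P %*% u); t <- drop(P %*% v)
  ch <- grDevices::chull(s, t)
  if (length(ch) < 3L) return(0)
  s <- s[ch]; t <- t[ch]
  abs(sum(s * (t[c(2:length(t), 1)] - t[c(length(t), 1:(length(t) - 1))]))) / 2
}

# core of hull_intersection_volume, reusable with precomputed hulls.
# Every vertex of the intersection polytope is (a) a vertex of one hull
# inside the other, or (b) an edge of one hull crossing a facet of the
# other. The volume then follows from the divergence theorem: every facet
# of the intersection lies on a known plane (of A or B), so each plane's
# on-plane feasible candidates form a facet polygon whose area is taken by
# a 2-D convex hull -- deliberately avoiding a 3-D re-hull of the heavily
# coplanar candidate set. V = (1/3) sum_i d_i * area_i (outward unit
# normals n_i, planes n_i . x = d_i).
.hull_pair_intersection <- function(hA, hB, ptsA, ptsB) {
  # cheap bounding-box reject
  loA <- apply(ptsA, 2, min); hiA <- apply(ptsA, 2, max)
  loB <- apply(ptsB, 2, min); hiB <- apply(ptsB, 2, max)
  if (any(loA > hiB) || any(loB > hiA)) return(0)

  scale <- max(1, max(abs(ptsA)), max(abs(ptsB)))
  tol <- 1e-8 * scale
  plA <- .dedupe_planes(hA$normals, hA$offsets)
  plB <- .dedupe_planes(hB$normals, hB$offsets)
  inside <- function(X, pl) {
    rowSums(X %*% t(pl$N) <= matrix(pl$d + tol, nrow(X), length(pl$d),
                                    byrow = TRUE)) == length(pl$d)
  }
  VA <- ptsA[hA$vertices, , drop = FALSE]
  VB <- ptsB[hB$vertices, , drop = FALSE]
  eA <- .hull_edges(hA)
  eB <- .hull_edges(hB)
  cand <- rbind(
    VA[inside(VA, plB), , drop = FALSE],
    VB[inside(VB, plA), , drop = FALSE],
    .segment_plane_points(ptsA[eA[, 1], , drop = FALSE],
                          ptsA[eA[, 2], , drop = FALSE], plB$N, plB$d),
    .segment_plane_points(ptsB[eB[, 1], , drop = FALSE],
                          ptsB[eB[, 2], , drop = FALSE], plA$N, plA$d))
  if (nrow(cand) < 4L) return(0)
  keep <- inside(cand, plA) & inside(cand, plB)
  X <- cand[keep, , drop = FALSE]
  if (nrow(X) < 4L) return(0)
  # one combined plane list (cross-hull duplicates merged, else a shared
  # facet plane would be double-counted)
  pl <- .dedupe_planes(rbind(plA$N, plB$N), c(plA$d, plB$d))
  vol <- 0
  for (i in seq_along(pl$d)) {
    on <- abs(drop(X %*% pl$N[i, ]) - pl$d[i]) <= 1e-7 * scale
    if (sum(on) < 3L) next
    vol <- vol + pl$d[i] * .plane_polygon_area(X[on, , drop = FALSE],
                                               pl$N[i, ])
  }
  max(vol / 3, 0)
}
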