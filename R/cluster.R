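#' Density-based clustering (DBSCAN) of 3D points
#'
#' Classic DBSCAN: points with at least `min_samples` neighbours within `eps`
#' (themselves included) are core points; clusters are the connected
#' components of core points under the eps-neighbour relation, plus the
#' non-core points reachable from them. Unreachable points are noise, label
#' -1. Used for splitting a sparse point cloud into leaves and for grouping
#' reconstructed fragment points into loops.
#'
#' @param points Nx2 or Nx3 numeric matrix.
#' @param eps neighbourhood radius (same units as `points`, typically mm).
#' @param min_samples minimum neighbourhood size for a core point.
#' @return integer vector of cluster labels (1, 2, ...; -1 for noise).
#' @export
dbscan_points <- function(points, eps, min_samples) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  stopifnot(n >= min_samples, eps > 0)
  # neighbour lists via blocked distance computation
  nb <- vector("list", n)
  block <- max(1L, floor(2e6 / n))
  for (s in seq(1L, n, by = block)) {
    idx <- s:min(n, s + block - 1L)
    d2 <- outer(rowSums(pts[idx, , drop = FALSE]^2), rowSums(pts^2), "+") -
      2 * pts[idx, , drop = FALSE] %*% t(pts)
    hit <- d2 <= eps^2 + 1e-12
    for (r in seq_along(idx)) nb[[idx[r]]] <- which(hit[r, ])
  }
  core <- vapply(nb, length, integer(1)) >= min_samples
  labels <- rep(0L, n) # 0 = unvisited
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue) > 0L) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      for (q in nb[[j]]) {
        if (labels[q] == 0L || labels[q] == -1L) {
          newly <- labels[q] == 0L
          labels[q] <- cl
          if (core[q] && newly) queue <- c(queue, q)
        }
      }
    }
  }
  labels[labels == 0L] <- -1L
  if (all(labels == -1L)) stop("DBSCAN found no cluster: all points are noise")
  labels
}

#' Convex hull of 3D points (incremental algorithm)
#'
#' Randomless incremental hull: seed tetrahedron from extreme points, then for
#' each remaining point find the faces it sees, remove them, and re-triangulate
#' the horizon. Returns the indices of points that are hull vertices.
#'
#' @param points Nx3 numeric matrix.
#' @return list with `vertices` (integer indices of hull vertices) and
#'   `faces` (Fx3 integer matrix of point indices, outward-oriented).
#' @export
convex_hull_3d <- function(points) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < 4L) stop("convex hull needs at least 4 points")
  scale <- max(apply(pts, 2, function(c.) diff(range(c.))))
  if (scale == 0) stop("degenerate point set: all points identical")
  tol <- 1e-10 * scale

  # seed tetrahedron from extremes
  i1 <- which.min(pts[, 1])
  d1 <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d1)
  ab <- pts[i2, ] - pts[i1, ]
  ap <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(ap[, 2] * ab[3] - ap[, 3] * ab[2],
              ap[, 3] * ab[1] - ap[, 1] * ab[3],
              ap[, 1] * ab[2] - ap[, 2] * ab[1])
  dline <- rowSums(cr^2)
  i3 <- which.max(dline)
  if (dline[i3] <= (tol * scale)^2) stop("degenerate point set: points are collinear")
  nrm0 <- pracma_cross(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  dplane <- abs(ap %*% nrm0) / sqrt(sum(nrm0^2))
  i4 <- which.max(dplane)
  if (dplane[i4] <= tol) stop("degenerate point set: points are coplanar")

  centroid <- colMeans(pts[c(i1, i2, i3, i4), ])
  # face store: index triples FV, unit outward normals FN, offsets Foff
  make_faces <- function(tri) {
    a <- pts[tri[, 1], , drop = FALSE]
    b <- pts[tri[, 2], , drop = FALSE]
    c. <- pts[tri[, 3], , drop = FALSE]
    e1 <- b - a; e2 <- c. - a
    nv <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    nn <- sqrt(rowSums(nv^2))
    nn[nn == 0] <- 1
    nv <- nv / nn
    flip <- rowSums(nv * (matrix(centroid, nrow(tri), 3, byrow = TRUE) - a)) > 0
    if (any(flip)) {
      tri[flip, 2:3] <- tri[flip, 3:2]
      nv[flip, ] <- -nv[flip, , drop = FALSE]
    }
    list(v = tri, n = nv, off = rowSums(nv * a))
  }
  f0 <- make_faces(rbind(c(i1, i2, i3), c(i1, i2, i4),
                         c(i1, i3, i4), c(i2, i3, i4)))
  FV <- f0$v; FN <- f0$n; Foff <- f0$off

  # far points first: grows the hull fast so later points are interior
  rest <- setdiff(order(rowSums(sweep(pts, 2, centroid)^2),
                        decreasing = TRUE), c(i1, i2, i3, i4))
  for (p in rest) {
    vis <- (FN %*% pts[p, ] - Foff) > tol
    if (!any(vis)) next
    visv <- FV[vis, , drop = FALSE]
    edges <- rbind(visv[, c(1, 2), drop = FALSE],
                   visv[, c(2, 3), drop = FALSE],
                   visv[, c(3, 1), drop = FALSE])
    keys <- edges[, 1] * (n + 1) + edges[, 2]
    rkeys <- edges[, 2] * (n + 1) + edges[, 1]
    horizon <- edges[!(keys %in% rkeys), , drop = FALSE]
    keep <- !vis
    nf <- make_faces(cbind(horizon, p))
    FV <- rbind(FV[keep, , drop = FALSE], nf$v)
    FN <- rbind(FN[keep, , drop = FALSE], nf$n)
    Foff <- c(Foff[keep], nf$off)
  }
  list(vertices = sort(unique(as.vector(FV))), faces = unname(FV))
}

#' Hidden point removal by spherical flipping
#'
#' Determines which points of a cloud are visible from a viewpoint: translate
#' the cloud so the viewpoint is the origin, reflect each point p to
#' p' = p + 2 (R - |p|) p / |p| with R = radius_factor * max |p| (spherical
#' flip), and take the convex hull of the flipped points together with the
#' origin; points whose flips are hull vertices are visible.
#'
#' @param points Nx3 matrix, world mm.
#' @param viewpoint 3-vector, world mm (typically a camera centre).
#' @param radius_factor multiple of the largest viewpoint distance used as
#'   the flipping sphere radius (default 100).
#' @return integer indices (rows of `points`) of visible points.
#' @export
hidden_point_removal <- function(points, viewpoint, radius_factor = 100) {
  pts <- to_matrix3(points)
  n <- nrow(pts)
  q <- sweep(pts, 2, viewpoint)
  nrm <- sqrt(rowSums(q^2))
  if (any(nrm < 1e-12)) stop("a point coincides with the viewpoint")
  R <- radius_factor * max(nrm)
  flipped <- q * (1 + 2 * (R - nrm) / nrm)
  hull <- tryCatch(
    convex_hull_3d(rbind(flipped, c(0, 0, 0))),
    error = function(e) NULL
  )
  if (is.null(hull)) {
    # degenerate cloud (coplanar/collinear as seen after flipping): nothing
    # can occlude anything that the hull could detect; report all visible
    warning("degenerate geometry in hidden point removal; treating all points as visible")
    return(seq_len(n))
  }
  sort(hull$vertices[hull$vertices <= n])
}
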