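#' Projective camera model and epipolar geometry
#'
#' A camera is a 3x4 projection matrix P mapping homogeneous world coordinates
#' (mm) to homogeneous pixel coordinates. The optical centre is the right null
#' space of P. Pixel coordinates are 0-based, origin at the top-left pixel
#' centre, u rightward, v downward; sub-pixel values are allowed.
#'
#' @param P 3x4 numeric projection matrix of rank 3.
#' @param view_id integer view identifier.
#' @param image_size optional c(width, height) in pixels.
#' @return An object of class `camera` with elements `P`, `center`, `view_id`,
#'   `image_size`.
#' @examples
#' cam <- camera(cbind(diag(3), c(0, 0, 0)), view_id = 1L)
#' cam$center
#' @export
camera <- function(P, view_id = NA_integer_, image_size = NULL) {
  P <- as.matrix(P)
  stopifnot(nrow(P) == 3L, ncol(P) == 4L, all(is.finite(P)))
  s <- svd(P)
  if (s$d[3] <= 1e-12 * s$d[1]) {
    stop("projection matrix must have rank 3")
  }
  # camera centre: right null vector of P
  n <- svd(P, nu = 0, nv = 4)$v[, 4]
  if (abs(n[4]) < 1e-14 * max(abs(n))) {
    stop("camera centre at infinity is not supported")
  }
  center <- n[1:3] / n[4]
  structure(
    list(P = P, center = center, view_id = as.integer(view_id),
         image_size = if (!is.null(image_size)) as.numeric(image_size)),
    class = "camera"
  )
}

#' @export
print.camera <- function(x, ...) {
  cat(sprintf("<camera view_id=%s centre=(%.2f, %.2f, %.2f) mm>\n",
              x$view_id, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Build a pinhole camera from intrinsics and pose
#'
#' Convenience constructor: P = K [R | -R c] with K built from a focal length
#' in pixels and a principal point, R the world-to-camera rotation, and c the
#' camera centre in world mm.
#'
#' @param focal_px focal length in pixels (same for u and v).
#' @param principal c(u0, v0) principal point in pixels.
#' @param R 3x3 world-to-camera rotation matrix (rows: camera x, y, z axes).
#' @param center camera centre, world mm.
#' @inheritParams camera
#' @return A `camera` object.
#' @export
pinhole_camera <- function(focal_px, principal, R, center,
                           view_id = NA_integer_, image_size = NULL) {
  K <- rbind(c(focal_px, 0, principal[1]),
             c(0, focal_px, principal[2]),
             c(0, 0, 1))
  P <- K %*% cbind(R, -R %*% center)
  camera(P, view_id = view_id, image_size = image_size)
}

#' Look-at rotation for a camera
#'
#' Returns a world-to-camera rotation whose +z axis points from `center`
#' towards `target`, with image v (down) chosen from the world `up` vector.
#'
#' @param center camera centre, world mm.
#' @param target point the optical axis passes through, world mm.
#' @param up approximate world up direction (default +z).
#' @return 3x3 rotation matrix.
#' @export
look_at_rotation <- function(center, target, up = c(0, 0, 1)) {
  z <- target - center
  nz <- sqrt(sum(z^2))
  stopifnot(nz > 0)
  z <- z / nz
  x <- pracma_cross(z, up)
  nx <- sqrt(sum(x^2))
  if (nx < 1e-12) { # optical axis parallel to up: pick another up
    x <- pracma_cross(z, c(1, 0, 0))
    nx <- sqrt(sum(x^2))
  }
  x <- x / nx
  y <- pracma_cross(z, x) # points "down" in image (v grows downward)
  rbind(x, y, z, deparse.level = 0)
}

# cross product (kept local; avoids pulling a dependency for one primitive)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Camera rig
#'
#' An ordered collection of cameras with the arithmetic mean of their centres,
#' used to measure inter-camera angles when admitting camera pairs.
#'
#' @param cameras list of [camera()] objects (at least 2).
#' @return Object of class `camera_rig` with `cameras` and `mean_position`.
#' @export
camera_rig <- function(cameras) {
  stopifnot(length(cameras) >= 2L,
            all(vapply(cameras, inherits, logical(1), "camera")))
  centers <- t(vapply(cameras, function(c.) c.$center, numeric(3)))
  structure(
    list(cameras = cameras, mean_position = colMeans(centers)),
    class = "camera_rig"
  )
}

#' @export
print.camera_rig <- function(x, ...) {
  cat(sprintf("<camera_rig of %d cameras, mean position (%.1f, %.1f, %.1f) mm>\n",
              length(x$cameras), x$mean_position[1], x$mean_position[2],
              x$mean_position[3]))
  invisible(x)
}

#' Project world points into a camera
#'
#' Dehomogenised pinhole projection. Points at the camera centre or behind the
#' camera (non-positive homogeneous w) are an error unless `allow_behind` is
#' set, in which case their rows are NA.
#'
#' @param cam a [camera()].
#' @param points numeric 3-vector or Nx3 matrix, world mm.
#' @param allow_behind if TRUE, invalid projections give NA rows instead of an
#'   error.
#' @return Nx2 matrix of pixel coordinates (u, v).
#' @export
project_points <- function(cam, points, allow_behind = FALSE) {
  X <- to_matrix3(points)
  Xh <- cbind(X, 1)
  Y <- Xh %*% t(cam$P)
  w <- Y[, 3]
  bad <- !is.finite(w) | w <= 1e-12
  if (any(bad) && !allow_behind) {
    stop("point at or behind the camera cannot be projected")
  }
  uv <- Y[, 1:2, drop = FALSE] / w
  if (any(bad)) uv[bad, ] <- NA_real_
  uv
}

to_matrix3 <- function(points) {
  if (is.null(dim(points))) {
    stopifnot(length(points) == 3L)
    matrix(points, 1L, 3L)
  } else {
    stopifnot(ncol(points) == 3L)
    as.matrix(points)
  }
}

#' Fundamental matrix between two known cameras
#'
#' F maps a point x_i in view i to its epipolar line l_j = F x_i in view j,
#' so that corresponding points satisfy x_j' F x_i = 0. Computed from the
#' projection matrices via the epipole construction: e_j = P_j C_i,
#' F = [e_j]_x P_j P_i^+ . Normalised to unit Frobenius norm.
#'
#' @param cam_i,cam_j [camera()] objects with distinct centres.
#' @return 3x3 rank-2 matrix with unit Frobenius norm.
#' @export
fundamental_matrix <- function(cam_i, cam_j) {
  if (sqrt(sum((cam_i$center - cam_j$center)^2)) < 1e-9) {
    stop("degenerate camera pair: identical centres")
  }
  Ci <- c(cam_i$center, 1)
  ej <- as.numeric(cam_j$P %*% Ci)
  ex <- rbind(c(0, -ej[3], ej[2]),
              c(ej[3], 0, -ej[1]),
              c(-ej[2], ej[1], 0))
  Pi_pinv <- pseudo_inverse(cam_i$P)
  F <- ex %*% cam_j$P %*% Pi_pinv
  F / sqrt(sum(F^2))
}

pseudo_inverse <- function(A) {
  s <- svd(A)
  tol <- max(dim(A)) * max(s$d) * .Machine$double.eps
  dinv <- ifelse(s$d > tol, 1 / s$d, 0)
  s$v %*% (dinv * t(s$u))
}

#' Epipolar line of image-i points in image j
#'
#' @param F fundamental matrix from view i to view j.
#' @param points_i 2-vector or Nx2 pixel coordinates in view i.
#' @return Nx3 matrix of homogeneous line coordinates (a, b, c), normalised so
#'   a^2 + b^2 = 1 (signed point-line distance is then a*u + b*v + c).
#' @export
epipolar_lines <- function(F, points_i) {
  x <- to_matrix2(points_i)
  L <- cbind(x, 1) %*% t(F)
  nrm <- sqrt(L[, 1]^2 + L[, 2]^2)
  L / nrm
}

to_matrix2 <- function(points) {
  if (is.null(dim(points))) {
    stopifnot(length(points) == 2L)
    matrix(points, 1L, 2L)
  } else {
    stopifnot(ncol(points) == 2L)
    as.matrix(points)
  }
}

#' Triangulate point correspondences from two views
#'
#' Homogeneous linear (DLT) triangulation: for each correspondence the 4x4
#' system stacks u*P3 - P1 and v*P3 - P2 for both views; the solution is the
#' right singular vector of the smallest singular value. Exact on noise-free
#' correspondences.
#'
#' @param cam_i,cam_j [camera()] objects with distinct centres.
#' @param x_i,x_j 2-vectors or Nx2 matrices of corresponding pixel coordinates.
#' @return Nx3 matrix of world points (mm).
#' @export
triangulate_points <- function(cam_i, cam_j, x_i, x_j) {
  if (sqrt(sum((cam_i$center - cam_j$center)^2)) < 1e-9) {
    stop("degenerate geometry: identical camera centres")
  }
  xi <- to_matrix2(x_i); xj <- to_matrix2(x_j)
  stopifnot(nrow(xi) == nrow(xj))
  Pi <- cam_i$P; Pj <- cam_j$P
  n <- nrow(xi)
  out <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    A <- rbind(xi[k, 1] * Pi[3, ] - Pi[1, ],
               xi[k, 2] * Pi[3, ] - Pi[2, ],
               xj[k, 1] * Pj[3, ] - Pj[1, ],
               xj[k, 2] * Pj[3, ] - Pj[2, ])
    # scale rows for numerical balance
    rs <- sqrt(rowSums(A^2))
    rs[rs == 0] <- 1
    v <- svd(A / rs, nu = 0, nv = 4)$v[, 4]
    if (abs(v[4]) < 1e-14 * max(abs(v))) {
      stop("degenerate geometry: triangulated point at infinity (parallel rays?)")
    }
    out[k, ] <- v[1:3] / v[4]
  }
  out
}

#' Angle between two cameras as seen from the rig centre
#'
#' The pairing angle b_ij is the angle at the mean camera position between the
#' directions to the two camera centres, in degrees in [0, 180].
#'
#' @param rig a [camera_rig()].
#' @param i,j distinct camera indices (1-based).
#' @return angle in degrees.
#' @export
pair_angle <- function(rig, i, j) {
  stopifnot(inherits(rig, "camera_rig"))
  if (i == j) stop("pair_angle requires two distinct cameras")
  p <- rig$mean_position
  a <- rig$cameras[[i]]$center - p
  b <- rig$cameras[[j]]$center - p
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) {
    stop("camera centre coincides with the rig mean position")
  }
  cth <- sum(a * b) / (na * nb)
  acos(pmin(1, pmax(-1, cth))) * 180 / pi
}

#' Epipolar band of a 2D curve fragment
#'
#' The set of epipolar lines of all points of a source fragment, summarised by
#' the two extreme lines of the pencil and dilated outward by a pixel margin.
#' Membership is tested with [point_in_band()].
#'
#' All epipolar lines of one image pass through the epipole, so the band is a
#' wedge; lines are sorted by their angle about the epipole and the two
#' extremes bound the wedge. Point membership is evaluated as signed distance
#' to the two boundary lines (consistent side, within dilation).
#'
#' @param F fundamental matrix from the fragment's view to the target view.
#' @param fragment_points Nx2 pixel coordinates of the source fragment.
#' @param dilation_px outward dilation of the band in pixels (default 2).
#' @return Object of class `epipolar_band` with `F`, `boundary_lines` (2x3,
#'   normalised), `dilation_px`, and `lines` (all member lines).
#' @export
epipolar_band <- function(F, fragment_points, dilation_px = 2) {
  pts <- to_matrix2(fragment_points)
  L <- epipolar_lines(F, pts)
  # Reference line: first point's line. Order the pencil by signed rotation
  # of (a,b) normals relative to the reference; extremes bound the wedge.
  ref <- L[1, ]
  ang <- atan2(L[, 1] * ref[2] - L[, 2] * ref[1],
               L[, 1] * ref[1] + L[, 2] * ref[2])
  lo <- which.min(ang); hi <- which.max(ang)
  structure(
    list(F = F, boundary_lines = rbind(L[lo, ], L[hi, ]),
         dilation_px = dilation_px, lines = L),
    class = "epipolar_band"
  )
}

#' Test pixel points for membership in an epipolar band
#'
#' A point lies in the band if it is between the two extreme epipolar lines of
#' the pencil, or within `dilation_px` of one of the member lines. Because the
#' pencil varies continuously over the source fragment, a point between the
#' extremes has member lines on both sides, so the test reduces to signed
#' distances against all member lines: inside iff min(d) <= dilation and
#' max(d) >= -dilation.
#'
#' @param band an [epipolar_band()].
#' @param points 2-vector or Nx2 pixel coordinates.
#' @return logical vector, one element per point.
#' @export
point_in_band <- function(band, points) {
  pts <- to_matrix2(points)
  L <- band$lines
  # signed distances: points x lines
  D <- pts %*% t(L[, 1:2, drop = FALSE]) +
    matrix(L[, 3], nrow(pts), nrow(L), byrow = TRUE)
  dmin <- apply(D, 1, min)
  dmax <- apply(D, 1, max)
  (dmin <= band$dilation_px) & (dmax >= -band$dilation_px)
}
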