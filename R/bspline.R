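#' Closed periodic B-spline fitting of leaf edge loops
#'
#' A closed leaf edge loop is modelled as a periodic piecewise-polynomial
#' curve f(l) = w b(l), l in [0, 1), with one coefficient vector per spatial
#' coordinate. The basis b(l) has n - 1 entries over uniform intervals: the
#' first n - k - 1 entries are plain uniform B-spline basis functions of
#' degree k, and the last k entries are wrap-around sums b_i(l) + b_{i-(n-1)}(l)
#' that enforce closure, so the periodic domain carries n - 1 uniform
#' intervals (knot spacing 1/(n - 1)).
#'
#' @name closed-bspline
#' @keywords internal
NULL

# Cardinal B-spline of degree d with support [0, d + 1), by the Cox-de Boor
# convolution recursion, vectorised over x.
cardinal_bspline <- function(x, d) {
  if (d == 0L) {
    return(as.numeric(x >= 0 & x < 1))
  }
  (x * cardinal_bspline(x, d - 1L) +
     ((d + 1) - x) * cardinal_bspline(x - 1, d - 1L)) / d
}

#' Design matrix of the closed periodic B-spline basis
#'
#' One row per parameter value, n - 1 columns. Columns 1 .. n-k-1 are plain
#' basis functions; columns n-k .. n-1 are wrap-around sums pairing basis i
#' with basis i - (n - 1). Rows sum to 1 (partition of unity) and are
#' 1-periodic in the parameter.
#'
#' @param ls numeric vector of curve parameters (any real; used modulo 1).
#' @param n number of intervals parameter of the model (coefficient count is
#'   n - 1 per coordinate).
#' @param k spline degree (default 3, cubic).
#' @return numeric matrix, length(ls) x (n - 1).
#' @export
closed_bspline_design <- function(ls, n, k = 3L) {
  stopifnot(n >= k + 2, k >= 1)
  l <- ls %% 1
  x <- (n - 1) * l
  m <- n - 1L
  B <- matrix(0, length(x), m)
  for (i in seq_len(m)) {
    v <- cardinal_bspline(x - (i - 1), k)
    if (i >= n - k) {
      v <- v + cardinal_bspline(x - i + n, k)
    }
    B[, i] <- v
  }
  B
}

#' Fit a closed periodic B-spline to parameterised loop samples
#'
#' Per-coordinate linear least squares of the sample positions against the
#' closed B-spline design matrix. A rank-deficient design (large gaps in the
#' parameter coverage, so some basis functions are never observed) is an
#' error; the message reports the largest cyclic parameter gap, which is the
#' quantity to inspect when a loop is only partially covered by curve
#' fragments.
#'
#' @param ls numeric vector of curve parameters in [0, 1).
#' @param points matrix with one row per sample (typically Nx3, world mm).
#' @param n number of intervals (16 is the working default; 64 for highly
#'   detailed shapes).
#' @param k spline degree (default 3).
#' @return Object of class `closed_bspline`: list with `coeffs`
#'   ((n-1) x ncol(points)), `n`, `k`, `rms` residual, `n_samples`.
#' @export
fit_closed_bspline <- function(ls, points, n = 16L, k = 3L) {
  pts <- as.matrix(points)
  stopifnot(length(ls) == nrow(pts), nrow(pts) >= n - 1)
  B <- closed_bspline_design(ls, n, k)
  qrB <- qr(B)
  if (qrB$rank < ncol(B)) {
    sl <- sort(ls %% 1)
    gaps <- diff(c(sl, sl[1] + 1))
    stop(sprintf(
      "ill-conditioned closed B-spline fit: design rank %d < %d; largest parameter gap %.3f",
      qrB$rank, ncol(B), max(gaps)))
  }
  coeffs <- qr.coef(qrB, pts)
  resid <- pts - B %*% coeffs
  structure(
    list(coeffs = unname(coeffs), n = as.integer(n), k = as.integer(k),
         rms = sqrt(mean(rowSums(resid^2))), n_samples = nrow(pts)),
    class = "closed_bspline"
  )
}

#' Evaluate a closed B-spline model
#'
#' @param model a [fit_closed_bspline()] result (or any list with `coeffs`,
#'   `n`, `k`).
#' @param ls numeric vector of parameters; the curve is 1-periodic.
#' @return matrix length(ls) x ncol(coeffs) of curve points.
#' @export
evaluate_bspline <- function(model, ls) {
  B <- closed_bspline_design(ls, model$n, model$k)
  B %*% model$coeffs
}

#' @export
print.closed_bspline <- function(x, ...) {
  cat(sprintf("<closed_bspline n=%d k=%d (%d coefficients/coordinate), rms %.4g from %d samples>\n",
              x$n, x$k, x$n - 1L, x$rms, x$n_samples))
  invisible(x)
}

#' Sample a closed B-spline as a closed polyline
#'
#' @param model a `closed_bspline`.
#' @param n_points number of samples over one period (default 256).
#' @param close if TRUE (default) the first point is repeated at the end.
#' @return matrix of curve points.
#' @export
sample_bspline <- function(model, n_points = 256L, close = TRUE) {
  pts <- evaluate_bspline(model, seq(0, 1, length.out = n_points + 1L)[-(n_points + 1L)])
  if (close) pts <- rbind(pts, pts[1, , drop = FALSE])
  pts
}

#' Order loop points by polar angle in their best-fit plane
#'
#' Reconstructed 3D fragment points of one loop arrive unordered; the fit
#' needs an abscissa. Leaves are near-planar, so the points are projected on
#' their PCA best-fit plane and parameterised by the normalised polar angle
#' about the projected centroid. Fails on (near-)collinear point sets, where
#' no plane or angular order is defined.
#'
#' @param points Nx3 matrix of loop points, world mm.
#' @return list with `l` (sorted parameters in [0,1)), `points` (rows sorted
#'   to match), `order` (permutation applied), `center`, `basis` (3x2 in-plane
#'   axes).
#' @export
parameterize_loop <- function(points) {
  pts <- to_matrix3(points)
  stopifnot(nrow(pts) >= 3)
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  sv <- svd(X, nu = 0)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300)) {
    stop("degenerate loop: points are collinear, no plane parameterization")
  }
  E <- sv$v[, 1:2]
  uv <- X %*% E
  theta <- atan2(uv[, 2], uv[, 1])
  l <- (theta %% (2 * pi)) / (2 * pi)
  ord <- order(l) # stable in R for ties
  list(l = l[ord], points = pts[ord, , drop = FALSE], order = ord,
       center = ctr, basis = E)
}
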