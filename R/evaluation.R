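#' Quantitative evaluation of reconstructed leaf edges
#'
#' Accuracy is measured with the discrete Frechet distance between the
#' reconstructed and true edge, standardised by the square root of the leaf
#' area (SFD) so differently sized leaves are comparable. Occlusion is
#' summarised by the occlusion index (OI), the mean fraction of a leaf's
#' cloud points hidden across views. The support threshold tau_t is tuned by
#' a precision-recall sweep and summarised in a regression guideline against
#' OI.
#'
#' @name evaluation
#' @keywords internal
NULL

#' Discrete Frechet distance between two polylines
#'
#' Dynamic-programming discrete Frechet distance over the polyline vertices;
#' symmetric in its arguments. For metric comparisons of reconstruction and
#' truth, both curves should be resampled to a common arc-length spacing
#' (`resample_mm = 1` is the working choice); with `resample_mm = NULL` the
#' vertices are used as given.
#'
#' @param a,b matrices of ordered vertices (Nx2 or Nx3).
#' @param resample_mm optional uniform resampling spacing applied to both
#'   curves before the DP.
#' @return distance in the curves' units (mm).
#' @export
discrete_frechet <- function(a, b, resample_mm = NULL) {
  A <- as.matrix(a); B <- as.matrix(b)
  if (!is.null(resample_mm)) {
    A <- resample_polyline(A, resample_mm)
    B <- resample_polyline(B, resample_mm)
  }
  na <- nrow(A); nb <- nrow(B)
  stopifnot(na >= 1L, nb >= 1L)
  # pairwise distances, computed by differences (exact zeros on identical
  # vertices, unlike the expanded quadratic form)
  d <- matrix(0, na, nb)
  tA <- t(A)
  for (j in seq_len(nb)) {
    d[, j] <- sqrt(colSums((tA - B[j, ])^2))
  }
  # DP vectorised over anti-diagonals: cell (i, j) depends on (i-1, j) and
  # (i, j-1) on the previous diagonal and (i-1, j-1) two diagonals back
  v_prev2 <- rep(Inf, na) # diagonal s - 2, indexed by i
  v_prev <- rep(Inf, na)  # diagonal s - 1
  v_prev[1] <- d[1, 1]    # s = 2 holds only (1, 1)
  if (na == 1L && nb == 1L) return(d[1, 1])
  for (s in 3:(na + nb)) {
    i <- max(1L, s - nb):min(na, s - 1L)
    up <- c(Inf, v_prev)[i]        # (i-1, j)   = v_prev[i - 1]
    left <- v_prev[i]              # (i, j-1)   = v_prev[i]
    diag2 <- c(Inf, v_prev2)[i]    # (i-1, j-1) = v_prev2[i - 1]
    v_new <- rep(Inf, na)
    v_new[i] <- pmax(pmin(up, left, diag2), d[cbind(i, s - i)])
    v_prev2 <- v_prev
    v_prev <- v_new
  }
  v_prev[na]
}

#' Discrete Frechet distance between two closed curves
#'
#' The discrete Frechet distance of closed curves is minimised over the
#' cyclic start alignment and traversal direction. Both loops are resampled
#' at `resample_mm`; the start of `a` is rotated to the sample nearest the
#' start of `b`, a small window of neighbouring shifts is searched, and both
#' orientations of `a` are tried.
#'
#' The default spacing adapts to the curve scale: 1/400 of the longer
#' perimeter, capped at the working 1 mm and floored at 0.1 mm. Sub-mm
#' reconstruction errors would otherwise be aliased by the sampling floor
#' (the discrete distance cannot fall below about half the spacing), while
#' at real leaf scales the default converges to the stated 1 mm.
#'
#' @param a,b closed polylines (first vertex repeated last or not; treated as
#'   cyclic).
#' @param resample_mm uniform resampling spacing; NULL (default) for the
#'   adaptive spacing above.
#' @param window number of neighbouring start shifts tried on each side of
#'   the nearest-point alignment (default 3).
#' @return distance in mm.
#' @export
frechet_closed <- function(a, b, resample_mm = NULL, window = 3L) {
  if (is.null(resample_mm)) {
    perim <- max(polyline_length(as.matrix(a)), polyline_length(as.matrix(b)))
    resample_mm <- min(1, max(0.1, perim / 400))
  }
  cyc <- function(p) { # cyclic sample set (no duplicated closure point)
    p <- as.matrix(p)
    if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    q <- resample_polyline(rbind(p, p[1, , drop = FALSE]), resample_mm)
    q[-nrow(q), , drop = FALSE]
  }
  A <- cyc(a); B <- cyc(b)
  close_up <- function(p) rbind(p, p[1, , drop = FALSE])
  best <- Inf
  for (dir in 1:2) {
    Ad <- if (dir == 1L) A else A[nrow(A):1, , drop = FALSE]
    base <- which.min(colSums((t(Ad) - B[1, ])^2))
    shifts <- unique((base - 1 + (-window):window) %% nrow(Ad)) + 1L
    for (s in shifts) {
      Ar <- Ad[c(s:nrow(Ad), if (s > 1L) 1:(s - 1L)), , drop = FALSE]
      best <- min(best, discrete_frechet(close_up(Ar), close_up(B)))
    }
  }
  best
}

#' Standardised Frechet distance (SFD)
#'
#' Frechet distance divided by the square root of the leaf's planform area,
#' making accuracy comparable across leaf sizes (scale-invariant).
#'
#' @param frechet Frechet distance, mm.
#' @param area leaf planform area, mm^2.
#' @return unitless SFD.
#' @export
sfd <- function(frechet, area) {
  stopifnot(frechet >= 0, area > 0)
  frechet / sqrt(area)
}

#' Occlusion index
#'
#' OI = (1/m) * sum_i (1 - n_i / n): the mean, over the m views, of the
#' fraction of the leaf's cloud points not visible on its own mask. 0 means
#' never occluded, 1 always occluded.
#'
#' @param n_i integer vector of per-view reprojected point counts (length m).
#' @param n total number of cloud points of the leaf.
#' @return OI in `[0, 1]`.
#' @export
occlusion_index <- function(n_i, n) {
  stopifnot(n > 0, all(n_i >= 0), all(n_i <= n))
  mean(1 - n_i / n)
}

#' Precision and recall of reconstructed fragments against the true edge
#'
#' The true edge is resampled at 1 mm. Precision is the fraction of truth
#' samples that have a reconstructed fragment point within `radius`; recall
#' is the fraction of fragment points that have a truth sample within
#' `radius`. (This orientation — precision over ground-truth samples, recall
#' over reconstructed points — is kept as such deliberately; set
#' `swap = TRUE` for the conventional orientation.) An empty fragment set
#' gives precision 0 and recall 0.
#'
#' @param fragment_points Nx3 matrix of reconstructed curve fragment points
#'   (pool of all surviving fragments), mm.
#' @param truth closed true edge polyline (Mx3) or list of polylines, mm.
#' @param radius match radius, mm (default 30).
#' @param swap swap the two fractions (conventional orientation).
#' @return named numeric vector c(precision, recall).
#' @export
precision_recall <- function(fragment_points, truth, radius = 30,
                             swap = FALSE) {
  truth_list <- if (is.list(truth)) truth else list(truth)
  Tr <- do.call(rbind, lapply(truth_list, resample_polyline, spacing = 1))
  if (is.null(fragment_points) || nrow(as.matrix(fragment_points)) == 0L) {
    return(c(precision = 0, recall = 0))
  }
  P <- to_matrix3(fragment_points)
  # nearest-neighbour distances both ways (chunked)
  min_dist <- function(Q, R) {
    out <- numeric(nrow(Q))
    blk <- max(1L, floor(4e6 / nrow(R)))
    for (s in seq(1L, nrow(Q), by = blk)) {
      ix <- s:min(nrow(Q), s + blk - 1L)
      d2 <- outer(rowSums(Q[ix, , drop = FALSE]^2), rowSums(R^2), "+") -
        2 * Q[ix, , drop = FALSE] %*% t(R)
      out[ix] <- sqrt(pmax(0, apply(d2, 1, min)))
    }
    out
  }
  precision <- mean(min_dist(Tr, P) <= radius)
  recall <- mean(min_dist(P, Tr) <= radius)
  if (swap) {
    c(precision = recall, recall = precision)
  } else {
    c(precision = precision, recall = recall)
  }
}

#' Default support-threshold sweep grid
#' @return eight ratios from 0.125 to 1.
#' @export
tau_t_grid <- function() seq(0.125, 1, by = 0.125)

#' Precision-recall sweep over the support threshold
#'
#' Re-filters an already support-evaluated sketch at each grid ratio and
#' computes precision/recall against the true edge.
#'
#' @param sketch result of [sketch_leaf()] (uses `fragments` and `m`).
#' @param truth true closed edge polyline(s), mm.
#' @param radius match radius, mm (default 30).
#' @param grid tau_t ratios (default [tau_t_grid()]).
#' @return data.frame with tau_t_ratio, precision, recall, n_fragments.
#' @export
sweep_support_threshold <- function(sketch, truth, radius = 30,
                                    grid = tau_t_grid()) {
  rows <- lapply(grid, function(r) {
    kept <- support_filter(sketch$fragments, sketch$m, r)
    pts <- if (length(kept)) do.call(rbind, lapply(kept, `[[`, "points"))
    pr <- precision_recall(pts, truth, radius)
    data.frame(tau_t_ratio = r, precision = pr[["precision"]],
               recall = pr[["recall"]], n_fragments = length(kept))
  })
  do.call(rbind, rows)
}

#' Optimal support threshold from a precision-recall table
#'
#' Among grid points with precision above `precision_bar` (0.99), picks those
#' with the highest recall, and of those the largest tau_t. If no grid point
#' clears the bar, the minimum grid value is returned, flagged.
#'
#' @param pr data.frame with columns tau_t_ratio, precision, recall (e.g.
#'   from [sweep_support_threshold()]).
#' @param precision_bar precision that must be exceeded (default 0.99).
#' @return list with `tau_t` and `flagged` (TRUE when the fallback minimum
#'   was used).
#' @export
optimal_support_threshold <- function(pr, precision_bar = 0.99) {
  ok <- pr$precision > precision_bar
  if (!any(ok)) {
    return(list(tau_t = min(pr$tau_t_ratio), flagged = TRUE))
  }
  sub <- pr[ok, , drop = FALSE]
  best <- sub[sub$recall >= max(sub$recall) - 1e-12, , drop = FALSE]
  list(tau_t = max(best$tau_t_ratio), flagged = FALSE)
}

#' Bayesian ridge regression (evidence maximisation)
#'
#' Linear model with a zero-mean isotropic Gaussian prior on the (centred)
#' coefficients and Gaussian noise; the prior precision lambda and noise
#' precision alpha are set by maximising the marginal likelihood (iterative
#' MacKay updates with weak Gamma hyperpriors). With negligible noise or
#' abundant data the fit approaches ordinary least squares.
#'
#' @param x predictor vector (or Nxp matrix).
#' @param y response vector.
#' @param max_iter,tol iteration controls.
#' @param hyper weak Gamma hyperprior parameter (default 1e-6).
#' @return object of class `bayes_ridge`: `coefficients` (intercept, slopes
#'   on the original scale), `alpha`, `lambda`, `sigma` (posterior
#'   coefficient covariance, centred scale), `x_center`, `y_center`.
#' @export
bayes_ridge <- function(x, y, max_iter = 300L, tol = 1e-10, hyper = 1e-6) {
  X <- as.matrix(x)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= p + 1L)
  xc <- colMeans(X); yc <- mean(y)
  Xc <- sweep(X, 2, xc); yv <- y - yc
  XtX <- crossprod(Xc); Xty <- crossprod(Xc, yv)
  ev <- eigen(XtX, symmetric = TRUE, only.values = TRUE)$values
  alpha <- 1 / max(stats::var(yv), 1e-12)
  lambda <- 1
  for (it in seq_len(max_iter)) {
    S <- solve(lambda * diag(p) + alpha * XtX)
    mu <- alpha * S %*% Xty
    gamma <- sum(alpha * ev / (lambda + alpha * ev))
    lambda_new <- (gamma + 2 * hyper) / (sum(mu^2) + 2 * hyper)
    rss <- sum((yv - Xc %*% mu)^2)
    alpha_new <- (n - gamma + 2 * hyper) / (rss + 2 * hyper)
    alpha_new <- min(alpha_new, 1e15)
    if (abs(log(alpha_new / alpha)) < tol &&
        abs(log(lambda_new / lambda)) < tol) {
      alpha <- alpha_new; lambda <- lambda_new
      break
    }
    alpha <- alpha_new; lambda <- lambda_new
  }
  S <- solve(lambda * diag(p) + alpha * XtX)
  mu <- as.numeric(alpha * S %*% Xty)
  coef <- c(intercept = yc - sum(mu * xc), mu)
  structure(list(coefficients = coef, alpha = alpha, lambda = lambda,
                 sigma = S, x_center = xc, y_center = yc, n = n),
            class = "bayes_ridge")
}

#' Posterior predictive mean and SD of a Bayesian ridge fit
#'
#' @param object a [bayes_ridge()] fit.
#' @param newdata predictor values (vector or matrix).
#' @param ... unused.
#' @return data.frame with `mean` and `sd` (predictive SD including noise).
#' @export
predict.bayes_ridge <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Xc <- sweep(X, 2, object$x_center)
  mu <- object$coefficients[-1]
  m <- object$coefficients[1] + as.numeric(X %*% mu)
  v <- 1 / object$alpha + rowSums((Xc %*% object$sigma) * Xc) +
    1 / (object$n * object$alpha)
  data.frame(mean = m, sd = sqrt(v))
}

#' Support-threshold guideline regression
#'
#' Bayesian ridge regression of per-leaf optimal support thresholds on the
#' occlusion index, with the three working lines used to choose tau_t in
#' practice: the predictive mean, mean - 0.25 SD, and mean - 0.5 SD.
#'
#' @param oi occlusion indices (one per leaf/scenario).
#' @param tau_opt matching optimal support thresholds.
#' @return object of class `threshold_guideline`: the `fit` ([bayes_ridge()])
#'   plus `lines(oi)` accessors via [predict_guideline()].
#' @export
fit_threshold_guideline <- function(oi, tau_opt) {
  stopifnot(length(oi) == length(tau_opt), length(oi) >= 3L)
  fit <- bayes_ridge(oi, tau_opt)
  structure(list(fit = fit, oi_range = range(oi)),
            class = "threshold_guideline")
}

#' Evaluate a threshold guideline
#'
#' @param g a [fit_threshold_guideline()] result.
#' @param oi occlusion index values.
#' @param line one of "mean", "mean-0.25sd", "mean-0.5sd".
#' @return recommended tau_t values (clamped to (0, 1]).
#' @export
predict_guideline <- function(g, oi, line = c("mean", "mean-0.25sd", "mean-0.5sd")) {
  line <- match.arg(line)
  pr <- predict(g$fit, oi)
  off <- switch(line, "mean" = 0, "mean-0.25sd" = 0.25, "mean-0.5sd" = 0.5)
  pmin(1, pmax(1e-6, pr$mean - off * pr$sd))
}

#' @export
print.threshold_guideline <- function(x, ...) {
  cf <- x$fit$coefficients
  cat(sprintf("<threshold_guideline: tau_t = %.3f %+.3f * OI (Bayesian ridge)>\n",
              cf[1], cf[2]))
  invisible(x)
}
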