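# independent Cox-de Boor recursion on the periodically extended uniform knot
# vector, used as the oracle for the closed design matrix
coxdeboor_basis <- function(x, i, k, knots) {
  if (k == 0L) {
    return(as.numeric(x >= knots[i] & x < knots[i + 1]))
  }
  a <- (x - knots[i]) / (knots[i + k] - knots[i])
  b <- (knots[i + k + 1] - x) / (knots[i + k + 1] - knots[i + 1])
  a * coxdeboor_basis(x, i, k - 1L, knots) +
    b * coxdeboor_basis(x, i + 1L, k - 1L, knots)
}

test_that("closed B-spline design is a periodic partition of unity", {
  ls <- seq(0, 0.999, length.out = 313)
  for (n in c(8L, 16L, 64L)) {
    D <- closed_bspline_design(ls, n, 3L)
    expect_equal(dim(D), c(length(ls), n - 1L))
    expect_lt(max(abs(rowSums(D) - 1)), 1e-12)
  }
  expect_equal(closed_bspline_design(0.3, 16L, 3L),
               closed_bspline_design(1.3, 16L, 3L), tolerance = 1e-12)
})

test_that("design basis matches a direct Cox-de Boor recursion", {
  n <- 12L; k <- 3L
  nint <- n - 1L # periodic intervals
  # plain (non-wrapping) columns: basis i spans knots (i-1)/nint ...
  knots <- (seq(-k, nint + k)) / nint
  ls <- seq(0.01, 0.99, length.out = 57)
  D <- closed_bspline_design(ls, n, k)
  # basis i is supported on [(i-1)/nint, (i+k)/nint); in the extended knot
  # vector (starting at -k/nint) that is the basis with start index i + k
  plain_ref <- function(i) coxdeboor_basis(ls, k + i, k, knots)
  for (i in seq_len(n - k - 1L)) {
    expect_equal(D[, i], plain_ref(i), tolerance = 1e-12)
  }
  # wrap-around columns: b_i + b_{i-(n-1)}
  for (i in (n - k):(n - 1L)) {
    expect_equal(D[, i], plain_ref(i) + plain_ref(i - nint), tolerance = 1e-12)
  }
})

test_that("a circle is fit within 0.5 percent radial error", {
  ls <- seq(0, 1, length.out = 201)[-201]
  circ <- cbind(50 * cos(2 * pi * ls), 50 * sin(2 * pi * ls), 0)
  model <- fit_closed_bspline(ls, circ, n = 16L, k = 3L)
  dense <- evaluate_bspline(model, seq(0, 1, length.out = 2000))
  radial <- abs(sqrt(rowSums(dense[, 1:2]^2)) - 50)
  expect_lt(max(radial), 0.25) # 0.5 percent of r = 50 mm
})

test_that("coefficients of a known model are recovered exactly", {
  set.seed(21)
  n <- 16L; k <- 3L
  w <- matrix(rnorm(3 * (n - 1L)), n - 1L, 3L)
  truth <- structure(list(coeffs = w, n = n, k = k), class = "closed_bspline")
  ls <- runif(500)
  samples <- evaluate_bspline(truth, ls)
  fit <- fit_closed_bspline(ls, samples, n = n, k = k)
  expect_lt(max(abs(fit$coeffs - w)), 1e-8)
})

test_that("evaluation is periodic, matches the design product, and constants stay constant", {
  set.seed(4)
  model <- fit_closed_bspline(seq(0, 0.995, by = 0.005),
                              cbind(cos(2 * pi * seq(0, 0.995, by = 0.005)),
                                    sin(2 * pi * seq(0, 0.995, by = 0.005)),
                                    0), n = 16L)
  ls <- runif(50)
  expect_equal(evaluate_bspline(model, ls), evaluate_bspline(model, ls + 1),
               tolerance = 1e-12)
  expect_equal(evaluate_bspline(model, ls),
               closed_bspline_design(ls, model$n, model$k) %*% model$coeffs,
               tolerance = 1e-14)
  const <- structure(list(coeffs = matrix(7, 15, 3), n = 16L, k = 3L),
                     class = "closed_bspline")
  expect_equal(unname(evaluate_bspline(const, ls)),
               matrix(7, 50, 3), tolerance = 1e-12)
})

test_that("fitted closed curves are C^{k-1} across the seam", {
  ls <- seq(0, 0.9975, by = 0.0025)
  pts <- cbind(40 * cos(2 * pi * ls) + 5 * cos(6 * pi * ls),
               40 * sin(2 * pi * ls), 3 * sin(4 * pi * ls))
  model <- fit_closed_bspline(ls, pts, n = 16L, k = 3L)
  # central differences at the seam: truncation error is identical at l = 0
  # and l = 1, so their difference isolates any discontinuity
  h <- 1e-3
  for (d in 1:2) { # first k-1 = 2 finite-difference derivatives
    fd <- function(l) {
      if (d == 1) (evaluate_bspline(model, l + h) - evaluate_bspline(model, l - h)) / (2 * h)
      else (evaluate_bspline(model, l + h) - 2 * evaluate_bspline(model, l) +
              evaluate_bspline(model, l - h)) / h^2
    }
    expect_lt(max(abs(fd(0) - fd(1))), 1e-4)
  }
})

test_that("refining the interval count never worsens the residual", {
  ls <- seq(0, 0.998, by = 0.002)
  pts <- cbind(30 * cos(2 * pi * ls) * (1 + 0.2 * cos(10 * pi * ls)),
               30 * sin(2 * pi * ls), 0)
  r16 <- fit_closed_bspline(ls, pts, n = 16L)$rms
  r64 <- fit_closed_bspline(ls, pts, n = 64L)$rms
  expect_lte(r64, r16 + 1e-12)
})

test_that("sparse angular coverage raises an ill-conditioned fit error", {
  ls <- seq(0, 0.35, length.out = 120) # only a third of the period
  pts <- cbind(cos(2 * pi * ls), sin(2 * pi * ls), 0)
  expect_error(fit_closed_bspline(ls, pts, n = 16L), "gap")
})

test_that("loop parameterization recovers circular order and rejects degeneracy", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  circ <- cbind(20 * cos(th), 20 * sin(th), 0)
  par <- parameterize_loop(circ)
  # l proportional to the circle angle: constant gaps
  gaps <- diff(par$l)
  expect_lt(max(abs(gaps - gaps[1])), 1e-6)
  # mild 3D warp keeps the order a cyclic rotation of the true sequence
  # (possibly reversed, depending on the recovered plane orientation)
  warp <- cbind(20 * cos(th), 20 * sin(th), 4 * sin(2 * th))
  ord <- parameterize_loop(warp)$order
  nw <- length(ord)
  steps <- (diff(c(ord, ord[1])) + nw) %% nw
  expect_true(all(steps == 1) || all(steps == nw - 1))
  line <- cbind(1:30, 2 * (1:30), 3 * (1:30))
  expect_error(parameterize_loop(line), "collinear")
})
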