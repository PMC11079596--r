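test_that("projection follows the pinhole model and rejects invalid points", {
  cam <- camera(cbind(diag(3), c(0, 0, 0)), view_id = 1L)
  expect_equal(as.numeric(project_points(cam, c(0, 0, 1))), c(0, 0))
  expect_equal(as.numeric(project_points(cam, c(2, 3, 2))), c(1, 1.5))
  expect_error(project_points(cam, c(0, 0, -1)), "behind")
  expect_error(project_points(cam, c(0, 0, 0)), "behind|center")
})

test_that("camera centre is the null space of P and rank checks hold", {
  set.seed(1)
  cam <- random_camera()
  expect_equal(as.numeric(cam$P %*% c(cam$center, 1)), rep(0, 3),
               tolerance = 1e-8)
  expect_error(camera(matrix(0, 3, 4)), "rank")
})

test_that("epipolar constraint and triangulation round-trip hold on random geometry", {
  set.seed(42)
  for (trial in 1:100) {
    cam1 <- random_camera(1L)
    cam2 <- random_camera(2L)
    X <- cbind(runif(10, -60, 60), runif(10, -60, 60), runif(10, -60, 60))
    x1 <- project_points(cam1, X)
    x2 <- project_points(cam2, X)
    F <- fundamental_matrix(cam1, cam2)
    L <- epipolar_lines(F, x1)
    resid <- abs(rowSums(L * cbind(x2, 1)))
    expect_lt(max(resid), 1e-9)
    Xh <- triangulate_points(cam1, cam2, x1, x2)
    expect_lt(max(abs(Xh - X)), 1e-6)
  }
})

test_that("fundamental matrix is rank 2 with unit norm, degenerate pairs error", {
  set.seed(7)
  cam1 <- random_camera(1L)
  cam2 <- random_camera(2L)
  F <- fundamental_matrix(cam1, cam2)
  sv <- svd(F)$d
  expect_lt(sv[3], 1e-12 * sv[1])
  expect_equal(sqrt(sum(F^2)), 1, tolerance = 1e-12)
  expect_error(fundamental_matrix(cam1, cam1), "degenerate")
})

test_that("pure translation along the camera x-axis gives parallel epipolar lines", {
  R <- look_at_rotation(c(400, 0, 0), c(0, 0, 0))
  c1 <- c(400, 0, 0)
  c2 <- c1 + 30 * R[1, ] # shift along the camera's own x-axis
  cam1 <- pinhole_camera(900, c(320, 240), R, c1, 1L)
  cam2 <- pinhole_camera(900, c(320, 240), R, c2, 2L)
  F <- fundamental_matrix(cam1, cam2)
  X <- cbind(runif(20, -50, 50), runif(20, -50, 50), runif(20, -50, 50))
  L <- epipolar_lines(F, project_points(cam1, X))
  # all normalised line normals (a, b) agree up to sign
  dirs <- L[, 1:2] * sign(L[, 1] + 1e-12)
  expect_lt(max(apply(dirs, 2, function(v) diff(range(v)))), 1e-8)
})

test_that("triangulation is the algebraic least-squares solution under perturbation", {
  set.seed(3)
  cam1 <- random_camera(1L)
  cam2 <- random_camera(2L)
  X <- cbind(runif(50, -50, 50), runif(50, -50, 50), runif(50, -50, 50))
  x1 <- project_points(cam1, X)
  x2 <- project_points(cam2, X) + 0.5 # half-pixel perturbation in view 2
  Xh <- triangulate_points(cam1, cam2, x1, x2)
  # DLT minimises |A y| over unit y: no candidate point (including the true
  # one) may achieve a smaller balanced algebraic residual
  alg_resid <- function(k, Y) {
    A <- rbind(x1[k, 1] * cam1$P[3, ] - cam1$P[1, ],
               x1[k, 2] * cam1$P[3, ] - cam1$P[2, ],
               x2[k, 1] * cam2$P[3, ] - cam2$P[1, ],
               x2[k, 2] * cam2$P[3, ] - cam2$P[2, ])
    A <- A / sqrt(rowSums(A^2))
    y <- c(Y, 1)
    sqrt(sum((A %*% y)^2)) / sqrt(sum(y^2))
  }
  for (k in sample(50, 10)) {
    expect_lte(alg_resid(k, Xh[k, ]), alg_resid(k, X[k, ]) + 1e-12)
    expect_lte(alg_resid(k, Xh[k, ]),
               alg_resid(k, Xh[k, ] + runif(3, -1, 1)) + 1e-12)
  }
  # and the geometric reprojection error stays at the perturbation scale
  r2 <- sqrt(rowSums((project_points(cam2, Xh) - x2)^2))
  expect_lt(median(r2), 1)
  expect_error(triangulate_points(cam1, cam1, x1, x2), "degenerate")
})

test_that("pair angles match the rig geometry and the direct formula", {
  cams <- lapply(1:32, function(i) {
    th <- (i - 1) * 2 * pi / 32
    c0 <- c(400 * cos(th), 400 * sin(th), 50)
    pinhole_camera(900, c(320, 240), look_at_rotation(c0, c(0, 0, 50)), c0, i)
  })
  rig <- camera_rig(cams)
  expect_equal(pair_angle(rig, 1, 2), 11.25, tolerance = 1e-9)
  expect_equal(pair_angle(rig, 1, 17), 180, tolerance = 1e-9)
  expect_equal(pair_angle(rig, 5, 9), pair_angle(rig, 9, 5))
  expect_error(pair_angle(rig, 3, 3), "distinct")
  # independent arccos formula on an arbitrary configuration
  set.seed(9)
  rig2 <- camera_rig(lapply(1:5, random_camera))
  p <- rig2$mean_position
  a <- rig2$cameras[[2]]$center - p
  b <- rig2$cameras[[4]]$center - p
  expected <- acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
  expect_equal(pair_angle(rig2, 2, 4), expected, tolerance = 1e-9)
})

test_that("epipolar bands contain their member lines and reject far points", {
  set.seed(5)
  cam1 <- random_camera(1L)
  cam2 <- random_camera(2L)
  F <- fundamental_matrix(cam1, cam2)
  X <- cbind(seq(-20, 20, length.out = 15), 5 * sin(1:15), rep(10, 15))
  frag <- project_points(cam1, X)
  band <- epipolar_band(F, frag, dilation_px = 2)
  # points on every member epipolar line are inside the band: take the
  # projection of each source 3D point into view 2, which lies on its line
  x2 <- project_points(cam2, X)
  expect_true(all(point_in_band(band, x2)))
  # single-point fragment: band collapses to one line +- dilation
  band1 <- epipolar_band(F, frag[1, , drop = FALSE], dilation_px = 2)
  l <- band1$lines[1, ]
  on_line <- c(-l[3] * l[1], -l[3] * l[2])
  expect_true(point_in_band(band1, on_line + 1.5 * l[1:2]))
  expect_false(point_in_band(band1, on_line + 3.5 * l[1:2]))
  # a point far outside both boundary lines is rejected
  far <- x2[8, ] + 500 * band$boundary_lines[1, 1:2]
  expect_false(point_in_band(band, far))
})

test_that("projection and triangulation are consistent under world similarity", {
  set.seed(11)
  cam1 <- random_camera(1L); cam2 <- random_camera(2L)
  X <- cbind(runif(20, -50, 50), runif(20, -50, 50), runif(20, -50, 50))
  s <- 2.5
  Rw <- rot_z_test(33)
  tw <- c(10, -4, 7)
  M <- function(p) sweep(s * p %*% t(Rw), 2, tw, "+")
  # transformed cameras: P' = P * inverse similarity
  Minv <- rbind(cbind(t(Rw) / s, -t(Rw) %*% tw / s), c(0, 0, 0, 1))
  cam1t <- camera(cam1$P %*% Minv, 1L)
  cam2t <- camera(cam2$P %*% Minv, 2L)
  expect_equal(project_points(cam1t, M(X)), project_points(cam1, X),
               tolerance = 1e-8)
  Xh <- triangulate_points(cam1t, cam2t, project_points(cam1, X),
                           project_points(cam2, X))
  expect_equal(Xh, M(X), tolerance = 1e-6 * s)
})
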