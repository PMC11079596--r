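# two fixed cameras looking at the origin from 15 degrees apart, used by the
# hypothesis and reconstruction tests
sketch_cams <- function() {
  mk <- function(th, id) {
    c0 <- c(400 * cos(th), 400 * sin(th), 60)
    pinhole_camera(900, c(319.5, 239.5), look_at_rotation(c0, c(0, 0, 0)), c0,
                   id, c(640, 480))
  }
  list(cam_i = mk(0, 1L), cam_j = mk(15 * pi / 180, 2L))
}

test_that("camera pairs are the combinations within the pairing angle", {
  rigs <- make_camera_rig(32L, target = c(0, 0, 100), extent = 200)
  rig <- rigs$clean
  pairs <- define_camera_pairs(rig, 30)
  # ring spacing 11.25 deg: each camera pairs with 2 neighbours per side
  expect_equal(nrow(pairs), 32 * 4 / 2)
  angs <- vapply(seq_len(nrow(pairs)), function(r) {
    pair_angle(rig, pairs[r, 1], pairs[r, 2])
  }, numeric(1))
  expect_true(all(angs <= 30))
  expect_setequal(round(unique(angs), 6), c(11.25, 22.5))
  expect_equal(nrow(define_camera_pairs(rig, 180)), choose(32, 2))
  expect_equal(nrow(define_camera_pairs(rig, 10)), 0)
  expect_equal(default_b_max(32), 30)
  expect_equal(default_b_max(64), 40)
  expect_equal(default_b_max(128), 60)
})

test_that("pair hypotheses find the true counterpart and cap the candidate count", {
  cams <- sketch_cams()
  th <- seq(0.3, 1.8, length.out = 60)
  X <- cbind(45 * cos(th), 45 * sin(th), 10 * sin(2 * th)) # 3D arc
  f_i <- curve_fragment_2d(project_points(cams$cam_i, X), 1L)
  true_j <- curve_fragment_2d(project_points(cams$cam_j, X), 2L)
  # decoy: counterpart shifted until it is wholly outside the epipolar band
  F <- fundamental_matrix(cams$cam_i, cams$cam_j)
  band <- epipolar_band(F, f_i$points)
  shift <- 200
  repeat {
    decoy_pts <- sweep(true_j$points, 2, c(0, shift), "+")
    if (!any(point_in_band(band, decoy_pts))) break
    shift <- shift + 200
  }
  decoy <- curve_fragment_2d(decoy_pts, 2L)
  hyps <- generate_pair_hypotheses(f_i, list(decoy, true_j), F,
                                   support_params())
  expect_length(hyps, 1L) # decoy excluded: wholly outside the band
  expect_gte(hyps[[1]]$frac, 0.5) # enough correspondences to reconstruct
  # the matched correspondences triangulate back to the arc
  g <- reconstruct_fragment(hyps[[1]], cams$cam_i, cams$cam_j)
  expect_lt(sqrt(mean(nn_dist(g$points, X)^2)), 1e-3)

  # 15 near-identical candidates inside the band: exactly 10 retained
  cands <- lapply(seq(-3.5, 3.5, length.out = 15), function(dv) {
    curve_fragment_2d(sweep(true_j$points, 2, c(0, dv), "+"), 2L)
  })
  hyps15 <- generate_pair_hypotheses(f_i, cands, F, support_params())
  expect_length(hyps15, 10L)
})

test_that("noise-free reconstruction is exact and drops uncorresponded points", {
  cams <- sketch_cams()
  th <- seq(0.2, 2.2, length.out = 80)
  X <- cbind(40 * cos(th), 40 * sin(th), 15 * sin(th))
  f_i <- curve_fragment_2d(project_points(cams$cam_i, X), 1L)
  # candidate covers only part of the curve: missing part absent from output
  part <- project_points(cams$cam_j, X[1:50, ])
  cand <- curve_fragment_2d(part, 2L)
  F <- fundamental_matrix(cams$cam_i, cams$cam_j)
  hyps <- generate_pair_hypotheses(f_i, list(cand), F, support_params())
  g <- reconstruct_fragment(hyps[[1]], cams$cam_i, cams$cam_j)
  expect_lt(nrow(g$points), 80) # truncated to the corresponded part
  expect_lt(sqrt(mean(nn_dist(g$points, X[1:50, ])^2)), 1e-3)
  # RMS against the truth on a fully covered arc
  full <- curve_fragment_2d(project_points(cams$cam_j, X), 2L)
  h2 <- generate_pair_hypotheses(f_i, list(full), F, support_params())
  g2 <- reconstruct_fragment(h2[[1]], cams$cam_i, cams$cam_j)
  expect_lt(sqrt(mean(nn_dist(g2$points, X)^2)), 1e-4)
})

test_that("double epipolar crossings are resolved by continuity on an S-curve", {
  cams <- sketch_cams()
  # S progressing transversally to the (roughly horizontal) epipolar pencil,
  # wiggling sideways: at the two bends an epipolar line crosses the
  # candidate twice, so the branch must be chosen by continuity
  s <- seq(-1, 1, length.out = 120)
  X <- cbind(12 * sin(pi * s), 8 * s, 35 * s + 6 * sin(2 * pi * s))
  f_i <- curve_fragment_2d(project_points(cams$cam_i, X), 1L)
  cand <- curve_fragment_2d(project_points(cams$cam_j, X), 2L)
  F <- fundamental_matrix(cams$cam_i, cams$cam_j)
  hyps <- generate_pair_hypotheses(f_i, list(cand), F, support_params())
  expect_gte(length(hyps), 1L)
  # the ambiguity is really exercised: several lines cross the curve twice
  e_i <- svd(F)$v[, 3]
  ta <- leafedge3d:::tangency_angles(f_i$points, e_i)
  L <- epipolar_lines(F, f_i$points)[ta >= 15, , drop = FALSE]
  multi <- sum(vapply(seq_len(nrow(L)), function(i) {
    d <- rowSums(cbind(cand$points, 1) *
                   matrix(L[i, ], nrow(cand$points), 3, byrow = TRUE))
    sum(d[-length(d)] * d[-1] < 0) > 1
  }, logical(1)))
  expect_gt(multi, 5)
  g <- reconstruct_fragment(hyps[[1]], cams$cam_i, cams$cam_j)
  # continuity picks the right branch: reconstruction follows the true curve
  expect_lt(max(nn_dist(g$points, X)), 0.1)
  # and the output preserves the source ordering: the nearest-true-vertex
  # sequence advances monotonically
  idx <- apply(g$points, 1, function(q) which.min(colSums((t(X) - q)^2)))
  expect_true(all(diff(idx) >= 0))
})

test_that("support filtering keeps true edges, removes ghosts, and shrinks with tau_t", {
  rb <- fx_single_recon(0)
  sk <- rb$leaves[[1]]$sketch
  sc <- fx_single_scene(0)
  truth <- resample_polyline(sc$true_edges[[1]][[1]], 0.5)

  kept_sets <- lapply(tau_t_grid(), function(r) {
    support_filter(sk$fragments, sk$m, r)
  })
  sizes <- lengths(kept_sets)
  expect_true(all(diff(sizes) <= 0)) # monotone shrinkage
  # subset property at the fragment level: the surviving index set at a
  # higher threshold is contained in the one at any lower threshold
  nsup <- vapply(sk$fragments, function(f) length(f$support_views), integer(1))
  survivors <- lapply(tau_t_grid(), function(r) which(nsup >= ceiling(r * sk$m)))
  for (i in seq_len(length(survivors) - 1L)) {
    expect_true(all(survivors[[i + 1]] %in% survivors[[i]]))
  }
  # tau_t = 1 can never be satisfied when support views exclude the source
  # pair (at most m - 2 supporters)
  expect_length(support_filter(sk$fragments, sk$m, 1), 0L)

  # accuracy: kept fragments hug the truth, the unfiltered pool has ghosts
  kept_pts <- do.call(rbind, lapply(sk$kept, `[[`, "points"))
  all_pts <- do.call(rbind, lapply(sk$fragments, `[[`, "points"))
  expect_lt(stats::quantile(nn_dist(kept_pts, truth), 0.95), 2)
  expect_gt(max(nn_dist(all_pts, truth)), 10) # ghosts exist pre-filter
})

test_that("kept fragment points are accurate at the swept optimal threshold", {
  rb <- fx_single_recon(0)
  sk <- rb$leaves[[1]]$sketch
  sc <- fx_single_scene(0)
  truth <- resample_polyline(sc$true_edges[[1]][[1]], 0.1)
  pr <- sweep_support_threshold(sk, sc$true_edges[[1]][[1]])
  opt <- optimal_support_threshold(pr)
  kept <- support_filter(sk$fragments, sk$m, opt$tau_t)
  pts <- do.call(rbind, lapply(kept, `[[`, "points"))
  expect_gte(mean(nn_dist(pts, truth) <= 1), 0.95)
})

test_that("camera noise increases the fragment-to-truth distance", {
  d_of <- function(sigma) {
    rb <- fx_single_recon(sigma)
    sc <- fx_single_scene(sigma)
    truth <- resample_polyline(sc$true_edges[[1]][[1]], 0.5)
    pts <- do.call(rbind, lapply(rb$leaves[[1]]$sketch$kept, `[[`, "points"))
    mean(nn_dist(pts, truth))
  }
  expect_gt(d_of(3), d_of(0))
})

test_that("loop grouping separates outer edge and holes and orders by extent", {
  rb <- fx_holes_recon(3)
  sk <- rb$leaves[[1]]$sketch
  pts <- do.call(rbind, lapply(sk$kept, `[[`, "points"))
  # permutation invariance of the grouping
  g1 <- group_fragments_into_loops(pts, eps = 3)
  set.seed(99)
  g2 <- group_fragments_into_loops(pts[sample(nrow(pts)), ], eps = 3)
  expect_length(g2, length(g1))
  expect_equal(sort(vapply(g1, nrow, integer(1))),
               sort(vapply(g2, nrow, integer(1))))
  # hole-free leaf: a single group
  rb0 <- fx_single_recon(0)
  pts0 <- do.call(rbind, lapply(rb0$leaves[[1]]$sketch$kept, `[[`, "points"))
  g0 <- group_fragments_into_loops(pts0, eps = 6)
  expect_length(g0, 1L)
})
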