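# Shared fixtures, built lazily and cached for the whole test run. The heavy
# end-to-end scenes are reconstructed once and reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# local rotation helpers (kept in the tests to stay independent of package
# internals)
rot_z_test <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
}
rot_y_test <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
}

# a generic random pinhole camera on a sphere around the origin, aimed inward
random_camera <- function(view_id = 1L, radius = 400) {
  u <- stats::rnorm(3)
  c0 <- radius * u / sqrt(sum(u^2))
  pinhole_camera(900, c(320, 240), look_at_rotation(c0, c(0, 0, 0)), c0,
                 view_id = view_id, image_size = c(640, 480))
}

# single-leaf study benchmark: 32 views, 640x480, true masks
fx_single_scene <- function(sigma = 0) {
  fixture(paste0("single_scene_", sigma), function() {
    make_scene(scene_spec(list(leaf_spec(1500)), n_views = 32L,
                          camera_noise_sigma = sigma, rng_seed = 3L))
  })
}

fx_single_recon <- function(sigma = 0) {
  fixture(paste0("single_recon_", sigma), function() {
    reconstruct_scene(fx_single_scene(sigma))
  })
}

# 8-leaf study plant (no pillars)
fx_plant_scene <- function() {
  fixture("plant_scene", function() {
    make_scene(scene_spec(study_leaf_specs(), n_views = 32L, rng_seed = 7L))
  })
}

fx_plant_identity <- function() {
  fixture("plant_identity", function() {
    sc <- fx_plant_scene()
    identify_leaves(sc$cloud$points, sc$rig, sc$masks,
                    eps = suggest_dbscan_eps(sc))
  })
}

# full 8-leaf reconstruction (used for the SFD-vs-area trend)
fx_plant_recon <- function() {
  fixture("plant_recon", function() {
    reconstruct_scene(fx_plant_scene())
  })
}

# map DBSCAN cluster labels to true leaf labels via the scene's cloud labels
cluster_truth_map <- function(scene, cluster_labels) {
  ks <- sort(unique(cluster_labels[cluster_labels > 0]))
  vapply(ks, function(k) {
    tt <- table(scene$cloud$labels[cluster_labels == k])
    as.integer(names(tt)[which.max(tt)])
  }, integer(1))
}

# instance assignment error count against ground truth (synthetic masks carry
# the true leaf label as the instance label)
assignment_errors <- function(scene, idres) {
  map <- cluster_truth_map(scene, idres$cluster_labels)
  errs <- 0L; assigned <- 0L; correct <- 0L
  for (v in seq_along(idres$identity$assignment)) {
    a <- idres$identity$assignment[[v]]
    for (nm in names(a)) {
      if (is.na(a[[nm]])) {
        errs <- errs + 1L
      } else {
        assigned <- assigned + 1L
        if (map[[a[[nm]]]] == as.integer(nm)) correct <- correct + 1L
        else errs <- errs + 1L
      }
    }
  }
  list(errors = errs, assigned = assigned, correct = correct)
}

# two-layer scene: two parallel vertical leaves 18 mm apart (front/back for
# half of the ring cameras); the canonical back-side leakage fixture
fx_two_layer <- function() {
  fixture("two_layer", function() {
    mk <- function(dx, id) {
      m <- make_leaf_mesh(leaf_spec(1200))
      m <- transform_mesh(m, rot_y_test(90), c(dx, 0, 120))
      m$leaf_id <- id
      m
    }
    meshes <- list(mk(9, 1L), mk(-9, 2L))
    rig <- make_camera_rig(32L, target = c(0, 0, 120), extent = 110)$clean
    masks <- lapply(rig$cameras, function(cam) {
      render_instance_masks(meshes, cam, c(640L, 480L))
    })
    cloud <- sample_point_cloud(meshes, 200L, rng_seed = 5L)
    list(meshes = meshes, rig = rig, masks = masks, cloud = cloud)
  })
}

# hole benchmarks
fx_holes_scene <- function(n_holes) {
  fixture(paste0("holes_scene_", n_holes), function() {
    make_scene(scene_spec(list(leaf_spec(1500, n_holes = n_holes)),
                          n_views = 32L, rng_seed = 11L))
  })
}

fx_holes_recon <- function(n_holes) {
  fixture(paste0("holes_recon_", n_holes), function() {
    reconstruct_scene(fx_holes_scene(n_holes))
  })
}

# brute-force discrete Frechet by recursive coupling enumeration (oracle)
frechet_bruteforce <- function(A, B) {
  na <- nrow(A); nb <- nrow(B)
  d <- function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))
  memo <- array(NA_real_, c(na, nb))
  rec <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- if (i == 1 && j == 1) {
      d(1, 1)
    } else if (i == 1) {
      max(rec(1, j - 1), d(1, j))
    } else if (j == 1) {
      max(rec(i - 1, 1), d(i, 1))
    } else {
      max(min(rec(i - 1, j), rec(i - 1, j - 1), rec(i, j - 1)), d(i, j))
    }
    memo[i, j] <<- v
    v
  }
  rec(na, nb)
}

# shortest distance from each point of Q to the polyline sample set S
nn_dist <- function(Q, S) {
  apply(Q, 1, function(q) sqrt(min(colSums((t(S) - q)^2))))
}

# arc-length position of a point on a closed contour (nearest-segment
# projection); ctr closed (first row repeated last)
arc_position <- function(x, ctr) {
  P <- ctr[-nrow(ctr), , drop = FALSE]
  Q <- ctr[-1, , drop = FALSE]
  seg <- sqrt(rowSums((Q - P)^2))
  cum <- c(0, cumsum(seg))
  d <- sweep(P, 2, x)
  e <- Q - P
  t <- pmin(1, pmax(0, -rowSums(d * e) / pmax(rowSums(e * e), 1e-300)))
  proj <- P + e * t
  dd <- rowSums(sweep(proj, 2, x)^2)
  j <- which.min(dd)
  cum[j] + t[j] * seg[j]
}
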