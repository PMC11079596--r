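#' Synthetic multiview leaf scenes
#'
#' Generates everything the reconstruction pipeline consumes, with exact
#' ground truth: virtual leaves (planar analytic outlines, triangulated),
#' a plant assembled with seeded placement jitter, a cylindrical camera rig
#' (noise-free and position-noised variants), occluder pillars, per-view
#' instance label masks (analytic z-buffered rasterisation), closed true 3D
#' edge polylines, and an area-uniform labeled point cloud standing in for a
#' sparse SfM cloud.
#'
#' @name synthetic-scene
#' @keywords internal
NULL

#' Specification of one virtual leaf
#'
#' @param area planform area, mm^2 (the study leaves span 312 to 3366 mm^2).
#' @param shape one of "plain", "lobed", "serrated", "elongated".
#' @param aspect_ratio width/length bounding-box ratio (used by "elongated";
#'   e.g. 0.16 or 0.04).
#' @param n_holes number of interior holes (circular, placed along the
#'   midline).
#' @param serration_depth tooth depth for "serrated", mm.
#' @param lobe_count number of lobes for "lobed".
#' @return object of class `leaf_spec`.
#' @export
leaf_spec <- function(area, shape = c("plain", "lobed", "serrated", "elongated"),
                      aspect_ratio = NULL, n_holes = 0L,
                      serration_depth = 2, lobe_count = 5L) {
  shape <- match.arg(shape)
  stopifnot(area > 0, n_holes >= 0)
  if (is.null(aspect_ratio)) {
    aspect_ratio <- if (shape == "elongated") 0.16 else 0.66
  }
  structure(list(area = area, shape = shape, aspect_ratio = aspect_ratio,
                 n_holes = as.integer(n_holes),
                 serration_depth = serration_depth,
                 lobe_count = as.integer(lobe_count)),
            class = "leaf_spec")
}

#' Specification of a synthetic scene
#'
#' @param leaves list of [leaf_spec()].
#' @param n_views number of cameras on the cylindrical rig (32, 64 or 128 in
#'   the study conditions).
#' @param camera_noise_sigma per-axis SD of Gaussian camera-centre noise, mm
#'   (0, 1 or 3 in the study conditions).
#' @param occluder "none", "thin" (5 mm pillars) or "thick" (20 mm pillars).
#' @param image_size c(width, height) px, default 640x480.
#' @param rng_seed integer seed driving all randomness of the scene.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(leaves, n_views = 32L, camera_noise_sigma = 0,
                       occluder = c("none", "thin", "thick"),
                       image_size = c(640L, 480L), rng_seed = 1L) {
  occluder <- match.arg(occluder)
  if (inherits(leaves, "leaf_spec")) leaves <- list(leaves)
  stopifnot(length(leaves) >= 1L, n_views >= 2L, camera_noise_sigma >= 0)
  structure(list(leaves = leaves, n_views = as.integer(n_views),
                 camera_noise_sigma = camera_noise_sigma,
                 occluder = occluder, image_size = as.integer(image_size),
                 rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

#' Standard 8-leaf study plant
#'
#' Eight plain leaves with areas log-spaced over the study range
#' 312 to 3366 mm^2.
#'
#' @return list of [leaf_spec()].
#' @export
study_leaf_specs <- function() {
  areas <- round(exp(seq(log(312), log(3366), length.out = 8)))
  lapply(areas, leaf_spec)
}

# analytic 2D outline of a leaf in its local plane (x along length, origin at
# outline centroid), area normalised to spec$area; holes as circular loops
leaf_outline <- function(spec, n_points = 256L) {
  th <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  # ovate base: mildly egg-shaped radial curve (star-shaped about origin)
  r <- 1 + 0.18 * cos(th) - 0.08 * cos(2 * th)
  if (spec$shape == "lobed") {
    r <- r * (1 + 0.30 * cos(spec$lobe_count * th))
  }
  # aspect ratio is enforced on the bounding box below
  pts <- cbind(r * cos(th), r * sin(th))
  bb <- apply(pts, 2, function(cc) diff(range(cc)))
  pts[, 2] <- pts[, 2] * (spec$aspect_ratio * bb[1] / bb[2])
  # scale to requested area
  a0 <- abs(shoelace_area(pts))
  s <- sqrt(spec$area / a0)
  pts <- pts * s
  if (spec$shape == "serrated") {
    # cosine teeth along the boundary, superposed radially
    nt <- 24L
    rr <- sqrt(rowSums(pts^2))
    dir <- pts / rr
    pts <- pts + dir * (spec$serration_depth / 2) * cos(nt * th)
    pts <- pts * sqrt(spec$area / abs(shoelace_area(pts)))
  }
  pts <- sweep(pts, 2, polygon_centroid(pts))
  outer <- pts

  holes <- list()
  if (spec$n_holes > 0L) {
    len <- diff(range(outer[, 1]))
    xs <- seq(-0.28, 0.28, length.out = spec$n_holes) * len
    ys <- rep_len(c(0.10, -0.10), spec$n_holes) * len * spec$aspect_ratio
    if (spec$n_holes == 1L) { xs <- 0; ys <- 0 }
    # hole radius: nominal 8.5 percent of the leaf length, shrunk when holes
    # are packed so tightly that they would otherwise touch
    hr <- 0.085 * len
    if (spec$n_holes > 1L) hr <- min(hr, 0.35 * min(dist(cbind(xs, ys))))
    tt <- seq(0, 2 * pi, length.out = 33L)[-33L]
    for (i in seq_len(spec$n_holes)) {
      h <- cbind(xs[i] + hr * cos(tt), ys[i] + hr * sin(tt))
      holes[[i]] <- h[nrow(h):1, , drop = FALSE] # clockwise
    }
    # validity: hole fully inside the outer ring and pairwise disjoint
    for (i in seq_along(holes)) {
      inside <- apply(holes[[i]], 1, point_in_polygon, poly = outer)
      if (!all(inside)) stop("invalid leaf spec: a hole intersects the outer boundary")
    }
    if (spec$n_holes > 1L) {
      ctrs <- cbind(xs, ys)
      dmin <- min(dist(ctrs))
      if (dmin <= 2 * hr) stop("invalid leaf spec: holes overlap")
    }
  }
  # total area correction for holes (planform area = outer - holes)
  if (length(holes) > 0L) {
    hole_a <- sum(vapply(holes, function(h) abs(shoelace_area(h)), numeric(1)))
    s2 <- sqrt(spec$area / (abs(shoelace_area(outer)) - hole_a))
    outer <- outer * s2
    holes <- lapply(holes, function(h) h * s2)
  }
  list(outer = outer, holes = holes)
}

polygon_centroid <- function(pts) {
  p <- as.matrix(pts)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Build a triangulated leaf mesh with exact boundary loops
#'
#' The leaf is a planar analytic outline (ovate base curve; cosine lobes or
#' serration; circular holes) triangulated by ear clipping. Returned in local
#' coordinates (z = 0, x along the leaf length, origin at the centroid).
#'
#' @param spec a [leaf_spec()].
#' @param n_points outline sampling density (default 256 vertices; serrated
#'   shapes use at least 512).
#' @return object of class `leaf_mesh`: `vertices` (Vx3 mm), `faces` (Fx3),
#'   `loops` (list of closed 3D polylines: outer first, then holes),
#'   `area` (planform mm^2), `spec`.
#' @export
make_leaf_mesh <- function(spec, n_points = 256L) {
  if (spec$shape == "serrated") n_points <- max(n_points, 512L)
  ol <- leaf_outline(spec, n_points)
  tri <- triangulate_polygon(ol$outer, ol$holes)
  close3 <- function(p2) {
    p <- cbind(p2, 0)
    rbind(p, p[1, , drop = FALSE])
  }
  loops <- c(list(close3(ol$outer)), lapply(ol$holes, close3))
  area <- abs(shoelace_area(ol$outer)) -
    sum(vapply(ol$holes, function(h) abs(shoelace_area(h)), numeric(1)))
  structure(
    list(vertices = cbind(tri$vertices, 0), faces = tri$faces,
         loops = loops, area = area, spec = spec),
    class = "leaf_mesh"
  )
}

#' @export
print.leaf_mesh <- function(x, ...) {
  cat(sprintf("<leaf_mesh %s: area %.0f mm^2, %d vertices, %d faces, %d loop(s)>\n",
              x$spec$shape, x$area, nrow(x$vertices), nrow(x$faces),
              length(x$loops)))
  invisible(x)
}

#' Apply a rigid transform to a leaf mesh
#'
#' @param mesh a `leaf_mesh`.
#' @param R 3x3 rotation matrix.
#' @param t 3-vector translation, mm.
#' @return the transformed mesh (vertices and boundary loops moved together).
#' @export
transform_mesh <- function(mesh, R, t) {
  tf <- function(p) sweep(p %*% t(R), 2, t, "+")
  mesh$vertices <- tf(mesh$vertices)
  mesh$loops <- lapply(mesh$loops, tf)
  mesh
}

#' Assemble a plant from leaf specifications
#'
#' Leaves are attached around a vertical stem with a golden-angle azimuth
#' sequence, a gentle downward tilt, and increasing height. Each leaf then
#' receives seeded placement jitter: a horizontal offset uniform in plus or
#' minus 33.33 percent of its bounding-box length, a vertical offset uniform
#' in -14.28 to 14.29 percent of its bounding-box width, and a rotation about
#' the vertical axis uniform in plus or minus 10 degrees.
#'
#' @param leaf_specs list of [leaf_spec()].
#' @param rng_seed integer seed; identical seeds give identical plants.
#' @return list of posed `leaf_mesh` objects (world mm).
#' @export
make_plant <- function(leaf_specs, rng_seed = 1L) {
  stopifnot(length(leaf_specs) >= 1L)
  with_seed(rng_seed, {
    n <- length(leaf_specs)
    meshes <- vector("list", n)
    for (i in seq_len(n)) {
      mesh <- make_leaf_mesh(leaf_specs[[i]])
      bb <- apply(mesh$vertices[, 1:2, drop = FALSE], 2,
                  function(cc) diff(range(cc)))
      len <- diff(range(mesh$vertices[, 1]))
      azim <- (i - 1) * 137.507764
      tilt <- 28 # degrees below horizontal, petiole-to-tip
      height <- 35 + (i - 1) * 26
      radial <- 0.62 * len
      # deterministic pose: tilt about y, swing to azimuth, move outward + up
      R0 <- rot_z(azim) %*% rot_y(tilt)
      t0 <- rot_z(azim) %*% c(radial, 0, 0) + c(0, 0, height)
      # seeded jitter (fractions of the leaf bounding box)
      jit <- sample_pose_jitter(bb)
      dx <- jit[["dx"]]; dz <- jit[["dz"]]; dth <- jit[["dth"]]
      R <- rot_z(dth) %*% R0
      t <- as.numeric(rot_z(dth) %*% (t0 + rot_z(azim) %*% c(dx, 0, 0))) +
        c(0, 0, dz)
      meshes[[i]] <- transform_mesh(mesh, R, t)
      meshes[[i]]$leaf_id <- i
    }
    meshes
  })
}

# one draw of the per-leaf placement jitter: horizontal offset uniform in
# +-33.33% of the bounding-box length, vertical offset uniform in
# [-14.28%, +14.29%] of the bounding-box width, rotation uniform in +-10 deg
sample_pose_jitter <- function(bb, seed = NULL) {
  draw <- function() c(dx = stats::runif(1, -1 / 3, 1 / 3) * bb[1],
                       dz = stats::runif(1, -0.1428, 0.1429) * bb[2],
                       dth = stats::runif(1, -10, 10))
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Cylindrical camera rig around a scene
#'
#' `n_views` pinhole cameras evenly spaced on a horizontal ring, all aimed at
#' the target point, with the focal length chosen so the stated scene extent
#' fills about 70 percent of the image height. The noised variant perturbs
#' each camera centre with isotropic Gaussian noise of SD `noise_sigma` mm and
#' re-aims at the target.
#'
#' @param n_views number of cameras.
#' @param target aim point, world mm (plant centroid).
#' @param extent approximate scene diameter to frame, mm.
#' @param image_size c(width, height) px.
#' @param ring_radius ring radius, mm (default 400).
#' @param noise_sigma camera-centre noise SD, mm.
#' @param rng_seed seed for the noise draws.
#' @return list with `clean` and `noisy` [camera_rig()] objects (`noisy`
#'   equals `clean` when `noise_sigma` is 0).
#' @export
make_camera_rig <- function(n_views, target = c(0, 0, 120), extent = 260,
                            image_size = c(640L, 480L), ring_radius = 400,
                            noise_sigma = 0, rng_seed = 1L) {
  stopifnot(n_views >= 2L)
  w <- image_size[1]; h <- image_size[2]
  focal <- 0.70 * h * ring_radius / extent
  pp <- c((w - 1) / 2, (h - 1) / 2)
  build <- function(centers) {
    cams <- lapply(seq_len(nrow(centers)), function(i) {
      c0 <- centers[i, ]
      pinhole <- pinhole_camera(focal, pp, look_at_rotation(c0, target), c0,
                                view_id = i, image_size = image_size)
      pinhole$K <- rbind(c(focal, 0, pp[1]), c(0, focal, pp[2]), c(0, 0, 1))
      pinhole$R <- look_at_rotation(c0, target)
      pinhole
    })
    camera_rig(cams)
  }
  th <- (seq_len(n_views) - 1) * 2 * pi / n_views
  centers <- cbind(ring_radius * cos(th), ring_radius * sin(th), target[3])
  clean <- build(centers)
  if (noise_sigma > 0) {
    noisy <- with_seed(rng_seed, {
      build(centers + matrix(stats::rnorm(3 * n_views, 0, noise_sigma),
                             n_views, 3))
    })
  } else {
    noisy <- clean
  }
  list(clean = clean, noisy = noisy)
}

# occluder pillars: vertical cylinders between the camera ring and the plant
make_pillars <- function(kind, z_top = 260) {
  if (kind == "none") return(list())
  r <- if (kind == "thin") 5 else 20
  n <- 6L
  th <- (seq_len(n) - 1) * 2 * pi / n + pi / n
  lapply(seq_len(n), function(i) {
    list(center = c(190 * cos(th[i]), 190 * sin(th[i])),
         radius = r, z0 = 0, z1 = z_top)
  })
}

# camera ray directions for pixel coordinates (world frame, unnormalised);
# requires cam$K and cam$R (pinhole cameras built here carry both)
camera_rays <- function(cam, uv) {
  if (is.null(cam$K) || is.null(cam$R)) {
    kr <- decompose_projection(cam$P)
    cam$K <- kr$K; cam$R <- kr$R
  }
  g_cam <- cbind((uv[, 1] - cam$K[1, 3]) / cam$K[1, 1],
                 (uv[, 2] - cam$K[2, 3]) / cam$K[2, 2], 1)
  g_cam %*% cam$R # = t(R) applied row-wise
}

#' Decompose a projection matrix into intrinsics and rotation
#'
#' RQ decomposition of the left 3x3 block with positive focal lengths and a
#' proper rotation.
#'
#' @param P 3x4 projection matrix.
#' @return list with `K` (upper triangular, K[3,3] = 1), `R` (rotation),
#'   `center`.
#' @export
decompose_projection <- function(P) {
  M <- P[, 1:3]
  # RQ via QR of the reversed transpose
  Erev <- diag(3)[3:1, ]
  qrd <- qr(t(Erev %*% M))
  Q <- qr.Q(qrd); Rq <- qr.R(qrd)
  K <- Erev %*% t(Rq) %*% Erev
  R <- Erev %*% t(Q)
  # make diagonal of K positive
  s <- sign(diag(K)); s[s == 0] <- 1
  S <- diag(s)
  K <- K %*% S
  R <- S %*% R
  if (det(R) < 0) { K <- -K; R <- -R }
  K <- K / K[3, 3]
  cam <- camera(P)
  list(K = K, R = R, center = cam$center)
}

#' Render per-view instance label masks
#'
#' Analytic z-buffered rasterisation: each (planar) leaf is filled by even-odd
#' scanline coverage of its projected boundary loops with per-pixel ray-plane
#' depth; occluder pillars are rasterised as label 0 by ray-cylinder
#' intersection. Nearer surface wins per pixel. Deterministic.
#'
#' @param meshes list of posed `leaf_mesh` objects (labels are their list
#'   positions).
#' @param cam a pinhole [camera()] (with intrinsics available).
#' @param image_size c(width, height) px.
#' @param pillars optional list of pillar definitions (see [make_scene()]).
#' @return integer label matrix `mask[v + 1, u + 1]` (0 background).
#' @export
render_instance_masks <- function(meshes, cam, image_size, pillars = list()) {
  w <- as.integer(image_size[1]); h <- as.integer(image_size[2])
  lab <- matrix(0L, h, w)
  zbuf <- matrix(Inf, h, w)
  C <- cam$center
  for (k in seq_along(meshes)) {
    mesh <- meshes[[k]]
    v3 <- mesh$vertices
    # supporting plane
    nrm <- pracma_cross(v3[2, ] - v3[1, ], v3[3, ] - v3[1, ])
    nn <- sqrt(sum(nrm^2))
    if (nn == 0) next
    nrm <- nrm / nn
    d <- sum(nrm * v3[1, ])
    denom0 <- d - sum(nrm * C)
    loops2 <- lapply(mesh$loops, function(L) {
      project_points(cam, L[-nrow(L), , drop = FALSE], allow_behind = TRUE)
    })
    if (any(!is.finite(unlist(loops2)))) next
    allp <- do.call(rbind, loops2)
    v0 <- max(0L, floor(min(allp[, 2]))); v1 <- min(h - 1L, ceiling(max(allp[, 2])))
    if (v1 < v0) next
    # scanline even-odd fill across all loops
    E <- do.call(rbind, lapply(loops2, function(p) {
      q <- p[c(2:nrow(p), 1), , drop = FALSE]
      cbind(p, q)
    }))
    for (v in v0:v1) {
      crossing <- (E[, 2] > v) != (E[, 4] > v)
      if (!any(crossing)) next
      ec <- E[crossing, , drop = FALSE]
      xc <- sort(ec[, 1] + (v - ec[, 2]) * (ec[, 3] - ec[, 1]) /
                   (ec[, 4] - ec[, 2]))
      np <- length(xc) %/% 2L
      for (s in seq_len(np)) {
        ua <- ceiling(xc[2 * s - 1]); ub <- floor(xc[2 * s])
        ua <- max(ua, 0L); ub <- min(ub, w - 1L)
        if (ub < ua) next
        us <- ua:ub
        g <- camera_rays(cam, cbind(us, v))
        t_hit <- denom0 / (g %*% nrm)
        ok <- which(t_hit > 0 & t_hit < zbuf[v + 1L, us + 1L])
        if (length(ok) > 0L) {
          zbuf[v + 1L, us[ok] + 1L] <- t_hit[ok]
          lab[v + 1L, us[ok] + 1L] <- k
        }
      }
    }
  }
  # pillars overwrite anything behind them with background
  for (pl in pillars) {
    box <- pillar_bbox(pl, cam, w, h)
    if (is.null(box)) next
    us <- box$u0:box$u1
    for (v in box$v0:box$v1) {
      g <- camera_rays(cam, cbind(us, v))
      oc <- c(C[1] - pl$center[1], C[2] - pl$center[2])
      A <- g[, 1]^2 + g[, 2]^2
      B <- 2 * (g[, 1] * oc[1] + g[, 2] * oc[2])
      Cc <- sum(oc^2) - pl$radius^2
      disc <- B^2 - 4 * A * Cc
      hit <- disc > 0 & A > 0
      if (!any(hit)) next
      sq <- sqrt(pmax(disc, 0))
      t1 <- (-B - sq) / (2 * A)
      t2 <- (-B + sq) / (2 * A)
      z1 <- C[3] + t1 * g[, 3]
      z2 <- C[3] + t2 * g[, 3]
      t1[!(hit & t1 > 0 & z1 >= pl$z0 & z1 <= pl$z1)] <- Inf
      t2[!(hit & t2 > 0 & z2 >= pl$z0 & z2 <= pl$z1)] <- Inf
      tp <- pmin(t1, t2)
      ok <- which(tp < zbuf[v + 1L, us + 1L])
      if (length(ok) > 0L) {
        zbuf[v + 1L, us[ok] + 1L] <- tp[ok]
        lab[v + 1L, us[ok] + 1L] <- 0L
      }
    }
  }
  lab
}

pillar_bbox <- function(pl, cam, w, h) {
  tt <- seq(0, 2 * pi, length.out = 17L)[-17L]
  ring <- cbind(pl$center[1] + pl$radius * cos(tt),
                pl$center[2] + pl$radius * sin(tt))
  pts <- rbind(cbind(ring, pl$z0), cbind(ring, pl$z1))
  uv <- project_points(cam, pts, allow_behind = TRUE)
  uv <- uv[is.finite(uv[, 1]), , drop = FALSE]
  if (nrow(uv) == 0L) return(NULL)
  u0 <- max(0L, floor(min(uv[, 1]))); u1 <- min(w - 1L, ceiling(max(uv[, 1])))
  v0 <- max(0L, floor(min(uv[, 2]))); v1 <- min(h - 1L, ceiling(max(uv[, 2])))
  if (u1 < u0 || v1 < v0) return(NULL)
  list(u0 = u0, u1 = u1, v0 = v0, v1 = v1)
}

#' Sample an area-uniform labeled point cloud from leaf meshes
#'
#' Stands in for the sparse SfM point cloud: exactly `points_per_leaf` points
#' per leaf, sampled uniformly by area (area-weighted triangle choice +
#' uniform barycentric coordinates), carrying the true leaf label.
#'
#' @param meshes list of posed `leaf_mesh`.
#' @param points_per_leaf samples per leaf (default 200).
#' @param rng_seed integer seed.
#' @return list with `points` (Nx3 mm) and `labels` (integer).
#' @export
sample_point_cloud <- function(meshes, points_per_leaf = 200L, rng_seed = 1L) {
  with_seed(rng_seed, {
    pts <- NULL; labs <- integer(0)
    for (k in seq_along(meshes)) {
      mesh <- meshes[[k]]
      V <- mesh$vertices; Fc <- mesh$faces
      e1 <- V[Fc[, 2], , drop = FALSE] - V[Fc[, 1], , drop = FALSE]
      e2 <- V[Fc[, 3], , drop = FALSE] - V[Fc[, 1], , drop = FALSE]
      cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                  e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                  e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
      a <- sqrt(rowSums(cr^2)) / 2
      tri <- sample.int(nrow(Fc), points_per_leaf, replace = TRUE,
                        prob = a / sum(a))
      r1 <- sqrt(stats::runif(points_per_leaf))
      r2 <- stats::runif(points_per_leaf)
      b1 <- 1 - r1; b2 <- r1 * (1 - r2); b3 <- r1 * r2
      p <- V[Fc[tri, 1], , drop = FALSE] * b1 +
        V[Fc[tri, 2], , drop = FALSE] * b2 +
        V[Fc[tri, 3], , drop = FALSE] * b3
      pts <- rbind(pts, p)
      labs <- c(labs, rep.int(k, points_per_leaf))
    }
    list(points = pts, labels = labs)
  })
}

#' Per-leaf visibility counts of the point cloud across views
#'
#' For each leaf: n is its number of cloud points and n_i the number of those
#' points whose projection into view i lands on a pixel carrying that leaf's
#' label (nearest-pixel mask lookup, so occlusion by other leaves or pillars
#' is accounted for by the rendered masks).
#'
#' @param cloud list with `points`, `labels` (see [sample_point_cloud()]).
#' @param rig a [camera_rig()] (the noise-free cameras that rendered the
#'   masks).
#' @param masks list of label matrices, one per view.
#' @return list per leaf label: `n`, `n_i` (length = number of views).
#' @export
occlude_counts <- function(cloud, rig, masks) {
  labs <- sort(unique(cloud$labels))
  m <- length(rig$cameras)
  out <- lapply(labs, function(l) {
    idx <- cloud$labels == l
    list(label = l, n = sum(idx), n_i = integer(m))
  })
  names(out) <- as.character(labs)
  for (i in seq_len(m)) {
    uv <- project_points(rig$cameras[[i]], cloud$points, allow_behind = TRUE)
    ui <- round(uv[, 1]); vi <- round(uv[, 2])
    msk <- masks[[i]]
    okpix <- is.finite(ui) & ui >= 0 & ui < ncol(msk) & vi >= 0 & vi < nrow(msk)
    hit_lab <- rep(0L, nrow(uv))
    hit_lab[okpix] <- msk[cbind(vi[okpix] + 1L, ui[okpix] + 1L)]
    for (l in labs) {
      out[[as.character(l)]]$n_i[i] <- sum(hit_lab == l & cloud$labels == l)
    }
  }
  out
}

#' Generate a complete synthetic scene with ground truth
#'
#' Builds the plant, camera rigs (noise-free and noised), occluder pillars,
#' per-view label masks (rendered with the noise-free cameras), true closed
#' 3D edge polylines, and the labeled point cloud. All randomness is driven
#' by `spec$rng_seed`.
#'
#' @param spec a [scene_spec()].
#' @param points_per_leaf cloud points per leaf (default 200).
#' @return object of class `leaf_scene` with fields `spec`, `meshes`,
#'   `true_edges` (per leaf, list of closed loops), `areas`, `rig`
#'   (noise-free), `rig_noisy`, `masks`, `cloud`, `pillars`, `image_size`.
#' @export
make_scene <- function(spec, points_per_leaf = 200L) {
  stopifnot(inherits(spec, "scene_spec"))
  meshes <- make_plant(spec$leaves, rng_seed = spec$rng_seed)
  allv <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  ctr <- colMeans(allv)
  extent <- max(dist(rbind(apply(allv, 2, min), apply(allv, 2, max))))
  rigs <- make_camera_rig(spec$n_views, target = ctr,
                          extent = max(extent * 1.35, 80),
                          image_size = spec$image_size,
                          noise_sigma = spec$camera_noise_sigma,
                          rng_seed = spec$rng_seed + 1L)
  pillars <- make_pillars(spec$occluder, z_top = max(allv[, 3]) + 30)
  masks <- lapply(rigs$clean$cameras, function(cam) {
    render_instance_masks(meshes, cam, spec$image_size, pillars)
  })
  cloud <- sample_point_cloud(meshes, points_per_leaf,
                              rng_seed = spec$rng_seed + 2L)
  structure(
    list(spec = spec, meshes = meshes,
         true_edges = lapply(meshes, `[[`, "loops"),
         areas = vapply(meshes, `[[`, numeric(1), "area"),
         rig = rigs$clean, rig_noisy = rigs$noisy,
         masks = masks, cloud = cloud, pillars = pillars,
         image_size = spec$image_size),
    class = "leaf_scene"
  )
}

#' @export
print.leaf_scene <- function(x, ...) {
  cat(sprintf(
    "<leaf_scene: %d leaves, %d views (%dx%d px), sigma=%g mm, occluder=%s>\n",
    length(x$meshes), length(x$rig$cameras), x$image_size[1], x$image_size[2],
    x$spec$camera_noise_sigma, x$spec$occluder))
  invisible(x)
}

#' Default fragmentation and support parameters for an image size
#'
#' The working parameter set for simulated imagery is stated at 1920x1080
#' (l_min 40, l_max 100, tau_overlap 15, tau_d 11 px); for other image sizes
#' they scale linearly with the image width.
#'
#' @param image_size c(width, height) px.
#' @return list with `fragmentation` ([fragmentation_params()]) and `tau_d`
#'   (px).
#' @export
default_sim_params <- function(image_size = c(640L, 480L)) {
  s <- image_size[1] / 1920
  list(
    fragmentation = fragmentation_params(max(4, round(40 * s)),
                                         max(8, round(100 * s)),
                                         max(2, round(15 * s))),
    tau_d = max(2, round(11 * s))
  )
}
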