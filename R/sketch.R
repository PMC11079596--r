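#' Curve-based multiview reconstruction (3D curve sketch)
#'
#' For one leaf: camera pairs with a small pairing angle are admitted; each 2D
#' curve fragment of a view is mapped through the fundamental matrix into an
#' epipolar band in the paired view; fragments overlapping the band form pair
#' hypotheses; per-point epipolar intersections give correspondences that are
#' triangulated into 3D curve fragments; and every reconstructed fragment is
#' reprojected into all remaining views and kept only when enough views
#' support it (enough of its points fall close to that view's 2D edges).
#'
#' @name curve-sketch
#' @keywords internal
NULL

#' Support and pairing parameters for the curve sketch
#'
#' @param tau_v percentage of a reprojected fragment's points that must lie
#'   within `tau_d` of the edges for a view to support it (default 80).
#' @param tau_d support distance in pixels (11 at 1920-wide simulated
#'   imagery; scale with image width, see [default_sim_params()]).
#' @param tau_t_ratio support threshold as a fraction of the total number of
#'   images m; a fragment needs support in at least ceiling(tau_t_ratio * m)
#'   views (default 0.5).
#' @param tau_p minimum per-point support count; points below it are removed
#'   from kept fragments. Default NULL = ceiling(0.5 * ceiling(tau_t_ratio *
#'   m)), computed at filter time.
#' @param b_max maximum camera pairing angle, degrees (30/40/60 for 32/64/128
#'   views; see [default_b_max()]).
#' @param max_hypotheses_per_band cap on pair hypotheses per source fragment
#'   (default 10).
#' @param tangency_angle_min source points whose contour tangent makes less
#'   than this angle (degrees) with their own epipolar line are excluded
#'   (default 15).
#' @param band_dilation_px outward dilation of epipolar bands (default 2).
#' @param min_correspondence_frac minimum fraction of source points with a
#'   correspondence for a hypothesis to be reconstructed (default 0.5).
#' @return object of class `support_params`.
#' @export
support_params <- function(tau_v = 80, tau_d = 11, tau_t_ratio = 0.5,
                           tau_p = NULL, b_max = 30,
                           max_hypotheses_per_band = 10L,
                           tangency_angle_min = 15,
                           band_dilation_px = 2,
                           min_correspondence_frac = 0.5) {
  stopifnot(tau_v > 0, tau_v <= 100, tau_d > 0,
            tau_t_ratio > 0, tau_t_ratio <= 1,
            is.null(tau_p) || tau_p >= 0, b_max > 0, b_max <= 180)
  structure(list(tau_v = tau_v, tau_d = tau_d, tau_t_ratio = tau_t_ratio,
                 tau_p = tau_p, b_max = b_max,
                 max_hypotheses_per_band = as.integer(max_hypotheses_per_band),
                 tangency_angle_min = tangency_angle_min,
                 band_dilation_px = band_dilation_px,
                 min_correspondence_frac = min_correspondence_frac),
            class = "support_params")
}

#' Default maximum pairing angle for an image count
#'
#' 30, 40 and 60 degrees for 32, 64 and 128 views respectively.
#'
#' @param n_views number of images.
#' @return degrees.
#' @export
default_b_max <- function(n_views) {
  if (n_views <= 32L) 30 else if (n_views <= 64L) 40 else 60
}

#' Admitted camera pairs
#'
#' All unordered camera pairs whose [pair_angle()] does not exceed `b_max`.
#'
#' @param rig a [camera_rig()].
#' @param b_max maximum pairing angle, degrees.
#' @return 2-column integer matrix of camera indices (i < j).
#' @export
define_camera_pairs <- function(rig, b_max) {
  m <- length(rig$cameras)
  out <- matrix(0L, 0L, 2L)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (pair_angle(rig, i, j) <= b_max) out <- rbind(out, c(i, j))
    }
  }
  out
}

# epipole of view i for fundamental matrix F (i -> j): right null vector of F
epipole_from_F <- function(F) {
  e <- svd(F, nu = 0, nv = 3)$v[, 3]
  e
}

# angle (deg, in [0,90]) between fragment tangents and the epipolar pencil
# direction at each fragment point; epipole homogeneous 3-vector
tangency_angles <- function(pts, e) {
  n <- nrow(pts)
  # central-difference tangents
  nxt <- pts[c(2:n, n), , drop = FALSE]
  prv <- pts[c(1, 1:(n - 1)), , drop = FALSE]
  tg <- nxt - prv
  # pencil direction at x: x - e (finite epipole) or e's direction (infinite)
  if (abs(e[3]) > 1e-10 * max(abs(e[1:2]))) {
    dir <- cbind(pts[, 1] - e[1] / e[3], pts[, 2] - e[2] / e[3])
  } else {
    dir <- matrix(e[1:2], n, 2, byrow = TRUE)
  }
  cross <- abs(tg[, 1] * dir[, 2] - tg[, 2] * dir[, 1])
  dot <- abs(tg[, 1] * dir[, 1] + tg[, 2] * dir[, 2])
  atan2(cross, dot) * 180 / pi
}

#' Generate pair hypotheses for one source fragment
#'
#' Maps the source fragment into an epipolar band in the paired view, admits
#' candidate fragments overlapping the band, intersects each source point's
#' epipolar line with the candidate polyline (continuity-disambiguated when a
#' line crosses the candidate more than once), drops source points tangential
#' to their epipolar line, ranks hypotheses by the fraction of corresponded
#' source points and truncates to the per-band cap.
#'
#' @param frag source [curve_fragment_2d()] in view i.
#' @param candidates list of [curve_fragment_2d()] in view j belonging to the
#'   same leaf.
#' @param F fundamental matrix from view i to view j.
#' @param params a [support_params()].
#' @return list of `pair_hypothesis` objects: `src_idx` (indices into the
#'   source fragment points), `pts_i`, `pts_j` (corresponding pixel
#'   coordinates), `frac`, `frag_i`, `frag_j`.
#' @export
generate_pair_hypotheses <- function(frag, candidates, F, params) {
  if (length(candidates) == 0L) return(list())
  band <- epipolar_band(F, frag$points, params$band_dilation_px)
  e_i <- epipole_from_F(F)
  tang <- tangency_angles(frag$points, e_i)
  keep_src <- which(tang >= params$tangency_angle_min)
  if (length(keep_src) < 2L) return(list())
  L <- band$lines[keep_src, , drop = FALSE]
  src_seg <- sqrt(rowSums((frag$points[-1, , drop = FALSE] -
                             frag$points[-nrow(frag$points), , drop = FALSE])^2))
  src_arcs <- c(0, cumsum(src_seg))[keep_src]
  hyps <- list()
  for (cand in candidates) {
    cpts <- cand$points
    if (!any(point_in_band(band, cpts))) next
    corr <- chain_epipolar_intersections(L, cpts, params$tangency_angle_min,
                                         src_arcs)
    n_ok <- sum(!is.na(corr[, 1]))
    if (n_ok < 2L) next
    ok <- !is.na(corr[, 1])
    hyps[[length(hyps) + 1L]] <- structure(
      list(src_idx = keep_src[ok],
           pts_i = frag$points[keep_src[ok], , drop = FALSE],
           pts_j = corr[ok, , drop = FALSE],
           frac = n_ok / nrow(frag$points),
           frag_i = frag, frag_j = cand),
      class = "pair_hypothesis")
  }
  if (length(hyps) > params$max_hypotheses_per_band) {
    ord <- order(vapply(hyps, `[[`, numeric(1), "frac"), decreasing = TRUE)
    hyps <- hyps[ord[seq_len(params$max_hypotheses_per_band)]]
  }
  hyps
}

# For each epipolar line (rows of L, normalised), intersect with the candidate
# polyline cpts; when lines cross the polyline several times, the branch is
# chosen by continuity: matched arc positions along the candidate should
# advance (in either global direction) roughly like the arc positions along
# the source fragment, so dynamic programming picks the assignment minimising
# the total deviation from that isometric advance, tried at both candidate
# orientations. A source point whose epipolar line touches the candidate
# nearly tangentially (within min_angle_deg at any crossing) is ambiguous —
# its correspondence sits at a fold where the intersection is unstable — and
# is dropped: the candidate-side mirror of the source-side tangency
# exclusion.
# Returns an n x 2 matrix of view-j points (NA rows = no correspondence).
chain_epipolar_intersections <- function(L, cpts, min_angle_deg = 15,
                                         src_arcs = NULL) {
  n <- nrow(L)
  m <- nrow(cpts)
  seg <- sqrt(rowSums((cpts[-1, , drop = FALSE] - cpts[-m, , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  # signed distances of candidate points to each line: n x m
  D <- L[, 1] %o% cpts[, 1] + L[, 2] %o% cpts[, 2] + matrix(L[, 3], n, m)
  inters <- vector("list", n)
  arcs <- vector("list", n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    tol <- 1e-9 * (1 + max(abs(d)))
    zero <- abs(d) < tol
    # a segment crosses when the signs differ or an endpoint sits on the line
    cross <- which((d[-m] * d[-1] < 0) | zero[-m])
    if (length(cross) == 0L && zero[m]) cross <- m - 1L
    if (length(cross) == 0L) {
      inters[[i]] <- matrix(numeric(0), 0L, 2L)
      arcs[[i]] <- numeric(0)
      next
    }
    # transversality: candidate tangent vs the line direction (-b, a); one
    # tangential touch poisons the whole source point
    tg <- cpts[cross + 1L, , drop = FALSE] - cpts[cross, , drop = FALSE]
    sin_ang <- abs(tg[, 1] * L[i, 1] + tg[, 2] * L[i, 2]) /
      pmax(sqrt(rowSums(tg^2)), 1e-300)
    if (any(sin_ang < sin(min_angle_deg * pi / 180))) {
      inters[[i]] <- matrix(numeric(0), 0L, 2L)
      arcs[[i]] <- numeric(0)
      next
    }
    den <- d[cross] - d[cross + 1L]
    t <- ifelse(abs(den) < tol, 0, d[cross] / den)
    t <- pmin(1, pmax(0, t))
    pts_i <- cpts[cross, , drop = FALSE] +
      (cpts[cross + 1L, , drop = FALSE] - cpts[cross, , drop = FALSE]) * t
    arc_i <- cum[cross] + t * seg[cross]
    # collapse duplicate hits at shared vertices
    if (nrow(pts_i) > 1L) {
      keep <- c(TRUE, rowSums(abs(pts_i[-1, , drop = FALSE] -
                                    pts_i[-nrow(pts_i), , drop = FALSE])) >= 1e-9)
      pts_i <- pts_i[keep, , drop = FALSE]
      arc_i <- arc_i[keep]
    }
    inters[[i]] <- pts_i
    arcs[[i]] <- arc_i
  }
  counts <- vapply(inters, nrow, integer(1))
  out <- matrix(NA_real_, n, 2L)
  active <- which(counts > 0L)
  if (length(active) == 0L) return(out)
  if (is.null(src_arcs)) src_arcs <- seq_len(n)
  # dynamic programme: state = intersection index at each active source
  # point; transition cost = deviation of the candidate arc advance from the
  # source arc advance (sign fixed by the global orientation being tried)
  run_dp <- function(orient) {
    cost <- vector("list", length(active))
    back <- vector("list", length(active))
    cost[[1]] <- rep(0, counts[active[1]])
    for (s in seq_along(active)[-1]) {
      a_now <- arcs[[active[s]]]
      a_prev <- arcs[[active[s - 1]]]
      dsrc <- src_arcs[active[s]] - src_arcs[active[s - 1]]
      k <- length(a_now)
      cost[[s]] <- numeric(k)
      back[[s]] <- integer(k)
      for (j in seq_len(k)) {
        tot <- cost[[s - 1]] + abs((a_now[j] - a_prev) - orient * dsrc)
        back[[s]][j] <- which.min(tot)
        cost[[s]][j] <- min(tot)
      }
    }
    pick <- integer(length(active))
    last <- length(active)
    pick[last] <- which.min(cost[[last]])
    total <- cost[[last]][pick[last]]
    if (last > 1L) {
      for (s in rev(seq_len(last - 1L))) {
        pick[s] <- back[[s + 1]][pick[s + 1]]
      }
    }
    list(total = total, pick = pick)
  }
  fwd <- run_dp(1)
  bwd <- run_dp(-1)
  pick <- if (fwd$total <= bwd$total) fwd$pick else bwd$pick
  for (s in seq_along(active)) {
    out[active[s], ] <- inters[[active[s]]][pick[s], ]
  }
  out
}

#' Reconstruct a 3D curve fragment from a pair hypothesis
#'
#' Per-correspondence DLT triangulation, ordered as the source fragment.
#' Hypotheses with fewer than `min_correspondence_frac` of their source
#' points corresponded are rejected (NULL).
#'
#' @param h a pair hypothesis from [generate_pair_hypotheses()].
#' @param cam_i,cam_j the two cameras.
#' @param params a [support_params()].
#' @return object of class `curve_fragment_3d` (fields `points`, `view_i`,
#'   `view_j`, `loop_id`, `support_views`, `point_support`), or NULL.
#' @export
reconstruct_fragment <- function(h, cam_i, cam_j, params = support_params()) {
  if (h$frac < params$min_correspondence_frac) return(NULL)
  X <- triangulate_points(cam_i, cam_j, h$pts_i, h$pts_j)
  structure(
    list(points = X, view_i = cam_i$view_id, view_j = cam_j$view_id,
         loop_id = h$frag_i$loop_id, is_hole = isTRUE(h$frag_i$is_hole),
         support_views = integer(0),
         point_support = rep.int(0L, nrow(X))),
    class = "curve_fragment_3d")
}

#' @export
print.curve_fragment_3d <- function(x, ...) {
  cat(sprintf("<curve_fragment_3d views (%s,%s) loop %s: %d points, %d supporting views>\n",
              x$view_i, x$view_j, x$loop_id, nrow(x$points),
              length(x$support_views)))
  invisible(x)
}

#' Distance transform of a leaf's 2D edges in one view
#'
#' Rasterises the contour points into an edge image and returns the Euclidean
#' distance to the nearest edge pixel for every pixel.
#'
#' @param contours list of closed Mx2 (u, v) contours (one leaf, one view).
#' @param image_size c(width, height).
#' @return matrix `dist[v + 1, u + 1]` in pixels.
#' @export
edge_distance_map <- function(contours, image_size) {
  w <- image_size[1]; h <- image_size[2]
  img <- matrix(1, h, w)
  for (ctr in contours) {
    p <- resample_polyline(ctr, 0.5)
    ui <- round(p[, 1]); vi <- round(p[, 2])
    okb <- ui >= 0 & ui < w & vi >= 0 & vi < h
    img[cbind(vi[okb] + 1L, ui[okb] + 1L)] <- 0
  }
  if (all(img == 1)) return(matrix(Inf, h, w))
  as.matrix(EBImage::distmap(img, metric = "euclidean"))
}

#' Evaluate reprojection support of reconstructed fragments
#'
#' Each fragment is reprojected into every view except the two it was
#' reconstructed from; a view supports the fragment when at least `tau_v`
#' percent of its points land within `tau_d` px of the leaf's 2D edges in
#' that view. Per-point support counts (number of supporting views containing
#' the point within `tau_d`) are accumulated for the point-level filter.
#' Thresholding is deferred to [support_filter()], so a threshold sweep costs
#' one support evaluation.
#'
#' @param fragments list of `curve_fragment_3d`.
#' @param rig [camera_rig()] (all m views).
#' @param edge_maps list per view of edge distance maps ([edge_distance_map()])
#'   for the target leaf.
#' @param params [support_params()].
#' @return the fragments with `support_views` and `point_support` filled in.
#' @export
evaluate_support <- function(fragments, rig, edge_maps, params) {
  if (length(fragments) == 0L) return(fragments)
  m <- length(rig$cameras)
  sizes <- vapply(fragments, function(f) nrow(f$points), integer(1))
  allpts <- do.call(rbind, lapply(fragments, `[[`, "points"))
  fid <- rep(seq_along(fragments), sizes)
  excl_i <- vapply(fragments, `[[`, integer(1), "view_i")
  excl_j <- vapply(fragments, `[[`, integer(1), "view_j")
  for (v in seq_len(m)) {
    dm <- edge_maps[[v]]
    h <- nrow(dm); w <- ncol(dm)
    uv <- project_points(rig$cameras[[v]], allpts, allow_behind = TRUE)
    ui <- round(uv[, 1]); vi <- round(uv[, 2])
    okb <- is.finite(ui) & ui >= 0 & ui < w & vi >= 0 & vi < h
    near <- rep(FALSE, nrow(allpts))
    near[okb] <- dm[cbind(vi[okb] + 1L, ui[okb] + 1L)] <= params$tau_d
    vid <- rig$cameras[[v]]$view_id
    for (k in seq_along(fragments)) {
      if (vid == excl_i[k] || vid == excl_j[k]) next
      nk <- near[fid == k]
      if (100 * mean(nk) >= params$tau_v) {
        fragments[[k]]$support_views <- c(fragments[[k]]$support_views, vid)
        fragments[[k]]$point_support <- fragments[[k]]$point_support +
          as.integer(nk)
      }
    }
  }
  fragments
}

#' Filter fragments by their support counts
#'
#' A fragment survives when supported in at least ceiling(tau_t_ratio * m)
#' views; on surviving fragments, points supported by fewer than tau_p views
#' are removed, and emptied fragments are dropped. The surviving set shrinks
#' monotonically as tau_t_ratio grows.
#'
#' @param fragments fragments with support filled in ([evaluate_support()]).
#' @param m total number of images in the scene.
#' @param tau_t_ratio support threshold as a fraction of m.
#' @param tau_p per-point minimum support count; default
#'   ceiling(0.5 * ceiling(tau_t_ratio * m)).
#' @return filtered list of `curve_fragment_3d`.
#' @export
support_filter <- function(fragments, m, tau_t_ratio = 0.5, tau_p = NULL) {
  need <- ceiling(tau_t_ratio * m)
  if (is.null(tau_p)) tau_p <- ceiling(0.5 * need)
  out <- list()
  for (f in fragments) {
    if (length(f$support_views) < need) next
    keep <- f$point_support >= tau_p
    if (sum(keep) < 2L) next
    f$points <- f$points[keep, , drop = FALSE]
    f$point_support <- f$point_support[keep]
    out[[length(out) + 1L]] <- f
  }
  out
}

#' Curve-based 3D reconstruction of one leaf
#'
#' Runs the full sketch for a single leaf: fragments the leaf's per-view
#' contours, admits camera pairs, generates pair hypotheses along epipolar
#' bands, triangulates, and evaluates reprojection support. Returns the
#' unfiltered fragments (with support counts) plus the filtered set at the
#' requested threshold; re-filter cheaply at other thresholds with
#' [support_filter()].
#'
#' @param contours_by_view list over views (same order as `rig$cameras`) of
#'   lists of closed Mx2 contours of this leaf in that view (may be empty).
#' @param rig [camera_rig()] used for reconstruction (noisy rig of a
#'   synthetic scene, or SfM cameras).
#' @param image_size c(width, height) px.
#' @param params [support_params()].
#' @param frag_params [fragmentation_params()].
#' @return list with `fragments` (all reconstructed, support evaluated),
#'   `kept` (after [support_filter()] at `params$tau_t_ratio`), `m`,
#'   `n_hypotheses`.
#' @export
sketch_leaf <- function(contours_by_view, rig, image_size,
                        params = support_params(),
                        frag_params = fragmentation_params()) {
  m <- length(rig$cameras)
  stopifnot(length(contours_by_view) == m)
  # contours may be bare point matrices or list(points, is_hole) records
  as_records <- function(ctrs) {
    lapply(ctrs, function(ct) {
      if (is.matrix(ct)) list(points = ct, is_hole = FALSE) else ct
    })
  }
  contours_by_view <- lapply(contours_by_view, as_records)
  frags2d <- vector("list", m)
  for (v in seq_len(m)) {
    fl <- list()
    ctrs <- contours_by_view[[v]]
    for (li in seq_along(ctrs)) {
      fl <- c(fl, fragment_contour(ctrs[[li]]$points, frag_params,
                                   view_id = rig$cameras[[v]]$view_id,
                                   loop_id = li - 1L,
                                   is_hole = isTRUE(ctrs[[li]]$is_hole)))
    }
    frags2d[[v]] <- fl
  }
  edge_maps <- lapply(seq_len(m), function(v) {
    edge_distance_map(lapply(contours_by_view[[v]], `[[`, "points"),
                      image_size)
  })
  pairs <- define_camera_pairs(rig, params$b_max)
  frag3 <- list()
  n_hyp <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (length(frags2d[[i]]) == 0L || length(frags2d[[j]]) == 0L) next
    F <- fundamental_matrix(rig$cameras[[i]], rig$cameras[[j]])
    j_is_hole <- vapply(frags2d[[j]], `[[`, logical(1), "is_hole")
    for (f in frags2d[[i]]) {
      # holes only pair with holes, the outer edge with the outer edge
      cands <- frags2d[[j]][j_is_hole == f$is_hole]
      hyps <- generate_pair_hypotheses(f, cands, F, params)
      n_hyp <- n_hyp + length(hyps)
      for (h in hyps) {
        g <- reconstruct_fragment(h, rig$cameras[[i]], rig$cameras[[j]], params)
        if (!is.null(g)) frag3[[length(frag3) + 1L]] <- g
      }
    }
  }
  frag3 <- evaluate_support(frag3, rig, edge_maps, params)
  kept <- support_filter(frag3, m, params$tau_t_ratio, params$tau_p)
  list(fragments = frag3, kept = kept, m = m, n_hypotheses = n_hyp)
}

#' Group pooled fragment points into loop candidates
#'
#' DBSCAN over a pool of reconstructed 3D fragment points; each cluster is
#' one loop candidate (outer edge or a hole), noise points are discarded.
#' Grouping is invariant to the order fragments are pooled in.
#'
#' @param points Nx3 pooled fragment points, mm.
#' @param eps DBSCAN radius, mm.
#' @param min_samples DBSCAN core threshold (default 10).
#' @return list of point matrices, one per group, largest spatial extent
#'   first.
#' @export
group_fragments_into_loops <- function(points, eps, min_samples = 10L) {
  pts <- to_matrix3(points)
  labels <- dbscan_points(pts, eps = eps, min_samples = min_samples)
  groups <- split(seq_len(nrow(pts)), labels)
  groups <- groups[names(groups) != "-1"]
  mats <- lapply(groups, function(ix) pts[ix, , drop = FALSE])
  extent <- vapply(mats, function(g) {
    sqrt(sum((apply(g, 2, max) - apply(g, 2, min))^2))
  }, numeric(1))
  unname(mats[order(extent, decreasing = TRUE)])
}

#' Group fragment points into loops and fit closed B-splines
#'
#' The surviving fragments of one leaf are pooled into an outer-edge pool and
#' a hole pool (fragments carry the hole flag of their source contours); each
#' pool is separated into loops with [group_fragments_into_loops()], every
#' group is ordered by polar angle in its best-fit plane, and a closed
#' periodic B-spline is fit per loop. The outer edge uses `n` intervals, hole
#' loops max(8, n/2).
#'
#' @param fragments list of `curve_fragment_3d` (typically `kept` from
#'   [sketch_leaf()]).
#' @param eps DBSCAN radius for the outer pool, mm; default 8 percent of the
#'   pooled bounding-box diagonal.
#' @param hole_eps DBSCAN radius for the hole pool, mm (default 3). A hole
#'   ring can carry systematic gaps of a couple of mm where ring-camera
#'   epipolar tangency excludes its top and bottom arcs, so the radius must
#'   bridge those gaps while staying below the spacing between neighbouring
#'   holes; 3 mm suits the mm-to-cm-scale holes of typical leaves. Hole
#'   groups below 2 percent of the hole pool are discarded as strays.
#' @param min_samples DBSCAN core threshold (default 10).
#' @param n B-spline interval parameter for the outer loop (default 16).
#' @param k spline degree (default 3).
#' @return object of class `leaf_edge_3d`: list with `loops` (each: `model`,
#'   `points` sampled closed polyline, `n_source_points`, `is_outer`),
#'   `failures` (messages for groups that could not be fit).
#' @export
fit_leaf_edges <- function(fragments, eps = NULL, hole_eps = 3,
                           min_samples = 10L, n = 16L, k = 3L) {
  stopifnot(length(fragments) >= 1L)
  hole_flag <- vapply(fragments, function(f) isTRUE(f$is_hole), logical(1))
  allpts <- do.call(rbind, lapply(fragments, `[[`, "points"))
  diag <- sqrt(sum((apply(allpts, 2, max) - apply(allpts, 2, min))^2))
  if (is.null(eps)) eps <- 0.08 * diag

  loops <- list()
  failures <- character(0)
  fit_group <- function(g, is_outer, gname) {
    n_loop <- if (is_outer) n else max(8L, n %/% 2L)
    res <- tryCatch({
      par <- parameterize_loop(g)
      model <- fit_closed_bspline(par$l, par$points, n = n_loop, k = k)
      list(model = model, points = sample_bspline(model),
           n_source_points = nrow(g), is_outer = is_outer)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <<- c(failures, sprintf("%s: %s", gname, res))
    } else {
      loops[[length(loops) + 1L]] <<- res
    }
  }

  outer_pts <- allpts[rep(!hole_flag, vapply(fragments, function(f)
    nrow(f$points), integer(1))), , drop = FALSE]
  if (nrow(outer_pts) >= min_samples) {
    og <- tryCatch(group_fragments_into_loops(outer_pts, eps, min_samples),
                   error = function(e) list())
    # the largest group is the outer edge; smaller outer-pool groups are
    # stray (typically ghost remnants) and reported, not fit
    if (length(og) >= 1L) fit_group(og[[1]], TRUE, "outer loop")
    if (length(og) > 1L) {
      failures <- c(failures,
                    sprintf("%d stray outer-pool group(s) discarded",
                            length(og) - 1L))
    }
  }
  hole_pts <- allpts[rep(hole_flag, vapply(fragments, function(f)
    nrow(f$points), integer(1))), , drop = FALSE]
  if (nrow(hole_pts) >= min_samples) {
    hg <- tryCatch(group_fragments_into_loops(hole_pts, hole_eps, min_samples),
                   error = function(e) list())
    big <- vapply(hg, nrow, integer(1)) >=
      max(min_samples, ceiling(0.02 * nrow(hole_pts)))
    if (any(!big)) {
      failures <- c(failures,
                    sprintf("%d stray hole group(s) discarded", sum(!big)))
    }
    hg <- hg[big]
    for (gi in seq_along(hg)) {
      fit_group(hg[[gi]], FALSE, sprintf("hole loop %d", gi))
    }
  }
  structure(list(loops = loops, failures = failures, eps = eps,
                 hole_eps = hole_eps),
            class = "leaf_edge_3d")
}

#' @export
print.leaf_edge_3d <- function(x, ...) {
  cat(sprintf("<leaf_edge_3d: %d closed loop(s)%s>\n", length(x$loops),
              if (length(x$failures)) sprintf(", %d failed group(s)", length(x$failures)) else ""))
  invisible(x)
}
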