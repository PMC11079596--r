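#' Leaf correspondence identification across views
#'
#' Mask instances are per-view: instance 3 in one image and instance 5 in
#' another may be the same physical leaf. Correspondence is recovered through
#' the 3D point cloud: cluster the cloud into leaves (DBSCAN), and in every
#' view project the points visible from that camera (hidden point removal
#' guards against back-side leakage) onto the mask; each instance is then
#' assigned to the cluster that drops the most points on it.
#'
#' @name correspondence
#' @keywords internal
NULL

#' Count reprojected cluster points per mask instance
#'
#' For each view: apply hidden point removal from the camera centre, project
#' the surviving points, and for each point landing on a non-background mask
#' pixel increment the (cluster, instance) cell. Points on background or
#' outside the frame are ignored.
#'
#' @param points Nx3 cloud, world mm.
#' @param cluster_labels integer labels from [dbscan_points()]; -1 (noise) is
#'   excluded from counting.
#' @param rig [camera_rig()] used for reprojection.
#' @param masks list of label matrices, one per view.
#' @param use_hpr apply hidden point removal per view (default TRUE).
#' @param radius_factor passed to [hidden_point_removal()].
#' @return list of per-view count matrices (rows: sorted cluster labels;
#'   columns: sorted instance labels present in that view's mask).
#' @export
count_reprojections <- function(points, cluster_labels, rig, masks,
                                use_hpr = TRUE, radius_factor = 100) {
  stopifnot(length(rig$cameras) == length(masks))
  keep <- cluster_labels != -1L
  pts <- points[keep, , drop = FALSE]
  cl <- cluster_labels[keep]
  clusters <- sort(unique(cl))
  out <- vector("list", length(masks))
  for (i in seq_along(masks)) {
    msk <- masks[[i]]
    instances <- sort(setdiff(unique(as.vector(msk)), 0L))
    counts <- matrix(0L, length(clusters), length(instances),
                     dimnames = list(cluster = clusters, instance = instances))
    if (length(instances) > 0L && nrow(pts) > 0L) {
      vis <- if (use_hpr && nrow(pts) >= 4L) {
        suppressWarnings(
          hidden_point_removal(pts, rig$cameras[[i]]$center, radius_factor))
      } else {
        seq_len(nrow(pts))
      }
      uv <- project_points(rig$cameras[[i]], pts[vis, , drop = FALSE],
                           allow_behind = TRUE)
      ui <- round(uv[, 1]); vi <- round(uv[, 2])
      okpix <- is.finite(ui) & ui >= 0 & ui < ncol(msk) &
        vi >= 0 & vi < nrow(msk)
      lab <- rep(0L, length(vis))
      lab[okpix] <- msk[cbind(vi[okpix] + 1L, ui[okpix] + 1L)]
      hit <- lab != 0L
      if (any(hit)) {
        tb <- table(factor(cl[vis][hit], levels = clusters),
                    factor(lab[hit], levels = instances))
        counts <- counts + unclass(tb)
      }
    }
    out[[i]] <- counts
  }
  out
}

#' Build the instance-to-leaf identity map from reprojection counts
#'
#' Each (view, instance) is assigned to the cluster with the maximal count
#' for that instance. Ties and all-zero columns are left UNASSIGNED (NA) and
#' excluded from reconstruction.
#'
#' @param counts list of per-view count matrices from [count_reprojections()].
#' @return object of class `leaf_identity_map`: list with `assignment`
#'   (list per view: named integer vector instance -> cluster, NA when
#'   unassigned) and `counts`.
#' @export
build_identity <- function(counts) {
  assignment <- lapply(counts, function(cm) {
    if (ncol(cm) == 0L) return(integer(0))
    clusters <- as.integer(rownames(cm))
    res <- vapply(seq_len(ncol(cm)), function(j) {
      col <- cm[, j]
      mx <- max(col)
      if (mx == 0L || sum(col == mx) > 1L) NA_integer_ else clusters[which.max(col)]
    }, integer(1))
    names(res) <- colnames(cm)
    res
  })
  structure(list(assignment = assignment, counts = counts),
            class = "leaf_identity_map")
}

#' @export
print.leaf_identity_map <- function(x, ...) {
  n_inst <- sum(lengths(x$assignment))
  n_un <- sum(vapply(x$assignment, function(a) sum(is.na(a)), integer(1)))
  cat(sprintf("<leaf_identity_map: %d views, %d instances (%d unassigned)>\n",
              length(x$assignment), n_inst, n_un))
  invisible(x)
}

#' Identify leaves across views from a labeled-free point cloud
#'
#' Convenience wrapper: DBSCAN clustering of the cloud, reprojection counting
#' with hidden point removal, and argmax assignment.
#'
#' @param points Nx3 sparse cloud, world mm.
#' @param rig [camera_rig()].
#' @param masks list of per-view label matrices.
#' @param eps DBSCAN radius, mm (required; for synthetic scenes
#'   [suggest_dbscan_eps()] gives half the minimum inter-leaf centroid
#'   spacing).
#' @param min_samples DBSCAN core threshold (default 10).
#' @param use_hpr apply hidden point removal (default TRUE).
#' @param radius_factor hidden point removal sphere factor (default 100).
#' @return list with `identity` ([build_identity()] result), `cluster_labels`.
#' @export
identify_leaves <- function(points, rig, masks, eps, min_samples = 10L,
                            use_hpr = TRUE, radius_factor = 100) {
  cl <- dbscan_points(points, eps = eps, min_samples = min_samples)
  counts <- count_reprojections(points, cl, rig, masks,
                                use_hpr = use_hpr,
                                radius_factor = radius_factor)
  list(identity = build_identity(counts), cluster_labels = cl)
}

#' Suggested DBSCAN radius for a synthetic scene
#'
#' Half the minimum inter-leaf centroid spacing.
#'
#' @param scene a `leaf_scene`.
#' @return eps in mm.
#' @export
suggest_dbscan_eps <- function(scene) {
  ctrs <- t(vapply(scene$meshes, function(m) colMeans(m$vertices), numeric(3)))
  if (nrow(ctrs) < 2L) return(0.25 * max(dist(scene$meshes[[1]]$vertices)))
  0.5 * min(dist(ctrs))
}
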