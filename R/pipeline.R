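#' Full reconstruction pipeline
#'
#' Masks + cameras (+ optional sparse cloud for leaf correspondence) to
#' fitted closed 3D leaf edges, with per-leaf error handling: a leaf that
#' yields no fragments or an ill-conditioned fit is reported and skipped,
#' never fatal.
#'
#' @name pipeline
#' @keywords internal
NULL

#' Run the reconstruction pipeline on in-memory inputs
#'
#' Stages: (1) leaf correspondence (when a cloud is given) via DBSCAN +
#' hidden point removal + reprojection counting, otherwise mask labels are
#' trusted to be consistent across views; (2) per-leaf contour extraction;
#' (3) curve-based multiview reconstruction with reprojection-support
#' filtering; (4) loop grouping and closed B-spline fitting; (5) evaluation
#' against ground truth when provided.
#'
#' @param masks list of per-view label matrices.
#' @param rig [camera_rig()] used for reconstruction.
#' @param image_size c(width, height) px.
#' @param cloud_points optional Nx3 sparse cloud (mm) for correspondence.
#' @param eps DBSCAN radius for the cloud, mm (required with `cloud_points`).
#' @param min_samples DBSCAN core threshold (default 10).
#' @param frag_params [fragmentation_params()]; default scaled to the image
#'   size via [default_sim_params()].
#' @param sup_params [support_params()]; default uses the image-size-scaled
#'   tau_d and [default_b_max()].
#' @param spline_n,spline_k closed B-spline intervals (outer loop) and degree.
#' @param use_hpr hidden point removal during correspondence (default TRUE).
#' @param truth_edges optional list (per true leaf) of lists of closed loops
#'   for evaluation.
#' @param truth_areas optional per-true-leaf planform areas, mm^2.
#' @param verbose print per-leaf progress.
#' @return object of class `reconstruction_bundle`: `leaves` (per
#'   reconstructed leaf: `label`, `sketch`, `edges`, optional `eval`),
#'   `identity`, `params`, `status` ("ok"/"partial"/"failed"), `failed`
#'   (messages).
#' @export
run_pipeline <- function(masks, rig, image_size, cloud_points = NULL,
                         eps = NULL, min_samples = 10L,
                         frag_params = NULL, sup_params = NULL,
                         spline_n = 16L, spline_k = 3L, use_hpr = TRUE,
                         truth_edges = NULL, truth_areas = NULL,
                         verbose = FALSE) {
  m <- length(rig$cameras)
  stopifnot(length(masks) == m)
  ds <- default_sim_params(image_size)
  if (is.null(frag_params)) frag_params <- ds$fragmentation
  if (is.null(sup_params)) {
    sup_params <- support_params(tau_d = ds$tau_d, b_max = default_b_max(m))
  }

  # --- correspondence ---
  identity <- NULL
  if (!is.null(cloud_points)) {
    stopifnot(!is.null(eps))
    idres <- identify_leaves(cloud_points, rig, masks, eps = eps,
                             min_samples = min_samples, use_hpr = use_hpr)
    identity <- idres$identity
    leaf_labels <- sort(unique(stats::na.omit(unlist(identity$assignment))))
    inst_for_leaf <- function(leaf, v) {
      a <- identity$assignment[[v]]
      as.integer(names(a)[!is.na(a) & a == leaf])
    }
  } else {
    leaf_labels <- sort(setdiff(unique(unlist(lapply(masks, unique))), 0L))
    inst_for_leaf <- function(leaf, v) leaf
  }

  leaves <- list()
  failed <- character(0)
  for (leaf in leaf_labels) {
    if (verbose) message("leaf ", leaf)
    res <- tryCatch({
      contours_by_view <- lapply(seq_len(m), function(v) {
        insts <- inst_for_leaf(leaf, v)
        cl <- list()
        for (ins in insts) {
          cl <- c(cl, extract_contours(masks[[v]], ins))
        }
        cl
      })
      if (all(lengths(contours_by_view) == 0L)) stop("leaf absent from all views")
      sk <- sketch_leaf(contours_by_view, rig, image_size,
                        params = sup_params, frag_params = frag_params)
      if (length(sk$kept) == 0L) stop("no supported curve fragments")
      edges <- fit_leaf_edges(sk$kept, n = spline_n, k = spline_k)
      if (length(edges$loops) == 0L) {
        stop(paste("no loop could be fit:",
                   paste(edges$failures, collapse = "; ")))
      }
      list(label = leaf, sketch = sk, edges = edges)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failed <- c(failed, sprintf("leaf %s: %s", leaf, res))
    } else {
      leaves[[length(leaves) + 1L]] <- res
    }
  }

  # --- evaluation against ground truth ---
  if (!is.null(truth_edges) && length(leaves) > 0L) {
    true_ctr <- t(vapply(truth_edges, function(loops) {
      colMeans(loops[[1]][-nrow(loops[[1]]), , drop = FALSE])
    }, numeric(3)))
    for (i in seq_along(leaves)) {
      outer_i <- which(vapply(leaves[[i]]$edges$loops, `[[`, logical(1),
                              "is_outer"))[1]
      rec <- leaves[[i]]$edges$loops[[outer_i]]$points
      ctr <- colMeans(rec)
      tk <- which.min(colSums((t(true_ctr) - ctr)^2))
      fr <- frechet_closed(rec, truth_edges[[tk]][[1]])
      ev <- list(true_leaf = tk, frechet = fr)
      if (!is.null(truth_areas)) ev$sfd <- sfd(fr, truth_areas[tk])
      leaves[[i]]$eval <- ev
    }
  }

  status <- if (length(leaves) == 0L) "failed"
            else if (length(failed) > 0L) "partial" else "ok"
  structure(
    list(leaves = leaves, identity = identity,
         params = list(fragmentation = frag_params, support = sup_params,
                       spline = list(n = spline_n, k = spline_k),
                       clustering = list(eps = eps, min_samples = min_samples)),
         status = status, failed = failed),
    class = "reconstruction_bundle")
}

#' @export
print.reconstruction_bundle <- function(x, ...) {
  cat(sprintf("<reconstruction_bundle: %d leaf edge set(s), status %s>\n",
              length(x$leaves), x$status))
  for (lf in x$leaves) {
    ev <- if (!is.null(lf$eval)) {
      sprintf("; Frechet %.2f mm%s", lf$eval$frechet,
              if (!is.null(lf$eval$sfd)) sprintf(", SFD %.3f", lf$eval$sfd) else "")
    } else ""
    cat(sprintf("  leaf %s: %d kept fragment(s), %d loop(s)%s\n",
                lf$label, length(lf$sketch$kept), length(lf$edges$loops), ev))
  }
  if (length(x$failed)) cat("  failed:", paste(x$failed, collapse = " | "), "\n")
  invisible(x)
}

#' Reconstruct a synthetic scene end to end
#'
#' Convenience wrapper around [run_pipeline()] for a [make_scene()] result:
#' masks from the scene, reconstruction cameras from the noised rig (equal to
#' the clean rig at sigma 0), the scene's sparse cloud for correspondence
#' (skipped for single-leaf scenes), and evaluation against the scene's true
#' edges.
#'
#' @param scene a `leaf_scene`.
#' @param use_cloud run leaf correspondence from the cloud (default: TRUE
#'   when the scene has more than one leaf).
#' @param ... passed to [run_pipeline()].
#' @return a `reconstruction_bundle`.
#' @export
reconstruct_scene <- function(scene, use_cloud = length(scene$meshes) > 1L,
                              ...) {
  run_pipeline(
    masks = scene$masks, rig = scene$rig_noisy,
    image_size = scene$image_size,
    cloud_points = if (use_cloud) scene$cloud$points,
    eps = if (use_cloud) suggest_dbscan_eps(scene),
    truth_edges = scene$true_edges, truth_areas = scene$areas, ...)
}
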