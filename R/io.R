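#' File formats
#'
#' All world units are millimetres and all image units pixels. Cameras travel
#' as JSON (3x4 projection matrices per view), masks as PNG label images,
#' point clouds as ASCII PLY with an integer `leaf` vertex property, curve
#' fragments and fitted edges as JSON, and fitted edges additionally as OBJ
#' polylines.
#'
#' @name file-formats
#' @keywords internal
NULL

#' Write / read cameras as JSON
#'
#' Format: `{"units": "mm/px", "views": [{"view_id", "P" (3x4 row-major),
#' "image_size"}]}`.
#'
#' @param rig a [camera_rig()].
#' @param path output file.
#' @return `read_cameras_json` returns a [camera_rig()].
#' @export
write_cameras_json <- function(rig, path) {
  views <- lapply(rig$cameras, function(cam) {
    list(view_id = cam$view_id,
         P = unname(apply(cam$P, 1, function(r) r, simplify = FALSE)),
         image_size = cam$image_size)
  })
  jsonlite::write_json(list(units = "world mm, image px", views = views),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cameras_json
#' @export
read_cameras_json <- function(path) {
  js <- jsonlite::read_json(path)
  cams <- lapply(js$views, function(v) {
    P <- do.call(rbind, lapply(v$P, unlist))
    camera(P, view_id = v$view_id,
           image_size = if (!is.null(v$image_size)) unlist(v$image_size))
  })
  camera_rig(cams)
}

#' Write / read a label mask as PNG
#'
#' Labels up to 255 are stored as 8-bit grayscale; larger labels are packed
#' losslessly into the red/green channels (label = 256 * R + G). Both
#' round-trip exactly.
#'
#' @param mask integer matrix `mask[v + 1, u + 1]`.
#' @param path file path.
#' @return `read_mask_png` returns the integer label matrix.
#' @export
write_mask_png <- function(mask, path) {
  mx <- max(mask)
  stopifnot(mx <= 65535L, min(mask) >= 0L)
  if (mx <= 255L) {
    png::writePNG(mask / 255, path)
  } else {
    arr <- array(0, dim = c(nrow(mask), ncol(mask), 3))
    arr[, , 1] <- (mask %/% 256L) / 255
    arr[, , 2] <- (mask %% 256L) / 255
    png::writePNG(arr, path)
  }
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    m <- round(img * 255)
  } else {
    m <- 256L * round(img[, , 1] * 255) + round(img[, , 2] * 255)
  }
  storage.mode(m) <- "integer"
  m
}

#' Write / read a labeled point cloud as ASCII PLY
#'
#' Vertices x, y, z (mm, double precision) with an integer `leaf` property.
#'
#' @param points Nx3 matrix, mm.
#' @param labels integer vector of leaf labels.
#' @param path file path.
#' @return `read_ply` returns list(points, labels).
#' @export
write_ply <- function(points, labels, path) {
  pts <- to_matrix3(points)
  stopifnot(length(labels) == nrow(pts))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    "comment units: mm",
    sprintf("element vertex %d", nrow(pts)),
    "property double x", "property double y", "property double z",
    "property int leaf", "end_header"), con)
  writeLines(paste(format(pts[, 1], digits = 17, trim = TRUE, scientific = FALSE),
                   format(pts[, 2], digits = 17, trim = TRUE, scientific = FALSE),
                   format(pts[, 3], digits = 17, trim = TRUE, scientific = FALSE),
                   as.integer(labels)), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  hend <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", lines, value = TRUE)[1]))
  props <- sub("^property \\S+ ", "", grep("^property ", lines, value = TRUE))
  body <- utils::read.table(text = lines[(hend + 1):(hend + nv)],
                            col.names = props)
  list(points = as.matrix(body[, c("x", "y", "z")]),
       labels = as.integer(body$leaf))
}

#' Write 3D curve fragments as JSON
#'
#' One record per fragment: leaf label, source view pair, loop id, points,
#' per-point support counts, supporting views.
#'
#' @param fragments_by_leaf named list (per leaf label) of lists of
#'   `curve_fragment_3d`.
#' @param path file path.
#' @return `read_fragments_json` returns the same structure.
#' @export
write_fragments_json <- function(fragments_by_leaf, path) {
  recs <- list()
  for (leaf in names(fragments_by_leaf)) {
    for (f in fragments_by_leaf[[leaf]]) {
      recs[[length(recs) + 1L]] <- list(
        leaf = as.integer(leaf), view_i = f$view_i, view_j = f$view_j,
        loop = f$loop_id, is_hole = isTRUE(f$is_hole),
        points = list(x = f$points[, 1], y = f$points[, 2],
                      z = f$points[, 3]),
        point_support = f$point_support, support_views = f$support_views)
    }
  }
  jsonlite::write_json(list(units = "mm", fragments = recs), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fragments_json
#' @export
read_fragments_json <- function(path) {
  js <- jsonlite::read_json(path)
  out <- list()
  for (rec in js$fragments) {
    f <- structure(list(
      points = cbind(unlist(rec$points$x), unlist(rec$points$y),
                     unlist(rec$points$z)),
      view_i = rec$view_i, view_j = rec$view_j, loop_id = rec$loop,
      is_hole = isTRUE(rec$is_hole),
      support_views = as.integer(unlist(rec$support_views)),
      point_support = as.integer(unlist(rec$point_support))),
      class = "curve_fragment_3d")
    leaf <- as.character(rec$leaf)
    out[[leaf]] <- c(out[[leaf]], list(f))
  }
  out
}

#' Write fitted leaf edges as JSON
#'
#' One record per loop: leaf label, loop index, `n`, `k`, and per-coordinate
#' B-spline coefficients.
#'
#' @param edges_by_leaf named list (per leaf label) of `leaf_edge_3d`.
#' @param path file path.
#' @return `read_edges_json` returns a named list per leaf of lists of
#'   `closed_bspline` models (with `is_outer` attribute).
#' @export
write_edges_json <- function(edges_by_leaf, path) {
  recs <- list()
  for (leaf in names(edges_by_leaf)) {
    loops <- edges_by_leaf[[leaf]]$loops
    for (li in seq_along(loops)) {
      md <- loops[[li]]$model
      recs[[length(recs) + 1L]] <- list(
        leaf = as.integer(leaf), loop = li - 1L, n = md$n, k = md$k,
        is_outer = loops[[li]]$is_outer,
        coeffs = list(x = md$coeffs[, 1], y = md$coeffs[, 2],
                      z = md$coeffs[, 3]))
    }
  }
  jsonlite::write_json(list(units = "mm", edges = recs), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_edges_json
#' @export
read_edges_json <- function(path) {
  js <- jsonlite::read_json(path)
  out <- list()
  for (rec in js$edges) {
    md <- structure(
      list(coeffs = cbind(unlist(rec$coeffs$x), unlist(rec$coeffs$y),
                          unlist(rec$coeffs$z)),
           n = rec$n, k = rec$k),
      class = "closed_bspline")
    attr(md, "is_outer") <- isTRUE(rec$is_outer)
    leaf <- as.character(rec$leaf)
    out[[leaf]] <- c(out[[leaf]], list(md))
  }
  out
}

#' Export fitted leaf edges as OBJ polylines
#'
#' Each loop is sampled at `n_points` positions and written as an OBJ line
#' element; vertex count is exactly `n_points` per loop.
#'
#' @param edges_by_leaf named list (per leaf label) of `leaf_edge_3d`.
#' @param path file path.
#' @param n_points samples per loop (default 256).
#' @export
write_obj_polylines <- function(edges_by_leaf, path, n_points = 256L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# leaf edge polylines (units mm)", con)
  off <- 0L
  for (leaf in names(edges_by_leaf)) {
    loops <- edges_by_leaf[[leaf]]$loops
    for (li in seq_along(loops)) {
      p <- sample_bspline(loops[[li]]$model, n_points, close = FALSE)
      writeLines(sprintf("o leaf%s_loop%d", leaf, li - 1L), con)
      writeLines(sprintf("v %.9f %.9f %.9f", p[, 1], p[, 2], p[, 3]), con)
      idx <- off + seq_len(n_points)
      writeLines(paste("l", paste(c(idx, idx[1]), collapse = " ")), con)
      off <- off + n_points
    }
  }
  invisible(path)
}

#' Write a synthetic scene to a directory
#'
#' Masks as PNG (`mask_####.png`), cameras (noise-free and noisy) as JSON,
#' the labeled cloud as PLY, true edges as JSON polylines, and the scene
#' specification as JSON.
#'
#' @param scene a `leaf_scene`.
#' @param dir output directory (created).
#' @return the directory, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(scene$masks)) {
    write_mask_png(scene$masks[[i]], file.path(dir, sprintf("mask_%04d.png", i)))
  }
  write_cameras_json(scene$rig, file.path(dir, "cameras.json"))
  write_cameras_json(scene$rig_noisy, file.path(dir, "cameras_noisy.json"))
  write_ply(scene$cloud$points, scene$cloud$labels, file.path(dir, "cloud.ply"))
  edges <- list()
  for (k in seq_along(scene$true_edges)) {
    edges[[k]] <- lapply(scene$true_edges[[k]], function(L) {
      list(x = L[, 1], y = L[, 2], z = L[, 3])
    })
  }
  jsonlite::write_json(list(units = "mm", leaves = edges),
                       file.path(dir, "true_edges.json"),
                       auto_unbox = TRUE, digits = NA)
  sp <- scene$spec
  jsonlite::write_json(
    list(n_views = sp$n_views, camera_noise_sigma = sp$camera_noise_sigma,
         occluder = sp$occluder, image_size = sp$image_size,
         rng_seed = sp$rng_seed,
         leaves = lapply(sp$leaves, unclass)),
    file.path(dir, "scene.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
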