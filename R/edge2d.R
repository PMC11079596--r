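#' 2D leaf contour extraction and fragmentation
#'
#' Leaf edges are extracted per instance from label masks as closed sub-pixel
#' contours (outer boundary plus one loop per hole), then divided into
#' overlapping curve fragments with arc lengths in a set range — the unit of
#' matching for curve-based multiview reconstruction.
#'
#' Masks are integer matrices indexed `mask[v + 1, u + 1]` (row = image row v,
#' column = image column u, both 0-based in pixel coordinates); 0 is
#' background.
#'
#' @name edge2d
#' @keywords internal
NULL

#' Fragmentation parameters
#'
#' @param l_min,l_max fragment arc-length range, pixels. Working defaults are
#'   (40, 100) for simulated imagery and (80, 200) for real photographs;
#'   scale them with the image size.
#' @param tau_overlap minimum arc-length overlap between cyclically
#'   consecutive fragments, pixels (15 simulated / 30 real).
#' @return object of class `fragmentation_params`.
#' @export
fragmentation_params <- function(l_min = 40, l_max = 100, tau_overlap = 15) {
  stopifnot(l_min > 0, l_min <= l_max, tau_overlap >= 0, tau_overlap < l_min)
  structure(list(l_min = l_min, l_max = l_max, tau_overlap = tau_overlap),
            class = "fragmentation_params")
}

#' Extract closed contours of one instance from a label mask
#'
#' Contours are traced on the pixel boundary (marching squares at level 0.5
#' on the instance's indicator image), giving sub-pixel vertices at
#' half-integer positions and vertex spacing below 2 px. Outer contours are
#' returned counter-clockwise (positive shoelace area in (u, v) coordinates),
#' hole contours clockwise.
#'
#' @param mask integer label matrix, `mask[v + 1, u + 1]`.
#' @param instance_id label to trace.
#' @return list of contours; each is a list with `points` (closed Mx2 (u, v)
#'   matrix, first row repeated last), `is_hole` (logical), `area` (unsigned
#'   enclosed area, px^2). Empty list if the instance is absent or smaller
#'   than 4 px.
#' @export
extract_contours <- function(mask, instance_id) {
  b <- mask == instance_id
  npix <- sum(b)
  if (npix == 0L) return(list())
  if (npix < 4L) {
    warning(sprintf("instance %s has only %d px; too small to trace", instance_id, npix))
    return(list())
  }
  h <- nrow(mask); w <- ncol(mask)
  # z[i, j] indexed by (u, v): transpose, then pad with background
  z <- matrix(0, w + 2L, h + 2L)
  z[2:(w + 1L), 2:(h + 1L)] <- t(b) * 1
  cl <- grDevices::contourLines(x = (-1):w, y = (-1):h, z = z, levels = 0.5)
  loops <- lapply(cl, function(ctr) {
    pts <- cbind(u = ctr$x, v = ctr$y)
    if (any(pts[1, ] != pts[nrow(pts), ])) pts <- rbind(pts, pts[1, ])
    a <- shoelace_area(pts)
    list(points = pts, signed_area = a)
  })
  # holes: loops contained in another loop (even-odd on a vertex)
  k <- length(loops)
  is_hole <- logical(k)
  if (k > 1L) {
    for (i in seq_len(k)) {
      inside <- vapply(seq_len(k)[-i], function(j) {
        point_in_polygon(loops[[i]]$points[1, ], loops[[j]]$points)
      }, logical(1))
      is_hole[i] <- (sum(inside) %% 2L) == 1L
    }
  }
  out <- vector("list", k)
  for (i in seq_len(k)) {
    pts <- loops[[i]]$points
    a <- loops[[i]]$signed_area
    want_ccw <- !is_hole[i] # outer: positive area; hole: negative
    if ((a > 0) != want_ccw) pts <- pts[nrow(pts):1, , drop = FALSE]
    out[[i]] <- list(points = pts, is_hole = is_hole[i], area = abs(a))
  }
  # outer loops first, larger first
  out[order(is_hole, -vapply(out, `[[`, numeric(1), "area"))]
}

#' Signed polygon area (shoelace formula)
#'
#' @param pts Mx2 polygon vertices (closed or open).
#' @return signed area in (u, v) coordinates.
#' @export
shoelace_area <- function(pts) {
  p <- as.matrix(pts)
  if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  u <- p[, 1]; v <- p[, 2]
  un <- c(u[-1], u[1]); vn <- c(v[-1], v[1])
  sum(u * vn - un * v) / 2
}

# even-odd point-in-polygon test for a single point
point_in_polygon <- function(pt, poly) {
  p <- as.matrix(poly)
  if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  crosses <- ((y > pt[2]) != (yn > pt[2])) &
    (pt[1] < x + (pt[2] - y) * (xn - x) / (yn - y))
  (sum(crosses, na.rm = TRUE) %% 2L) == 1L
}

#' A 2D curve fragment
#'
#' @param points Mx2 (u, v) sub-pixel pixel coordinates, ordered.
#' @param view_id,leaf_instance_id,loop_id identity of the fragment (loop 0 is
#'   the outer contour; holes are numbered from 1).
#' @param is_hole whether the fragment comes from a hole contour (hole
#'   fragments only pair with hole fragments across views).
#' @param flag optional character flag (e.g. "short" for a whole contour below
#'   l_min).
#' @return object of class `curve_fragment_2d` with an `arc_length` field.
#' @export
curve_fragment_2d <- function(points, view_id = NA_integer_,
                              leaf_instance_id = NA_integer_,
                              loop_id = 0L, is_hole = FALSE, flag = NULL) {
  pts <- to_matrix2(points)
  stopifnot(nrow(pts) >= 2L)
  structure(
    list(points = pts, view_id = as.integer(view_id),
         leaf_instance_id = as.integer(leaf_instance_id),
         loop_id = as.integer(loop_id), is_hole = isTRUE(is_hole),
         arc_length = polyline_length(pts), flag = flag),
    class = "curve_fragment_2d"
  )
}

#' @export
print.curve_fragment_2d <- function(x, ...) {
  cat(sprintf("<curve_fragment_2d view %s leaf %s loop %s: %d points, %.1f px>\n",
              x$view_id, x$leaf_instance_id, x$loop_id, nrow(x$points),
              x$arc_length))
  invisible(x)
}

#' Total length of a polyline
#' @param pts Mx2 or Mx3 matrix of ordered vertices.
#' @return sum of segment lengths.
#' @export
polyline_length <- function(pts) {
  p <- as.matrix(pts)
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# point at arc-length position s along an open polyline (clamped)
interp_along <- function(pts, cum, s) {
  s <- min(max(s, 0), cum[length(cum)])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(cum) - 1L)
  t <- if (cum[i + 1] > cum[i]) (s - cum[i]) / (cum[i + 1] - cum[i]) else 0
  pts[i, ] + t * (pts[i + 1, ] - pts[i, ])
}

# sub-polyline between arc positions s0 < s1 on a cyclic contour
# (pts closed representation with cum arc positions); wraps modulo perim
cyclic_subcurve <- function(pts, cum, perim, s0, s1) {
  stopifnot(s1 > s0)
  grab <- function(a, b) { # 0 <= a < b <= perim
    p0 <- interp_along(pts, cum, a)
    p1 <- interp_along(pts, cum, b)
    inner <- which(cum > a + 1e-9 & cum < b - 1e-9)
    rbind(p0, pts[inner, , drop = FALSE], p1)
  }
  a <- s0 %% perim
  b <- s1 %% perim
  if (s1 - s0 >= perim - 1e-9) {
    seg <- rbind(grab(a, perim), if (a > 1e-9) grab(0, a))
  } else if (a < b) {
    seg <- grab(a, b)
  } else {
    seg <- rbind(grab(a, perim), grab(0, b))
  }
  keep <- c(TRUE, rowSums(abs(seg[-1, , drop = FALSE] -
                                seg[-nrow(seg), , drop = FALSE])) > 1e-9)
  seg[keep, , drop = FALSE]
}

#' Divide a closed contour into overlapping fragments
#'
#' Greedy cyclic partition: fragments start at arc position 0; each targets
#' length min(l_max, remaining + tau_overlap) (clamped up to l_min for the
#' closing fragment) and the next starts tau_overlap before the previous end,
#' so that every cyclically consecutive pair overlaps by at least tau_overlap
#' px and the union covers the whole contour. A contour no longer than l_max
#' is returned as a single whole-contour fragment; below l_min it is
#' additionally flagged "short".
#'
#' @param contour closed Mx2 (u, v) matrix (first row repeated last), e.g.
#'   from [extract_contours()].
#' @param params a [fragmentation_params()].
#' @param view_id,leaf_instance_id,loop_id identity attached to the fragments.
#' @param is_hole whether the contour is a hole loop.
#' @return list of [curve_fragment_2d()] objects.
#' @export
fragment_contour <- function(contour, params, view_id = NA_integer_,
                             leaf_instance_id = NA_integer_, loop_id = 0L,
                             is_hole = FALSE) {
  pts <- to_matrix2(contour)
  closed <- all(pts[1, ] == pts[nrow(pts), ])
  open_pts <- if (closed) pts[-nrow(pts), , drop = FALSE] else pts
  seglen <- sqrt(rowSums((rbind(open_pts[-1, , drop = FALSE], open_pts[1, , drop = FALSE]) - open_pts)^2))
  perim <- sum(seglen)
  cum <- c(0, cumsum(seglen[-length(seglen)]))
  # closed-polyline representation for arc interpolation
  cpts <- rbind(open_pts, open_pts[1, , drop = FALSE])
  ccum <- c(cum, perim)

  l_min <- params$l_min; l_max <- params$l_max; tau <- params$tau_overlap
  if (perim <= l_max) {
    flag <- if (perim < l_min) "short" else NULL
    return(list(curve_fragment_2d(cpts, view_id, leaf_instance_id, loop_id,
                                  is_hole = is_hole, flag = flag)))
  }
  frags <- list()
  a <- 0
  repeat {
    len <- min(l_max, perim + tau - a)
    len <- max(len, l_min)
    seg <- cyclic_subcurve(cpts, ccum, perim, a, a + len)
    frags[[length(frags) + 1L]] <-
      curve_fragment_2d(seg, view_id, leaf_instance_id, loop_id,
                        is_hole = is_hole)
    if (a + len >= perim + tau - 1e-9) break
    a <- a + len - tau
  }
  frags
}

#' Extract and fragment all contours of an instance
#'
#' @inheritParams extract_contours
#' @inheritParams fragment_contour
#' @return list of [curve_fragment_2d()] across all loops of the instance
#'   (loop 0 = largest outer contour; further loops numbered in the order of
#'   [extract_contours()]).
#' @export
extract_leaf_fragments <- function(mask, instance_id, params,
                                   view_id = NA_integer_) {
  ctrs <- extract_contours(mask, instance_id)
  out <- list()
  for (i in seq_along(ctrs)) {
    out <- c(out, fragment_contour(ctrs[[i]]$points, params,
                                   view_id = view_id,
                                   leaf_instance_id = instance_id,
                                   loop_id = i - 1L,
                                   is_hole = ctrs[[i]]$is_hole))
  }
  out
}
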