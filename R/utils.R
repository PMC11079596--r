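# internal helpers shared across modules

# evaluate expr with a temporarily seeded RNG, restoring the caller's state
with_seed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Resample a polyline at uniform arc-length spacing
#'
#' @param pts Mx2 or Mx3 ordered vertices.
#' @param spacing target spacing between consecutive samples (same units as
#'   `pts`); the actual spacing divides the total length evenly.
#' @return matrix of resampled points (first and last original vertices kept).
#' @export
resample_polyline <- function(pts, spacing) {
  p <- as.matrix(pts)
  if (nrow(p) < 2L) return(p)
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  keep <- c(TRUE, seg > 0)
  p <- p[keep, , drop = FALSE]
  if (nrow(p) < 2L) return(p)
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  n <- max(2L, ceiling(total / spacing) + 1L)
  s <- seq(0, total, length.out = n)
  i <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(p) - 1L)
  t <- (s - cum[i]) / pmax(cum[i + 1L] - cum[i], 1e-300)
  p[i, , drop = FALSE] + (p[i + 1L, , drop = FALSE] - p[i, , drop = FALSE]) * t
}

# rotation about world z axis, degrees
rot_z <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
}

# rotation about world y axis, degrees
rot_y <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
}
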