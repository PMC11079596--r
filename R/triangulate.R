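# Ear-clipping triangulation of a polygon with holes (2D).
#
# Holes are joined to the outer ring by bridge edges (rightmost hole vertex to
# a visible outer vertex), producing a single simple polygon that is then
# ear-clipped. Adequate for the gently star-shaped leaf outlines generated in
# this package; not a general-purpose robust triangulator.

#' Triangulate a polygon with holes
#'
#' @param outer Mx2 matrix, outer ring, counter-clockwise (open or closed).
#' @param holes optional list of Mx2 hole rings, clockwise.
#' @return list with `vertices` (Vx2; outer then hole vertices in input
#'   order) and `faces` (Fx3 integer indices, counter-clockwise).
#' @export
triangulate_polygon <- function(outer, holes = list()) {
  open_ring <- function(p) {
    p <- as.matrix(p)
    if (all(p[1, ] == p[nrow(p), ])) p[-nrow(p), , drop = FALSE] else p
  }
  outer <- open_ring(outer)
  if (shoelace_area(outer) < 0) outer <- outer[nrow(outer):1, , drop = FALSE]
  holes <- lapply(holes, open_ring)
  holes <- lapply(holes, function(h) {
    if (shoelace_area(h) > 0) h[nrow(h):1, , drop = FALSE] else h
  })

  verts <- outer
  for (h in holes) verts <- rbind(verts, h)
  n_out <- nrow(outer)
  ring <- seq_len(n_out) # indices into verts, CCW simple polygon
  offs <- n_out
  # join holes, rightmost first
  if (length(holes) > 0L) {
    hx <- vapply(holes, function(h) max(h[, 1]), numeric(1))
    ord <- order(hx, decreasing = TRUE)
    hole_offsets <- cumsum(c(0, vapply(holes, nrow, integer(1))))[seq_along(holes)] + n_out
    for (hi in ord) {
      h <- holes[[hi]]
      off <- hole_offsets[hi]
      m <- which.max(h[, 1]) # rightmost hole vertex
      M <- h[m, ]
      # ray cast +x from M against current ring edges; nearest crossing
      rp <- verts[ring, , drop = FALSE]
      rq <- rp[c(2:nrow(rp), 1), , drop = FALSE]
      crossing <- ((rp[, 2] > M[2]) != (rq[, 2] > M[2]))
      xc <- rp[, 1] + (M[2] - rp[, 2]) * (rq[, 1] - rp[, 1]) /
        (rq[, 2] - rp[, 2])
      ok <- which(crossing & xc >= M[1] - 1e-12)
      if (length(ok) == 0L) stop("hole cannot be bridged to the outer ring")
      e <- ok[which.min(xc[ok])]
      # bridge target: endpoint of the crossed edge with the larger x
      tgt <- if (rp[e, 1] >= rq[e, 1]) e else (e %% length(ring)) + 1L
      tgt_idx <- ring[tgt]
      # splice: ... tgt, hole(m..), hole(..m), tgt, ...
      hseq <- off + c(m:nrow(h), if (m > 1L) 1:(m - 1L), m)
      pos <- which(ring == tgt_idx)[1]
      ring <- c(ring[seq_len(pos)], hseq, tgt_idx,
                if (pos < length(ring)) ring[(pos + 1L):length(ring)])
    }
  }

  faces <- ear_clip(verts, ring)
  list(vertices = verts, faces = faces)
}

# ear clipping on a simple (possibly bridged) CCW polygon given as vertex
# indices into verts; returns Fx3 index matrix
ear_clip <- function(verts, ring) {
  cross2 <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  faces <- matrix(0L, 0L, 3L)
  idx <- ring
  guard <- 0L
  while (length(idx) > 3L) {
    n <- length(idx)
    clipped <- FALSE
    for (i in seq_len(n)) {
      ip <- idx[if (i == 1L) n else i - 1L]
      iv <- idx[i]
      in_ <- idx[if (i == n) 1L else i + 1L]
      a <- verts[ip, ]; b <- verts[iv, ]; c. <- verts[in_, ]
      cr <- cross2(a, b, c.)
      if (cr <= 1e-12) next # reflex or degenerate corner
      # no other ring vertex strictly inside triangle a-b-c
      others <- setdiff(idx, c(ip, iv, in_))
      if (length(others) > 0L) {
        P <- verts[others, , drop = FALSE]
        s1 <- (b[1] - a[1]) * (P[, 2] - a[2]) - (b[2] - a[2]) * (P[, 1] - a[1])
        s2 <- (c.[1] - b[1]) * (P[, 2] - b[2]) - (c.[2] - b[2]) * (P[, 1] - b[1])
        s3 <- (a[1] - c.[1]) * (P[, 2] - c.[2]) - (a[2] - c.[2]) * (P[, 1] - c.[1])
        eps <- 1e-12
        if (any(s1 > eps & s2 > eps & s3 > eps)) next
      }
      faces <- rbind(faces, c(ip, iv, in_))
      idx <- idx[-i]
      clipped <- TRUE
      break
    }
    if (!clipped) {
      guard <- guard + 1L
      if (guard > 2L) stop("ear clipping failed on a degenerate polygon")
      # relax by removing an exactly-collinear corner
      drop <- NULL
      for (i in seq_along(idx)) {
        n2 <- length(idx)
        a <- verts[idx[if (i == 1L) n2 else i - 1L], ]
        b <- verts[idx[i], ]
        c. <- verts[idx[if (i == n2) 1L else i + 1L], ]
        if (abs(cross2(a, b, c.)) <= 1e-12) { drop <- i; break }
      }
      if (is.null(drop)) stop("ear clipping failed: no ear and no degenerate corner")
      idx <- idx[-drop]
    }
  }
  if (length(idx) == 3L) faces <- rbind(faces, idx)
  storage.mode(faces) <- "integer"
  unname(faces)
}
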