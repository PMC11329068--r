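# 2-D Delaunay triangulation (Bowyer-Watson incremental insertion).
# Written for the scattered topographic interpolation: sensor counts are
# small (tens to low hundreds), so an O(n^2) incremental build is ample.

# signed twice-area; > 0 for counter-clockwise (a, b, c)
orient2d <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}

# TRUE if d lies strictly inside the circumcircle of CCW triangle (a, b, c)
in_circumcircle <- function(a, b, c, d) {
  m <- rbind(
    c(a[1] - d[1], a[2] - d[2], (a[1] - d[1])^2 + (a[2] - d[2])^2),
    c(b[1] - d[1], b[2] - d[2], (b[1] - d[1])^2 + (b[2] - d[2])^2),
    c(c[1] - d[1], c[2] - d[2], (c[1] - d[1])^2 + (c[2] - d[2])^2)
  )
  det(m) > 0
}

#' Delaunay triangulation of planar points
#'
#' @param pts n x 2 coordinate matrix, n >= 3, not all collinear.
#' @return Integer matrix (triangles x 3) of 1-based point indices.
#' @keywords internal
delaunay_triangulate <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points to triangulate")

  span <- max(apply(pts, 2, function(v) diff(range(v))))
  if (span == 0) stop("degenerate point set (all points coincide)")
  ctr <- colMeans(pts)
  big <- 64 * span + 1
  super <- rbind(
    ctr + c(0, big),
    ctr + c(-big, -big),
    ctr + c(big, -big)
  )
  P <- rbind(pts, super)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L

  tris <- list(c(s1, s2, s3))
  for (ip in seq_len(n)) {
    p <- P[ip, ]
    bad <- vapply(tris, function(t) {
      a <- P[t[1], ]; b <- P[t[2], ]; c_ <- P[t[3], ]
      if (orient2d(a, b, c_) < 0) { tmp <- b; b <- c_; c_ <- tmp }
      in_circumcircle(a, b, c_, p)
    }, logical(1))
    if (!any(bad)) {
      # point falls exactly on an existing circumcircle boundary or outside
      # every circle due to ties; nudge membership by nearest triangle
      bad <- seq_along(tris) == which.min(vapply(tris, function(t) {
        sum((colMeans(P[t, , drop = FALSE]) - p)^2)
      }, numeric(1)))
    }
    bad_tris <- tris[bad]
    tris <- tris[!bad]
    # boundary polygon: edges used by exactly one bad triangle
    edges <- do.call(rbind, lapply(bad_tris, function(t) {
      rbind(t[c(1, 2)], t[c(2, 3)], t[c(3, 1)])
    }))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    keep <- !(key %in% key[duplicated(key)])
    for (ei in which(keep)) {
      tris[[length(tris) + 1L]] <- c(edges[ei, 1], edges[ei, 2], ip)
    }
  }

  out <- do.call(rbind, tris)
  out <- out[rowSums(out > n) == 0, , drop = FALSE]
  storage.mode(out) <- "integer"
  if (nrow(out) == 0) stop("triangulation failed (collinear points?)")
  out
}

# barycentric coordinates of point p in triangle (a, b, c); NULL if outside
barycentric <- function(p, a, b, c, tol = 1e-9) {
  detT <- (b[2] - c[2]) * (a[1] - c[1]) + (c[1] - b[1]) * (a[2] - c[2])
  if (abs(detT) < 1e-300) return(NULL)
  w1 <- ((b[2] - c[2]) * (p[1] - c[1]) + (c[1] - b[1]) * (p[2] - c[2])) / detT
  w2 <- ((c[2] - a[2]) * (p[1] - c[1]) + (a[1] - c[1]) * (p[2] - c[2])) / detT
  w3 <- 1 - w1 - w2
  if (w1 < -tol || w2 < -tol || w3 < -tol) return(NULL)
  w <- pmax(c(w1, w2, w3), 0)
  w / sum(w)
}
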