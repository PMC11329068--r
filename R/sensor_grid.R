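#' Project 3-D sensor positions to the plane
#'
#' Azimuthal-equidistant projection about the mean sensor direction: each
#' sensor maps to polar coordinates (angular distance from the projection
#' pole, azimuth in a fixed tangent basis), so the planar radius equals the
#' angular distance exactly and the ordering of angular distances from the
#' pole is preserved. This is the standard projection behind scalp topographic
#' maps.
#'
#' @param positions_3d C x 3 sensor coordinates (any radius; directions used).
#' @return C x 2 matrix of planar coordinates (radians).
#' @export
project_sensors <- function(positions_3d) {
  p <- as.matrix(positions_3d)
  if (nrow(p) < 3) stop("need at least 3 sensors")
  u <- p / sqrt(rowSums(p^2))
  pole <- colMeans(u)
  np <- sqrt(sum(pole^2))
  if (np < 1e-12) stop("degenerate sensor geometry: mean direction undefined")
  pole <- pole / np

  # fixed tangent basis: e1 from the global axis least aligned with the pole
  seed_ax <- diag(3)[, which.min(abs(pole))]
  e1 <- seed_ax - sum(seed_ax * pole) * pole
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    pole[2] * e1[3] - pole[3] * e1[2],
    pole[3] * e1[1] - pole[1] * e1[3],
    pole[1] * e1[2] - pole[2] * e1[1]
  )

  ct <- pmin(1, pmax(-1, u %*% pole))
  theta <- acos(ct)
  phi <- atan2(u %*% e2, u %*% e1)
  out <- cbind(theta * cos(phi), theta * sin(phi))
  if (abs(orient2d(out[1, ], out[2, ], out[3, ])) == 0 && nrow(out) == 3) {
    stop("degenerate sensor geometry: projected sensors are collinear")
  }
  unname(out)
}

#' Topographic grid encoding of a sensor array
#'
#' Precomputes everything needed to interpolate a C-channel topography onto a
#' regular 2-D grid: the planar sensor projection, a Delaunay triangulation of
#' the projected sensors, and per-cell barycentric interpolation weights.
#' Cells outside the sensor convex hull get `fill_value`. Because the weights
#' are fixed, the encoding is a single sparse linear map `values = A y` —
#' linear in the channel vector and exact wherever a grid node coincides with
#' a sensor.
#'
#' @param positions_3d C x 3 sensor coordinates.
#' @param grid_size `c(rows, cols)` of the output matrix. Default 16 x 16.
#' @param fill_value Value assigned to out-of-hull cells (default 0).
#' @return A `grid_encoding`: list with `grid_size`, `planar_coords`, `A`
#'   (cells x C interpolation matrix), `mask` (logical, in-hull cells),
#'   `fill_value`.
#' @export
grid_encoding <- function(positions_3d, grid_size = c(16, 16), fill_value = 0) {
  planar <- project_sensors(positions_3d)
  C <- nrow(planar)
  tri <- delaunay_triangulate(planar)

  rows <- grid_size[1]; cols <- grid_size[2]
  gx <- seq(min(planar[, 1]), max(planar[, 1]), length.out = cols)
  gy <- seq(max(planar[, 2]), min(planar[, 2]), length.out = rows)
  cells <- cbind(rep(gx, each = rows), rep(gy, times = cols)) # column-major grid

  G <- rows * cols
  A <- matrix(0, G, C)
  mask <- logical(G)
  for (g in seq_len(G)) {
    pnt <- cells[g, ]
    for (t in seq_len(nrow(tri))) {
      idx <- tri[t, ]
      w <- barycentric(pnt, planar[idx[1], ], planar[idx[2], ], planar[idx[3], ])
      if (!is.null(w)) {
        A[g, idx] <- w
        mask[g] <- TRUE
        break
      }
    }
  }

  structure(
    list(grid_size = grid_size, planar_coords = planar, triangles = tri,
         A = A, mask = mask, fill_value = fill_value),
    class = "grid_encoding"
  )
}

#' @export
print.grid_encoding <- function(x, ...) {
  cat(sprintf("<grid_encoding> %dx%d grid, %d sensors, %d in-hull cells\n",
              x$grid_size[1], x$grid_size[2], nrow(x$planar_coords), sum(x$mask)))
  invisible(x)
}

#' Encode a channel topography as an input matrix
#'
#' Piecewise-linear scattered interpolation of a channel vector onto the
#' encoding grid (barycentric weights within the Delaunay triangles of the
#' projected sensors); out-of-hull cells take the encoding's fill value.
#'
#' @param y Length-C channel vector (finite).
#' @param enc A [grid_encoding()].
#' @return An `input_matrix`: list with `values` (rows x cols matrix) and the
#'   grid size.
#' @export
encode_topography <- function(y, enc) {
  if (length(y) != ncol(enc$A)) {
    stop(sprintf("channel vector has length %d, encoding expects %d",
                 length(y), ncol(enc$A)))
  }
  if (any(!is.finite(y))) stop("non-finite channel values")
  v <- as.vector(enc$A %*% y)
  v[!enc$mask] <- enc$fill_value
  structure(
    list(values = matrix(v, enc$grid_size[1], enc$grid_size[2]),
         grid_size = enc$grid_size),
    class = "input_matrix"
  )
}
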