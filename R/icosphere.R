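#' Icosphere source space
#'
#' Builds a triangulated sphere by repeated subdivision of a regular
#' icosahedron and uses its vertices as dipole locations. A subdivided
#' icosahedron has \eqn{10 \cdot 4^s + 2} vertices, so `subdivisions = 0, 1, 2`
#' give 12, 42 and 162 dipoles. The icosphere stands in for a cortical source
#' grid at desk scale: it is connected, nearly uniform, and its ring structure
#' around any vertex makes neighborhood-based source patches well defined.
#'
#' @param subdivisions Number of 4-to-1 triangle subdivisions (>= 0).
#' @param radius_m Sphere radius in meters, in (0, 0.12].
#' @param orientation Dipole orientation model: `"radial"` (outward surface
#'   normal) or `"random"` (uniform random unit vectors, seeded by
#'   `orientation_seed`). In a spherical conductor MEG is blind to radial
#'   dipoles, so `"random"` is the choice that lets both modalities carry
#'   information.
#' @param orientation_seed Integer seed used only when `orientation = "random"`.
#'
#' @return A `source_space` object: list with `positions` (N x 3, meters),
#'   `triangles` (T x 3, 1-based vertex indices), `orientations` (N x 3 unit
#'   vectors) and `radius_m`.
#' @examples
#' sp <- make_icosphere_source_space(1, 0.08)
#' nrow(sp$positions) # 42
#' @export
make_icosphere_source_space <- function(subdivisions = 2, radius_m = 0.08,
                                        orientation = c("radial", "random"),
                                        orientation_seed = 1L) {
  orientation <- match.arg(orientation)
  if (subdivisions < 0 || subdivisions != round(subdivisions)) {
    stop("`subdivisions` must be a non-negative integer")
  }
  if (radius_m <= 0 || radius_m > 0.12) {
    stop("`radius_m` must lie in (0, 0.12] meters")
  }

  ico <- icosahedron()
  v <- ico$vertices
  f <- ico$faces
  if (subdivisions > 0) {
    for (i in seq_len(subdivisions)) {
      sub <- subdivide_mesh(v, f)
      v <- sub$vertices
      f <- sub$faces
    }
  }
  # project onto the sphere
  v <- v / sqrt(rowSums(v^2)) * radius_m

  ori <- v / radius_m # outward normals of a sphere are radial
  if (orientation == "random") {
    ori <- withr_seed(orientation_seed, {
      o <- matrix(stats::rnorm(3 * nrow(v)), ncol = 3)
      o / sqrt(rowSums(o^2))
    })
  }

  structure(
    list(positions = v, triangles = f, orientations = ori, radius_m = radius_m),
    class = "source_space"
  )
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf(
    "<source_space> %d dipoles, %d triangles, radius %.3f m\n",
    nrow(x$positions), nrow(x$triangles), x$radius_m
  ))
  invisible(x)
}

# regular icosahedron with unit circumradius
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(vertices = v, faces = f)
}

# one 4-to-1 loop subdivision step (midpoint insertion, no smoothing)
subdivide_mesh <- function(v, f) {
  n <- nrow(v)
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  midpoints <- new.env(hash = TRUE)
  verts <- list(v)
  next_id <- n
  get_mid <- function(a, b) {
    k <- edge_key(a, b)
    id <- midpoints[[k]]
    if (!is.null(id)) return(id)
    next_id <<- next_id + 1L
    verts[[length(verts) + 1L]] <<- (v[a, ] + v[b, ]) / 2
    midpoints[[k]] <- next_id
    next_id
  }
  new_f <- matrix(0L, nrow(f) * 4L, 3L)
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
    ab <- get_mid(a, b); bc <- get_mid(b, c); ca <- get_mid(c, a)
    new_f[(i - 1) * 4 + 1, ] <- c(a, ab, ca)
    new_f[(i - 1) * 4 + 2, ] <- c(b, bc, ab)
    new_f[(i - 1) * 4 + 3, ] <- c(c, ca, bc)
    new_f[(i - 1) * 4 + 4, ] <- c(ab, bc, ca)
  }
  mids <- do.call(rbind, verts[-1])
  list(vertices = rbind(v, mids), faces = new_f)
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
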