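#' Mesh graph, geodesic distances and the topological weight matrix
#'
#' The topological loss and the localization-error metric both live on the
#' source mesh: distances between dipoles are measured along mesh edges
#' (graph geodesics), not through the volume. These helpers build the weighted
#' mesh graph, compute all-pairs shortest paths, and derive the
#' distance-weighted mask used by the topological loss.
#'
#' @name geometry
NULL

#' Build the weighted adjacency graph of a triangulated mesh
#'
#' Vertices are dipole locations; an edge joins two vertices iff they share a
#' triangle edge, weighted by Euclidean length in millimeters. Positions are
#' taken in meters and converted, because localization error is conventionally
#' reported in mm.
#'
#' @param mesh A `source_space`, or any list with `positions` (N x 3, meters)
#'   and `triangles` (T x 3, 1-based indices).
#' @return An `igraph` undirected graph with a `weight` edge attribute (mm).
#' @export
build_mesh_graph <- function(mesh) {
  pos <- mesh$positions
  tri <- mesh$triangles
  n <- nrow(pos)
  if (is.null(pos) || is.null(tri)) stop("mesh must have `positions` and `triangles`")
  if (any(tri < 1L) || any(tri > n)) stop("triangle indices out of range")

  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  w <- sqrt(rowSums((pos[e[, 1], , drop = FALSE] - pos[e[, 2], , drop = FALSE])^2)) * 1000
  if (any(w <= 0)) stop("degenerate mesh edge of zero length")

  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  # vertices never referenced by a triangle are isolated
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- w

  comp <- igraph::components(g)
  if (comp$no > 1L) {
    sizes <- paste(comp$csize, collapse = ", ")
    stop(sprintf(
      "mesh graph is disconnected: %d components of sizes %s", comp$no, sizes
    ))
  }
  g
}

#' All-pairs geodesic distances on the mesh graph
#'
#' Shortest-path lengths between every pair of vertices (Dijkstra), in
#' millimeters. The result is symmetric with a zero diagonal and finite
#' everywhere on a connected mesh.
#'
#' @param graph Weighted `igraph` graph from [build_mesh_graph()].
#' @return N x N numeric matrix of geodesic distances (mm).
#' @export
geodesic_all_pairs <- function(graph) {
  D <- igraph::distances(graph, weights = igraph::E(graph)$weight,
                         algorithm = "dijkstra")
  if (any(!is.finite(D))) stop("graph is disconnected: infinite geodesic distances")
  dimnames(D) <- NULL
  D
}

#' Topological transformation matrix
#'
#' Distance-dependent weights used to mask the outer-product error matrix in
#' the topological loss:
#' \deqn{m_{ij} = 0 \ (i = j);\quad \tanh(\rho d_{ij}) \ (0 < d_{ij} < \tau);\quad 1 \ \text{otherwise},}
#' where \eqn{d_{ij}} is the mesh geodesic distance in mm. Within the
#' neighborhood radius `tau` the penalty grows smoothly with distance; beyond
#' it every mislocalization is penalized fully. `rho` (the kernel width, in
#' (0, 1]) sets how fast the within-neighborhood penalty saturates.
#'
#' @param D Geodesic distance matrix (mm) from [geodesic_all_pairs()].
#' @param rho Kernel width, in (0, 1]. Default 0.005.
#' @param tau Neighborhood radius in mm (> 0). Default 100. The neighborhood
#'   threshold is a free parameter of the loss; 100 mm with the default `rho`
#'   keeps the smooth branch below tanh(0.5) so the saturated branch only
#'   applies to remote region pairs.
#' @return An N x N `topology_matrix` (plain matrix with attributes `rho`,
#'   `tau`); symmetric, zero diagonal, off-diagonal entries in (0, 1].
#' @examples
#' D <- matrix(c(0, 10, 10, 0), 2)
#' topology_matrix(D, rho = 0.005, tau = 100)[1, 2] # tanh(0.05)
#' @export
topology_matrix <- function(D, rho = 0.005, tau = 100) {
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0 || rho > 1) {
    stop("`rho` must be a single value in (0, 1]")
  }
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0) {
    stop("`tau` must be a single positive value (mm)")
  }
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("`D` must be symmetric")
  M <- ifelse(D < tau, tanh(rho * D), 1)
  diag(M) <- 0
  dimnames(M) <- NULL
  structure(M, rho = rho, tau = tau, class = c("topology_matrix", "matrix", "array"))
}

#' Graph-hop rings around a vertex
#'
#' Vertices grouped by unweighted hop distance from `center` on the mesh
#' graph, up to `max_ring`. Ring 0 is the center itself.
#'
#' @param graph Mesh graph.
#' @param center 1-based vertex index.
#' @param max_ring Largest ring order to return.
#' @return List of integer vectors, element `k + 1` holding ring-`k` vertices.
#' @keywords internal
hop_rings <- function(graph, center, max_ring) {
  n <- igraph::vcount(graph)
  if (center < 1 || center > n) stop("`center` out of range")
  hops <- igraph::distances(graph, v = center, weights = NA)[1, ]
  lapply(0:max_ring, function(k) which(hops == k))
}
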