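# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# 42-vertex icosphere with graph and geodesics
tiny_head <- function() {
  memo("tiny_head", function() {
    space <- make_icosphere_source_space(1, 0.08)
    graph <- build_mesh_graph(space)
    list(space = space, graph = graph, D = geodesic_all_pairs(graph))
  })
}

# small simulated dataset on the 42-vertex sphere
tiny_set <- function() {
  memo("tiny_set", function() {
    build_dataset(sim_config(
      subdivisions = 1, n_train = 16, n_test = 6, reps_per_center = 2,
      lns = 1, snr_db = 30, grid_size = c(8, 8), seed = 42
    ))
  })
}

# small network descriptor matching tiny_set
tiny_descriptor <- function(n_out = 42, dilation = 2) {
  fusion_descriptor(grid = c(8, 8), n_out = n_out, conv_filters = c(4, 8),
                    dilation = dilation, reduction = 4, fc_hidden = 24)
}

# independent Floyd-Warshall all-pairs oracle
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  D <- adj
  D[adj == 0] <- Inf
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  D
}

# independent O(n^2) average-precision oracle: precision/recall evaluated by
# direct counting at every distinct threshold
ap_oracle <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels)
  prev_rec <- 0
  ap <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels & sel)
    prec <- tp / sum(sel)
    rec <- tp / npos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# random connected weighted graph as an adjacency matrix (0 = no edge)
random_connected_adj <- function(n, p = 0.3) {
  repeat {
    A <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (stats::runif(1) < p) A[i, j] <- A[j, i] <- stats::runif(1, 0.5, 10)
      }
    }
    # ensure connectivity via a random spanning chain
    ord <- sample(n)
    for (k in seq_len(n - 1)) {
      i <- ord[k]; j <- ord[k + 1]
      if (A[i, j] == 0) A[i, j] <- A[j, i] <- stats::runif(1, 0.5, 10)
    }
    return(A)
  }
}

adj_to_graph <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
  igraph::E(g)$weight <- A[as.matrix(igraph::as_edgelist(g))]
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
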