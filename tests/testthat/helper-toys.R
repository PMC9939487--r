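# Small graph builders used across the test files.

# A straight segment between two points with n samples and constant radius.
straight_segment <- function(id, node_ids, from, to, n = 2, radius = 2) {
  pts <- sapply(seq_len(3), function(k) seq(from[k], to[k], length.out = n))
  if (n == 1) pts <- matrix(pts, ncol = 3)
  vessel_segment(id, node_ids, pts, rep(radius, n))
}

# Nodes data frame from a named list of positions.
make_nodes <- function(pos) {
  data.frame(id = names(pos),
             x = vapply(pos, `[`, numeric(1), 1),
             y = vapply(pos, `[`, numeric(1), 2),
             z = vapply(pos, `[`, numeric(1), 3),
             stringsAsFactors = FALSE)
}

# Chain A --e1-- B --e2-- C ... along x, unit radius, 10 mm per edge.
make_chain <- function(k = 2, step = 10) {
  pos <- lapply(0:k, function(i) c(i * step, 0, 0))
  names(pos) <- LETTERS[seq_len(k + 1)]
  edges <- lapply(seq_len(k), function(i)
    straight_segment(paste0("e", i), c(LETTERS[i], LETTERS[i + 1]),
                     pos[[i]], pos[[i + 1]], n = 5, radius = 1))
  vessel_graph(make_nodes(pos), edges)
}

# Random small multigraph for oracle tests: nodes on [0,100]^3, straight
# edges, random radii; parallel edges allowed.
random_toy_graph <- function(n_nodes, n_edges) {
  pos <- lapply(seq_len(n_nodes), function(i) stats::runif(3, 0, 100))
  names(pos) <- sprintf("v%02d", seq_len(n_nodes))
  edges <- list()
  k <- 0
  while (k < n_edges) {
    ab <- sample(n_nodes, 2)
    k <- k + 1
    edges[[k]] <- straight_segment(sprintf("e%02d", k),
                                   names(pos)[ab], pos[[ab[1]]], pos[[ab[2]]],
                                   n = 4, radius = stats::runif(1, 1, 4))
  }
  vessel_graph(make_nodes(pos), edges)
}
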