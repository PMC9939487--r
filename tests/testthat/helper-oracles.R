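# Independent oracles used to cross-check the package's recursive scoring.

# Exhaustive path-score oracle: enumerate ALL maximal edge-simple candidate
# paths starting at (edge, node), score each path as a whole (fold-right sum
# of edge costs under the accumulated weight sequence), and take the maximum.
# Shares only the edge-cost and transition-weight primitives with the
# implementation; the maximization structure is entirely different.
enumerate_path_score <- function(graph, edge_id, node_id, candidate,
                                 params = cow_params()) {
  paths <- list()
  walk <- function(eid, vid, avail, acc) {
    e <- graph$edges[[eid]]
    far <- if (e$nodes[1] == vid) e$nodes[2] else e$nodes[1]
    nb <- intersect(neighbor_edges(graph, e, vid), setdiff(avail, eid))
    if (length(nb) == 0) {
      paths[[length(paths) + 1L]] <<- c(acc, eid)
      return(invisible(NULL))
    }
    for (f in nb) walk(f, far, setdiff(avail, eid), c(acc, eid))
  }
  walk(edge_id, node_id, candidate$edges, character(0))
  best <- -Inf
  best_path <- NULL
  for (p in paths) {
    # accumulated weight sequence along the path
    w <- 1
    vid <- node_id
    costs <- numeric(length(p))
    for (i in seq_along(p)) {
      e <- graph$edges[[p[i]]]
      if (i > 1) {
        w <- c(w, transition_weight(graph, graph$edges[[p[i - 1]]], e, vid,
                                    params))
      }
      costs[i] <- edge_cost(e, w, candidate$scores[[p[i]]], params)
      vid <- if (e$nodes[1] == vid) e$nodes[2] else e$nodes[1]
    }
    total <- costs[length(costs)]
    for (i in rev(seq_len(length(costs) - 1))) total <- costs[i] + total
    if (total > best) { best <- total; best_path <- p }
  }
  list(score = best, path = best_path, n_paths = length(paths))
}

# A random candidate set over a toy graph: all edges, with random finite
# distance scores.
random_candidate <- function(graph) {
  ids <- names(graph$edges)
  list(artery = "ICA_L", edges = sort(ids),
       scores = stats::setNames(stats::runif(length(ids), 0.5, 19.5), ids))
}

# Brute-force double loop for the landmark distance score (points x
# landmarks), mirroring the omission rule and support requirement.
brute_distance_score <- function(points, landmarks) {
  N <- nrow(points); M <- nrow(landmarks)
  s <- numeric(0)
  for (n in seq_len(N)) {
    d <- apply(landmarks, 1, function(l) sqrt(sum((points[n, ] - l)^2)))
    if (which.min(d) %in% c(1L, M)) next
    s <- c(s, min(d))
  }
  if (length(s) < max(2, ceiling(0.1 * N))) return(Inf)
  mean(s) + sqrt(mean((s - min(s))^2))
}
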