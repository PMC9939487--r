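#' Edge cost along a scored vessel path
#'
#' The score contribution of one edge inside a path, given the transition
#' weights accumulated so far (the sequence always starts with 1):
#'
#' `c_a(e, w) = (w_N + prod(w)) / 2 * l_e / d_a(e) * (1 + delta * r_e)`
#'
#' where `w_N` is the last weight, the product runs over the whole sequence,
#' `l_e` is the edge's arc length, `d_a(e)` its landmark distance score and
#' `r_e` its mean radius.  Long, close, smooth and (mildly, `delta` = 0.1)
#' thick edges score high.  A distance score of zero is floored at
#' `params$distance_floor` (0.1 mm): sub-resolution distances are
#' geometrically meaningless and would otherwise divide by zero.
#'
#' @param edge A vessel segment.
#' @param weights Numeric vector of accumulated transition weights, first
#'   element 1.
#' @param score The edge's distance score `d_a(e)` (mm), finite and from the
#'   artery's candidate set.
#' @param params A [cow_params()].
#' @return Non-negative cost (dimensionless).
#' @export
edge_cost <- function(edge, weights, score, params = cow_params()) {
  if (length(weights) == 0) stop("weight sequence must be non-empty")
  if (!is.finite(score)) stop("infinite distance score: edge '", edge$id,
                              "' is not in the candidate set")
  d <- max(score, params$distance_floor)
  wN <- weights[length(weights)]
  (wN + prod(weights)) / 2 * (edge$length / d) * (1 + params$delta * edge$mean_radius)
}

#' Maximum recursive path score from a node and edge
#'
#' Scores the best vessel path for one artery starting at `node` and walking
#' away through `edge`, restricted to the artery's candidate edge set.  The
#' score of a path is the sum of its edge costs, where each edge's cost uses
#' the transition weights accumulated from the start of the path (see
#' [edge_cost()]).  Recursively: the value at `(edge, node)` is the edge's
#' cost, plus -- whenever any neighboring edge across `edge` is still in the
#' candidate set -- the maximum value over those neighbors, with `edge`
#' removed from the set along that branch.  The removal makes every explored
#' path edge-simple; since all costs are positive the maximum is attained on
#' a maximal (non-extendable) path.
#'
#' @param graph A [vessel_graph()].
#' @param edge Starting edge (object or id); must be in the candidate set.
#' @param node Node id at which the path starts; an endpoint of `edge`.
#' @param candidate One artery's candidate set from [build_candidates()].
#' @param weights Accumulated weight sequence; the initial call uses `c(1)`.
#' @param params A [cow_params()]; `max_path_edges` guards the recursion
#'   depth against pathological loop graphs.
#' @return A list with `score` and `path` (ordered character edge ids).
#' @export
path_score <- function(graph, edge, node, candidate, weights = 1,
                       params = cow_params()) {
  eid <- if (is.character(edge)) edge else edge$id
  if (!(eid %in% candidate$edges))
    stop("edge '", eid, "' is not in the candidate set of ", candidate$artery)
  rec <- function(eid, vid, avail, w, depth) {
    if (depth > params$max_path_edges)
      stop("path recursion exceeded ", params$max_path_edges,
           " edges; pathological loop graph?")
    e <- graph$edges[[eid]]
    cost <- edge_cost(e, w, candidate$scores[[eid]], params)
    vtil <- other_node(e, vid)
    nb <- intersect(neighbor_edges(graph, e, vid), setdiff(avail, eid))
    if (length(nb) == 0) return(list(score = cost, path = eid))
    best <- NULL
    for (f in nb) {
      wf <- transition_weight(graph, e, graph$edges[[f]], vtil, params)
      sub <- rec(f, vtil, setdiff(avail, eid), c(w, wf), depth + 1L)
      if (is.null(best) || sub$score > best$score) best <- sub
    }
    list(score = cost + best$score, path = c(eid, best$path))
  }
  rec(eid, if (is.list(node)) node$id else as.character(node),
      candidate$edges, weights, 1L)
}

# Ordered injective assignments of k = min(3, length(edges)) distinct edges
# to k of the 3 arteries.  Returns a list of length-3 character vectors (NA =
# artery unassigned); supports occluded vessels via degree-1/2 nodes.
enumerate_configs <- function(edges) {
  k <- min(3L, length(edges))
  if (k == 0L) return(list())
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  configs <- list()
  slots <- utils::combn(3L, k)
  edge_choices <- if (k == length(edges)) list(edges)
                  else utils::combn(edges, k, simplify = FALSE)
  for (j in seq_len(ncol(slots)))
    for (ec in edge_choices)
      for (p in perms(ec)) {
        cfg <- rep(NA_character_, 3L)
        cfg[slots[, j]] <- p
        configs <- c(configs, list(cfg))
      }
  configs
}

#' Match one bifurcation to its optimal graph node
#'
#' For every candidate node (see [candidate_bifurcation_nodes()]), all
#' injective assignments of distinct incident edges to the bifurcation's
#' three adjacent arteries are enumerated -- 6 configurations for a degree-3
#' node -- and each assigned artery is scored with [path_score()] starting at
#' the node (an edge outside that artery's candidate set scores 0).  At
#' nodes of degree below 3, configurations leave the surplus arteries
#' unassigned with score 0, so a bifurcation can still be matched when a
#' vessel is missing, e.g. occluded by stroke.  The configuration score is
#' the mean of the three artery scores; the node with the maximal score wins
#' (ties: smallest node id, then lexicographic edge tuple).
#'
#' @param graph A [vessel_graph()].
#' @param atlas Aligned [landmark_atlas()].
#' @param bifurcation Bifurcation id.
#' @param candidates Output of [build_candidates()].
#' @param params A [cow_params()].
#' @return An object of class `bifurcation_match`: list with `bifurcation`,
#'   `matched` (logical), `node`, `artery_paths` (named list of ordered edge
#'   ids, possibly empty), `artery_scores`, `mean_score`, and `runner_up`
#'   (same shape for the second-best node, or `NULL`).  When no candidate
#'   node or only zero-score configurations exist the match is unmatched --
#'   a legal outcome, not an error.
#' @export
match_bifurcation <- function(graph, atlas, bifurcation, candidates,
                              params = cow_params()) {
  arts <- cow_bifurcations()[[bifurcation]]
  if (is.null(arts)) stop("unknown bifurcation id: ", bifurcation)
  nodes <- candidate_bifurcation_nodes(graph, atlas, bifurcation,
                                       params$node_radius)
  unmatched <- structure(list(bifurcation = bifurcation, matched = FALSE,
                              node = NA_character_,
                              artery_paths = stats::setNames(
                                rep(list(character(0)), 3), arts),
                              artery_scores = stats::setNames(numeric(3), arts),
                              mean_score = 0, runner_up = NULL),
                         class = "bifurcation_match")
  if (length(nodes) == 0) return(unmatched)

  eval_node <- function(v) {
    inc <- sort(incident_edges(graph, v))
    cache <- new.env(parent = emptyenv())
    score_one <- function(a, eid) {
      key <- paste(a, eid)
      if (!is.null(cache[[key]])) return(cache[[key]])
      res <- if (eid %in% candidates[[a]]$edges)
        path_score(graph, eid, v, candidates[[a]], 1, params)
      else list(score = 0, path = character(0))
      cache[[key]] <- res
      res
    }
    best <- NULL
    for (cfg in enumerate_configs(inc)) {
      scored <- lapply(seq_len(3), function(i) {
        if (is.na(cfg[i])) list(score = 0, path = character(0))
        else score_one(arts[i], cfg[i])
      })
      total <- mean(vapply(scored, `[[`, numeric(1), "score"))
      key <- paste(ifelse(is.na(cfg), "", cfg), collapse = "\r")
      if (is.null(best) || total > best$mean_score ||
          (total == best$mean_score && key < best$key)) {
        best <- list(mean_score = total, key = key,
                     paths = stats::setNames(lapply(scored, `[[`, "path"), arts),
                     scores = stats::setNames(
                       vapply(scored, `[[`, numeric(1), "score"), arts))
      }
    }
    best
  }

  per_node <- lapply(nodes, eval_node)
  ok <- !vapply(per_node, is.null, logical(1))
  nodes <- nodes[ok]; per_node <- per_node[ok]
  if (length(nodes) == 0) return(unmatched)
  means <- vapply(per_node, `[[`, numeric(1), "mean_score")
  # ties: smallest node id (nodes are pre-sorted, which.max takes the first)
  ord <- order(-means, nodes)
  if (means[ord[1]] <= 0) return(unmatched)
  mk <- function(i) structure(
    list(bifurcation = bifurcation, matched = TRUE, node = nodes[i],
         artery_paths = per_node[[i]]$paths,
         artery_scores = per_node[[i]]$scores,
         mean_score = per_node[[i]]$mean_score, runner_up = NULL),
    class = "bifurcation_match")
  m <- mk(ord[1])
  if (length(nodes) >= 2 && means[ord[2]] > 0) m$runner_up <- mk(ord[2])
  m
}
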