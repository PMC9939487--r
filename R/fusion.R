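#' Merge an inner artery covered by two bifurcation matches
#'
#' Inner arteries (AComm, ACA 1 left/right, A. basilaris) border two labeled
#' bifurcations and are therefore found twice, once per adjacent match.  The
#' two candidate paths are merged according to their overlap: when they share
#' edges, the merged artery is the shortest (arc-length) path between the two
#' bifurcation nodes restricted to the union of the two edge lists; when they
#' are disjoint, the global graph shortest path between the two paths' far
#' endpoints is inserted as a connector and the merged artery is the
#' resulting node-to-node path.  When either bifurcation is unmatched (or its
#' path empty) the other path is returned unchanged.
#'
#' @param matchA,matchB The two `bifurcation_match` objects adjacent to the
#'   artery.
#' @param artery An inner artery id present in both matches.
#' @param graph A [vessel_graph()].
#' @return Ordered character vector of edge ids, running from `matchA`'s node
#'   to `matchB`'s.  When no connecting path exists the two partial paths are
#'   concatenated and the result carries `attr(, "interrupted") = TRUE` -- the
#'   stroke case, a legal outcome.
#' @export
merge_inner <- function(matchA, matchB, artery, graph) {
  pathA <- if (isTRUE(matchA$matched)) matchA$artery_paths[[artery]] else character(0)
  pathB <- if (isTRUE(matchB$matched)) matchB$artery_paths[[artery]] else character(0)
  # one-sided recovery: when the other bifurcation is matched but contributed
  # no path, the artery's connection to it was not found -> interrupted
  if (length(pathA) == 0)
    return(if (isTRUE(matchA$matched) && length(pathB) > 0)
             structure(pathB, interrupted = TRUE) else pathB)
  if (length(pathB) == 0)
    return(if (isTRUE(matchB$matched)) structure(pathA, interrupted = TRUE)
           else pathA)
  pool <- union(pathA, pathB)
  if (length(intersect(pathA, pathB)) == 0) {
    # disjoint: bridge the far endpoints through the whole graph
    farA <- utils::tail(path_nodes(graph, pathA, matchA$node), 1)
    farB <- utils::tail(path_nodes(graph, pathB, matchB$node), 1)
    bridge <- shortest_edge_path(graph, farA, farB)
    if (is.null(bridge))
      return(structure(c(pathA, pathB), interrupted = TRUE))
    pool <- union(pool, bridge)
  }
  merged <- shortest_edge_path(graph, matchA$node, matchB$node, pool)
  if (is.null(merged))
    return(structure(c(pathA, pathB), interrupted = TRUE))
  merged
}

#' Extend an outer or incoming artery past its landmarks
#'
#' Outgoing and incoming vessels often extend beyond the landmark coverage,
#' so after fusion their paths are traced onward from the free end: the
#' incident unlabeled edge with the largest transition weight is appended,
#' repeatedly, as long as the best transition angle exceeds 120 degrees
#' (direction dot product above 0.5, i.e. weight above 0.8 under the default
#' weight map).  Tracing stops at sharp turns, at already-labeled edges and
#' never revisits an edge, so the input path is always a prefix of the
#' result.
#'
#' @param graph A [vessel_graph()].
#' @param path Non-empty ordered edge-id vector, starting at the artery's
#'   bifurcation node.
#' @param start_node Node id of the bifurcation end of `path`.
#' @param labeled Character vector of edge ids already claimed by any artery.
#' @param params A [cow_params()].
#' @return The extended ordered edge-id vector.
#' @export
trace_outer <- function(graph, path, start_node, labeled = character(0),
                        params = cow_params()) {
  if (length(path) == 0) return(path)
  wt_min <- (1 + params$weight_floor) / 2 +
    (1 - params$weight_floor) / 2 * params$trace_min_dot
  free <- utils::tail(path_nodes(graph, path, start_node), 1)
  repeat {
    last <- graph$edges[[path[length(path)]]]
    cand <- setdiff(sort(incident_edges(graph, free)), c(path, labeled))
    if (length(cand) == 0) break
    w <- vapply(cand, function(f)
      transition_weight(graph, last, graph$edges[[f]], free, params), numeric(1))
    if (max(w) <= wt_min) break
    nxt <- cand[which.max(w)]
    path <- c(path, nxt)
    free <- other_node(graph$edges[[nxt]], free)
  }
  path
}

#' Resolve a double assignment of the two anterior bifurcations
#'
#' The two ACA 2 segments are similar, so the left and right anterior
#' bifurcations may be matched onto the same node.  A true double assignment
#' would mean only a single ACA 2 exists (a known variant of the Circle of
#' Willis).  To distinguish the cases, the runner-up node of the lower-scored
#' match is consulted: if its score reaches 80% of that match's best score,
#' two ACA 2s are assumed and the lower match is reassigned to its runner-up
#' node; otherwise the single-ACA 2 interpretation is kept and the lower
#' bifurcation is reported unmatched.
#'
#' @param matchL,matchR The ACA_L and ACA_R `bifurcation_match` objects.
#' @param params A [cow_params()] (supplies `anterior_ratio`).
#' @return List of the two (possibly modified) matches, left then right.
#' @export
resolve_anterior <- function(matchL, matchR, params = cow_params()) {
  if (!isTRUE(matchL$matched) || !isTRUE(matchR$matched) ||
      !identical(matchL$node, matchR$node))
    return(list(matchL, matchR))
  lower_is_left <- matchL$mean_score <= matchR$mean_score
  lower <- if (lower_is_left) matchL else matchR
  ru <- lower$runner_up
  if (!is.null(ru) && ru$mean_score >= params$anterior_ratio * lower$mean_score) {
    lower <- ru
  } else {
    lower$matched <- FALSE
    lower$node <- NA_character_
    lower$artery_paths <- lapply(lower$artery_paths, function(x) character(0))
    lower$artery_scores[] <- 0
    lower$mean_score <- 0
  }
  lower$runner_up <- NULL
  if (lower_is_left) list(lower, matchR) else list(matchL, lower)
}

# Inner arteries and the two bifurcation matches each is merged from.
inner_merge_plan <- function() {
  list(BASILAR = c("VERTEBRAL", "POSTERIOR"),
       ACA1_L  = c("MEDIA_L", "ACA_L"),
       ACA1_R  = c("MEDIA_R", "ACA_R"),
       ACOMM   = c("ACA_L", "ACA_R"))
}

#' Fuse six bifurcation matches into one labeling
#'
#' Applies the anterior double-assignment resolution, merges the four inner
#' arteries from their two adjacent matches, copies the outer and incoming
#' artery paths from their single match, and finally traces outer/incoming
#' ends onward through smooth unlabeled continuations.  Every edge carries at
#' most one artery label; when two paths claim the same edge the artery
#' processed earlier wins and the later path is truncated at the collision
#' (inner arteries are claimed first, then outer/incoming in descending
#' order of their bifurcation's mean score).
#'
#' @param matches Named list of the six `bifurcation_match` objects, keyed by
#'   bifurcation id (unmatched entries allowed).
#' @param graph A [vessel_graph()].
#' @param params A [cow_params()].
#' @return A `cow_labeling`: list with `assignments` (named list artery ->
#'   ordered edge ids, empty = not found), `bifurcation_nodes` (named
#'   character, `NA` = unmatched) and `provenance` (named character:
#'   `"matching"`, `"merging"`, `"tracing"`, `"interrupted"` or `"absent"`).
#' @export
fuse_matches <- function(matches, graph, params = cow_params()) {
  bifs <- names(cow_bifurcations())
  for (b in setdiff(bifs, names(matches)))
    matches[[b]] <- structure(list(bifurcation = b, matched = FALSE,
                                   node = NA_character_,
                                   artery_paths = list(),
                                   artery_scores = numeric(0),
                                   mean_score = 0, runner_up = NULL),
                              class = "bifurcation_match")
  ant <- resolve_anterior(matches$ACA_L, matches$ACA_R, params)
  matches$ACA_L <- ant[[1]]; matches$ACA_R <- ant[[2]]

  arteries <- cow_arteries()
  assignments <- stats::setNames(rep(list(character(0)), nrow(arteries)),
                                 arteries$artery)
  provenance <- stats::setNames(rep("absent", nrow(arteries)), arteries$artery)
  labeled <- character(0)  # edge id -> artery

  claim <- function(artery, path) {
    kept <- character(0)
    for (eid in path) {
      if (eid %in% names(labeled)) break  # collision: truncate
      kept <- c(kept, eid)
    }
    labeled[kept] <<- artery
    assignments[[artery]] <<- kept
    attr(kept, "cut") <- length(kept) < length(path)
    kept
  }

  for (a in names(inner_merge_plan())) {
    pair <- inner_merge_plan()[[a]]
    merged <- merge_inner(matches[[pair[1]]], matches[[pair[2]]], a, graph)
    kept <- claim(a, merged)
    if (length(kept) > 0)
      provenance[a] <- if (isTRUE(attr(merged, "interrupted")) ||
                           isTRUE(attr(kept, "cut"))) "interrupted"
                       else "merging"
  }

  ends <- cow_artery_ends()
  outer <- arteries$artery[arteries$role != "inner"]
  home_bif <- vapply(outer, function(a) ends[[a]][1], character(1))
  scores <- vapply(outer, function(a) matches[[home_bif[a]]]$mean_score, numeric(1))
  for (a in outer[order(-scores, outer)]) {
    m <- matches[[home_bif[a]]]
    if (!isTRUE(m$matched)) next
    kept <- claim(a, m$artery_paths[[a]])
    if (length(kept) > 0)
      provenance[a] <- if (isTRUE(attr(kept, "cut"))) "interrupted" else "matching"
  }

  # tracing sees the final label map and stops at labeled edges
  for (a in outer) {
    path <- assignments[[a]]
    if (length(path) == 0) next
    node <- matches[[home_bif[a]]]$node
    ext <- trace_outer(graph, path, node, setdiff(names(labeled), path), params)
    added <- setdiff(ext, path)
    if (length(added) > 0) {
      labeled[added] <- a
      assignments[[a]] <- ext
      provenance[a] <- "tracing"
    }
  }

  structure(list(
    assignments = assignments,
    bifurcation_nodes = stats::setNames(
      vapply(bifs, function(b) matches[[b]]$node, character(1)), bifs),
    provenance = provenance
  ), class = "cow_labeling")
}

#' Check the structural invariants of a labeling
#'
#' Verifies that no edge carries two artery labels and that every matched
#' bifurcation's non-empty artery paths terminate at its node (arteries
#' whose provenance is `interrupted` or `variant` are exempt: a stroke may
#' disconnect them, and a fetal-origin PCA never reaches the posterior
#' bifurcation).
#'
#' @param labeling A `cow_labeling`.
#' @param graph The [vessel_graph()] it refers to.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_labeling <- function(labeling, graph) {
  all_edges <- unlist(labeling$assignments, use.names = FALSE)
  if (anyDuplicated(all_edges))
    stop("labeling invariant violated: edge '",
         all_edges[duplicated(all_edges)][1], "' carries two artery labels")
  bifs <- cow_bifurcations()
  for (b in names(bifs)) {
    v <- labeling$bifurcation_nodes[[b]]
    if (is.na(v)) next
    for (a in bifs[[b]]) {
      path <- labeling$assignments[[a]]
      if (length(path) == 0) next
      if (!is.null(labeling$provenance) &&
          labeling$provenance[[a]] %in% c("interrupted", "variant")) next
      # a path may also pass through the node mid-way after tracing/merging
      nds <- path_nodes(graph, path, v)
      if (!(v %in% nds))
        stop("labeling invariant violated: path of ", a,
             " does not touch bifurcation node '", v, "' (", b, ")")
    }
  }
  invisible(TRUE)
}

#' Read and write labelings as JSON
#'
#' Dialect: `{"arteries": {artery: [edge ids]}, "bifurcations":
#' {bifurcation: node id or null}}`.
#'
#' @param labeling A `cow_labeling`.
#' @param path File path.
#' @export
write_labeling <- function(labeling, path) {
  bn <- as.list(labeling$bifurcation_nodes)
  bn <- lapply(bn, function(x) if (is.na(x)) NULL else x)
  jsonlite::write_json(list(arteries = lapply(labeling$assignments, as.list),
                            bifurcations = bn),
                       path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_labeling
#' @export
read_labeling <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  assignments <- lapply(obj$arteries, function(x) as.character(unlist(x)))
  assignments <- lapply(assignments, function(x) if (length(x)) x else character(0))
  bn <- vapply(obj$bifurcations, function(x)
    if (is.null(x)) NA_character_ else as.character(x), character(1))
  structure(list(assignments = assignments, bifurcation_nodes = bn,
                 provenance = NULL), class = "cow_labeling")
}
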