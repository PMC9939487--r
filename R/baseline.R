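#' Distance-driven baseline: greedy radius-ordered assignment
#'
#' A deliberately simple reference labeler sharing the registration and the
#' landmark distance score with the main method.  Edges are sorted by
#' descending mean radius and processed in sweeps: an edge is assigned to its
#' *closest* artery landmark set (argmin of the distance score) if that score
#' is below `threshold` and one of its neighboring edges is already in the
#' same set; the first edge of each artery set is exempt from the neighbor
#' condition, so every artery can seed.  Sweeps repeat until no assignment
#' changes.
#'
#' @param graph A [vessel_graph()].
#' @param atlas Aligned [landmark_atlas()] (same ICP as the main method).
#' @param threshold Assignment cutoff, mm (default 20, as for the candidate
#'   graphs).
#' @return Named list mapping artery ids to character vectors of edge ids.
#' @export
baseline_assign <- function(graph, atlas, threshold = 20) {
  arts <- names(atlas$sets)
  assigned <- stats::setNames(rep(list(character(0)), length(arts)), arts)
  if (length(graph$edges) == 0) return(assigned)
  scores <- vapply(arts, function(a)
    vapply(graph$edges, function(e) distance_score(e, atlas$sets[[a]])$value,
           numeric(1)),
    numeric(length(graph$edges)))
  if (is.null(dim(scores)))
    scores <- matrix(scores, nrow = 1, dimnames = list(names(graph$edges), arts))
  radii <- vapply(graph$edges, function(e) e$mean_radius, numeric(1))
  order_ids <- names(graph$edges)[order(-radii, names(graph$edges))]
  owner <- character(0)  # edge id -> artery
  repeat {
    changed <- FALSE
    for (eid in order_ids) {
      if (eid %in% names(owner)) next
      row <- stats::setNames(as.numeric(scores[eid, , drop = FALSE]), arts)
      if (all(!is.finite(row))) next
      a <- arts[which.min(row)]
      if (!(row[a] < threshold)) next
      nb <- unique(unlist(lapply(graph$edges[[eid]]$nodes,
                                 function(v) incident_edges(graph, v))))
      nb <- setdiff(nb, eid)
      ok <- length(assigned[[a]]) == 0 || any(nb %in% assigned[[a]])
      if (ok) {
        assigned[[a]] <- c(assigned[[a]], eid)
        owner[eid] <- a
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  assigned
}

#' Distance-driven baseline: longest-shortest-path extraction
#'
#' Within each artery's assigned edge set, all-pairs shortest (arc-length)
#' paths are computed on the induced sub-graph and the longest of them is
#' taken as the artery's path, which avoids branching.  Bifurcation nodes
#' are not enforced: a baseline bifurcation is reported only where the three
#' adjacent artery paths happen to share an endpoint node.
#'
#' @param assigned Output of [baseline_assign()].
#' @param graph A [vessel_graph()].
#' @return A `cow_labeling` (provenance `"baseline"` for found arteries).
#' @export
baseline_extract <- function(assigned, graph) {
  arteries <- cow_arteries()$artery
  assignments <- stats::setNames(rep(list(character(0)), length(arteries)),
                                 arteries)
  provenance <- stats::setNames(rep("absent", length(arteries)), arteries)
  for (a in intersect(arteries, names(assigned))) {
    eids <- assigned[[a]]
    if (length(eids) == 0) next
    g <- as_igraph(graph, eids)
    D <- igraph::distances(g)
    D[!is.finite(D)] <- -Inf
    best <- which(D == max(D), arr.ind = TRUE)
    vn <- igraph::V(g)$name
    # deterministic endpoint pair: smallest node-id pair lexicographically
    pairs <- cbind(vn[best[, 1]], vn[best[, 2]])
    key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    pick <- order(key)[1]
    from <- pairs[pick, 1]; to <- pairs[pick, 2]
    path <- if (identical(from, to)) eids[1]
            else shortest_edge_path(graph, from, to, eids)
    assignments[[a]] <- path
    provenance[a] <- "baseline"
  }
  bifs <- cow_bifurcations()
  bn <- stats::setNames(rep(NA_character_, length(bifs)), names(bifs))
  for (b in names(bifs)) {
    ends <- lapply(bifs[[b]], function(a) {
      p <- assignments[[a]]
      if (length(p) == 0) NULL
      else {
        nds <- path_nodes(graph, p)
        c(nds[1], utils::tail(nds, 1))
      }
    })
    if (any(vapply(ends, is.null, logical(1)))) next
    common <- Reduce(intersect, ends)
    if (length(common) == 1) bn[b] <- common
  }
  structure(list(assignments = assignments, bifurcation_nodes = bn,
                 provenance = provenance), class = "cow_labeling")
}

#' @rdname baseline_assign
#' @param params A [cow_params()] (supplies the threshold and ICP settings).
#' @return `baseline_label()` runs ICP, assignment and extraction end to end
#'   and returns a `cow_labeling`.
#' @export
baseline_label <- function(graph, atlas, params = cow_params()) {
  ali <- icp_align(atlas, graph, params$icp_max_iter, params$icp_tol)
  assigned <- baseline_assign(graph, ali$atlas, params$candidate_threshold)
  baseline_extract(assigned, graph)
}
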