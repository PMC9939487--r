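#' Landmark distance score of a vessel segment
#'
#' For every centerline point of the segment, the Euclidean distance `s_n` to
#' the closest landmark of the artery's set is computed.  Points whose
#' closest landmark is one of the two *end* landmarks (first or last of the
#' ordered set) are omitted from the score: they lie beyond the artery's
#' anatomical extent and should not be penalized.  The score is
#'
#' `d_a(e) = mean(s) + sqrt(mean((s - min(s))^2))`
#'
#' over the retained points.  The second term is a spread measure around the
#' *minimum* (not the mean): it penalizes segments running perpendicular to
#' the landmark array, whose point distances fan out from a single close
#' approach, while a segment parallel to the landmarks has nearly constant
#' `s_n` and no spread penalty.  If every point is omitted the score is
#' `Inf`, which excludes the edge from all candidate sets.
#'
#' @param edge A vessel segment.
#' @param landmarks Numeric M x 3 landmark matrix (ordered; M >= 2) or a
#'   single artery's set from a [landmark_atlas()].
#' @return A list with `value` (mm), `s` (retained per-point distances) and
#'   `retained` (logical per centerline point).
#' @export
distance_score <- function(edge, landmarks) {
  L <- as.matrix(landmarks)
  if (nrow(L) == 0) stop("empty landmark set")
  P <- edge$points
  D2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)
  D2[D2 < 0] <- 0
  nn <- max.col(-D2, ties.method = "first")
  s_all <- sqrt(D2[cbind(seq_len(nrow(P)), nn)])
  retained <- !(nn %in% c(1L, nrow(L)))
  s <- s_all[retained]
  # Support requirement: a score carried by almost no retained points is
  # geometrically meaningless (and with a single point the spread term is
  # identically zero), so such edges are excluded via the Inf sentinel.
  value <- if (length(s) < max(2, ceiling(0.1 * nrow(P)))) Inf
           else mean(s) + sqrt(mean((s - min(s))^2))
  list(value = value, s = s, retained = retained)
}

#' Per-artery candidate sub-graphs
#'
#' Scores every edge of the graph against every artery's landmark set and
#' keeps, per artery, exactly the edges whose distance score is strictly
#' below `threshold`.  The threshold (2 cm by default) bounds the search
#' space of the bifurcation matcher while absorbing residual registration
#' error; candidate graphs of different arteries may overlap, and an empty
#' candidate graph is legal (possibly a missing artery).
#'
#' @param graph A [vessel_graph()].
#' @param atlas An aligned [landmark_atlas()] (post [icp_align()]).
#' @param threshold Inclusion cutoff, mm.
#' @return Named list (by artery) of lists with `artery`, `edges` (character
#'   edge ids) and `scores` (named numeric distance scores for all graph
#'   edges, `Inf` where fully omitted).
#' @export
build_candidates <- function(graph, atlas, threshold = 20) {
  out <- list()
  for (a in names(atlas$sets)) {
    L <- atlas$sets[[a]]
    vals <- vapply(graph$edges, function(e) distance_score(e, L)$value,
                   numeric(1))
    if (length(vals) == 0) vals <- stats::setNames(numeric(0), character(0))
    out[[a]] <- list(artery = a,
                     edges = sort(names(vals)[is.finite(vals) & vals < threshold]),
                     scores = vals)
  }
  out
}

#' Candidate bifurcation nodes
#'
#' Graph nodes within `radius` (1.5 cm by default) of at least one of the
#' three bifurcation-end landmarks of the bifurcation's adjacent arteries.
#'
#' @param graph A [vessel_graph()].
#' @param atlas An aligned [landmark_atlas()].
#' @param bifurcation Bifurcation id (see [cow_bifurcations()]).
#' @param radius Search radius, mm.
#' @return Sorted character vector of node ids (possibly empty; an empty set
#'   leaves the bifurcation unmatched downstream).
#' @export
candidate_bifurcation_nodes <- function(graph, atlas, bifurcation, radius = 15) {
  ends <- bifurcation_end_landmarks(atlas, bifurcation)
  if (nrow(ends) == 0 || nrow(graph$nodes) == 0) return(character(0))
  NP <- node_positions(graph)
  D2 <- outer(rowSums(NP^2), rowSums(ends^2), "+") - 2 * NP %*% t(ends)
  keep <- apply(D2, 1, min) < radius^2
  sort(graph$nodes$id[keep])
}
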