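#' Vessel centerline graphs
#'
#' A patient's cerebrovascular model is an undirected graph whose nodes are
#' vessel bifurcations and endpoints and whose edges are vessel segments.
#' Each segment carries an ordered 3-D centerline polyline with a radius per
#' point.  Parallel edges and cycles are permitted: segmentation artifacts
#' such as loops and shortcuts occur in real CTA-derived models and the
#' labeler must cope with them.
#'
#' @param nodes Data frame with columns `id` (character, unique), `x`, `y`,
#'   `z` (numeric, millimeters).
#' @param edges List of segments created by [vessel_segment()].
#' @return An object of class `vessel_graph` with components `nodes` (data
#'   frame), `edges` (named list of segments) and `adjacency` (named list
#'   mapping node id to incident edge ids).
#' @seealso [vessel_segment()], [read_vessel_graph()]
#' @export
vessel_graph <- function(nodes = data.frame(id = character(), x = numeric(),
                                            y = numeric(), z = numeric()),
                         edges = list()) {
  stopifnot(is.data.frame(nodes), all(c("id", "x", "y", "z") %in% names(nodes)))
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  ids <- vapply(edges, function(e) e$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate edge ids")
  names(edges) <- ids
  adjacency <- stats::setNames(rep(list(character(0)), nrow(nodes)), nodes$id)
  for (e in edges) {
    miss <- setdiff(e$nodes, nodes$id)
    if (length(miss) > 0)
      stop("integrity error: edge '", e$id, "' references unknown node id '",
           miss[1], "'")
    for (n in unique(e$nodes)) adjacency[[n]] <- c(adjacency[[n]], e$id)
    # endpoints must coincide with the node positions
    for (k in 1:2) {
      p <- node_position(nodes, e$nodes[k])
      q <- e$points[if (k == 1) 1 else nrow(e$points), ]
      if (sqrt(sum((p - q)^2)) > 1e-6)
        stop("integrity error: edge '", e$id, "' endpoint ", k,
             " does not coincide with node '", e$nodes[k], "'")
    }
  }
  structure(list(nodes = nodes, edges = edges, adjacency = adjacency),
            class = "vessel_graph")
}

#' @param id Segment identifier, unique within a graph.
#' @param node_ids Character vector of length 2: the ids of the two endpoint
#'   nodes, in centerline order.
#' @param points Numeric matrix (N x 3), the ordered centerline, N >= 2; the
#'   first and last rows must coincide with the endpoint node positions.
#' @param radii Numeric vector of length N, per-point vessel radius, all > 0.
#' @rdname vessel_graph
#' @export
vessel_segment <- function(id, node_ids, points, radii) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3 || nrow(points) < 2)
    stop("centerline must be a numeric N x 3 matrix with N >= 2")
  if (length(radii) != nrow(points))
    stop("radii count (", length(radii), ") must equal centerline point count (",
         nrow(points), ")")
  if (any(radii <= 0)) stop("all radii must be > 0")
  dimnames(points) <- NULL
  list(id = as.character(id), nodes = as.character(node_ids),
       points = points, radii = as.numeric(radii),
       length = polyline_length(points),
       mean_radius = mean(radii))
}

polyline_length <- function(points) {
  if (nrow(points) < 2) return(0)
  d <- diff(points)
  sum(sqrt(rowSums(d * d)))
}

node_position <- function(nodes, id) {
  i <- match(id, nodes$id)
  if (is.na(i)) stop("unknown node id: ", id)
  c(nodes$x[i], nodes$y[i], nodes$z[i])
}

node_positions <- function(graph) {
  m <- as.matrix(graph$nodes[, c("x", "y", "z")])
  rownames(m) <- graph$nodes$id
  m
}

incident_edges <- function(graph, node_id) {
  e <- graph$adjacency[[node_id]]
  if (is.null(e)) stop("unknown node id: ", node_id)
  e
}

other_node <- function(edge, node_id) {
  if (edge$nodes[1] == node_id) edge$nodes[2]
  else if (edge$nodes[2] == node_id) edge$nodes[1]
  else stop("node '", node_id, "' is not an endpoint of edge '", edge$id, "'")
}

# All centerline points of the graph pooled into one matrix.
all_centerline_points <- function(graph) {
  if (length(graph$edges) == 0) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, lapply(graph$edges, function(e) e$points))
}

#' Neighboring edges across a segment
#'
#' Given an edge and one of its endpoint nodes, returns the edges incident to
#' the *other* endpoint, excluding the edge itself.  This is the neighbor set
#' used by the recursive path score to continue a vessel path away from the
#' query node.
#'
#' @param graph A [vessel_graph()].
#' @param edge A segment of `graph` (or its id).
#' @param node Id of one endpoint of `edge`; the traversal enters the edge
#'   here and exits at the opposite node.
#' @return Character vector of edge ids (possibly empty), sorted.
#' @export
neighbor_edges <- function(graph, edge, node) {
  if (is.character(edge)) edge <- graph$edges[[edge]]
  node <- if (is.list(node)) node$id else as.character(node)
  far <- other_node(edge, node)
  sort(setdiff(incident_edges(graph, far), edge$id))
}

# Unit direction of an edge leaving `node_id`, taken as the chord from the
# node to the centerline point at arc length min(chord, length/2).  Using a
# short fixed chord instead of the full edge keeps the measured angle local
# for strongly curved segments.
edge_direction <- function(edge, node_id, chord = 3) {
  pts <- edge$points
  if (edge$nodes[2] == node_id && edge$nodes[1] != node_id)
    pts <- pts[nrow(pts):1, , drop = FALSE]
  else if (edge$nodes[1] != node_id)
    stop("node '", node_id, "' is not an endpoint of edge '", edge$id, "'")
  target <- min(chord, edge$length / 2)
  d <- diff(pts)
  cum <- cumsum(sqrt(rowSums(d * d)))
  i <- which(cum >= target)[1]
  if (is.na(i)) i <- length(cum)
  v <- pts[i + 1, ] - pts[1, ]
  nv <- sqrt(sum(v * v))
  if (nv < 1e-12)
    stop("degenerate centerline: zero-length direction on edge '", edge$id, "'")
  v / nv
}

#' Transition weight between two adjacent segments
#'
#' The smoothness of a vessel transition at a shared node, mapped linearly
#' from the dot product of the travel directions onto `[floor, 1]`:
#' `w = (1 + floor)/2 + (1 - floor)/2 * (u . v)`, i.e. `0.6 + 0.4 (u . v)`
#' with the default floor 0.2.  A straight continuation (transition angle of
#' 180 degrees) yields 1, a full reversal the floor.
#'
#' @param graph A [vessel_graph()].
#' @param edge_in,edge_out Two distinct segments incident to `shared_node`
#'   (objects or ids).
#' @param shared_node Node id at which the path passes from `edge_in` to
#'   `edge_out`.
#' @param params A [cow_params()] object (supplies the weight floor and the
#'   direction chord length).
#' @return Weight in `[params$weight_floor, 1]`.
#' @export
transition_weight <- function(graph, edge_in, edge_out, shared_node,
                              params = cow_params()) {
  if (is.character(edge_in)) edge_in <- graph$edges[[edge_in]]
  if (is.character(edge_out)) edge_out <- graph$edges[[edge_out]]
  if (identical(edge_in$id, edge_out$id)) stop("edges must be distinct")
  # u: direction of travel INTO the node along edge_in = -(direction leaving it)
  u <- -edge_direction(edge_in, shared_node, params$direction_chord)
  v <- edge_direction(edge_out, shared_node, params$direction_chord)
  dp <- max(-1, min(1, sum(u * v)))
  f <- params$weight_floor
  (1 + f) / 2 + (1 - f) / 2 * dp
}

#' Read and write vessel graphs as JSON
#'
#' The serialization dialect is
#' `{"nodes":[{"id","pos":[x,y,z]}],
#'   "edges":[{"id","nodes":[id,id],"points":[[x,y,z],...],"radii":[...],
#'             "label": optional artery id}]}`
#' with 0-based-free, order-preserving arrays; coordinates are millimeters in
#' a right-handed LPS frame.  `write_vessel_graph()` followed by
#' `read_vessel_graph()` is the identity on all fields (positions to 1e-9).
#'
#' @param path File path.
#' @param graph A [vessel_graph()].
#' @param labels Optional named character vector mapping edge ids to artery
#'   ids, stored in the per-edge `label` field.
#' @return `read_vessel_graph()` returns a `vessel_graph`; edge labels, when
#'   present, are attached as the `labels` attribute (named character vector).
#' @export
read_vessel_graph <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("nodes", "edges"))
    if (is.null(obj[[field]]))
      stop("parse error in '", path, "': missing field '", field, "'")
  nodes <- do.call(rbind, lapply(obj$nodes, function(n) {
    if (is.null(n$id) || is.null(n$pos) || length(n$pos) != 3)
      stop("parse error in '", path, "': node needs fields 'id' and 'pos' [x,y,z]")
    data.frame(id = as.character(n$id), x = as.numeric(n$pos[[1]]),
               y = as.numeric(n$pos[[2]]), z = as.numeric(n$pos[[3]]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(nodes)) nodes <- data.frame(id = character(), x = numeric(),
                                          y = numeric(), z = numeric())
  labels <- character(0)
  edges <- lapply(obj$edges, function(e) {
    for (field in c("id", "nodes", "points", "radii"))
      if (is.null(e[[field]]))
        stop("parse error in '", path, "': edge missing field '", field, "'")
    pts <- do.call(rbind, lapply(e$points, as.numeric))
    vessel_segment(e$id, unlist(e$nodes), pts, unlist(e$radii))
  })
  for (e in obj$edges)
    if (!is.null(e$label)) labels[[as.character(e$id)]] <- e$label
  g <- vessel_graph(nodes, edges)
  if (length(labels) > 0) attr(g, "labels") <- labels
  g
}

#' @rdname read_vessel_graph
#' @export
write_vessel_graph <- function(graph, path, labels = NULL) {
  nodes <- lapply(seq_len(nrow(graph$nodes)), function(i) {
    list(id = graph$nodes$id[i],
         pos = c(graph$nodes$x[i], graph$nodes$y[i], graph$nodes$z[i]))
  })
  edges <- lapply(graph$edges, function(e) {
    out <- list(id = e$id, nodes = e$nodes,
                points = lapply(seq_len(nrow(e$points)),
                                function(i) e$points[i, ]),
                radii = e$radii)
    if (!is.null(labels) && !is.na(labels[e$id]) && e$id %in% names(labels))
      out$label <- unname(labels[e$id])
    out
  })
  jsonlite::write_json(list(nodes = nodes, edges = unname(edges)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# igraph view of (a subset of) the vessel graph, arc-length weighted.
# Multi-edges are preserved; edge attribute `eid` carries the segment id.
as_igraph <- function(graph, edge_ids = names(graph$edges)) {
  edges <- graph$edges[edge_ids]
  if (length(edges) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(g)
  }
  ends <- do.call(rbind, lapply(edges, function(e) e$nodes))
  verts <- sort(unique(as.vector(ends)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ends[, 1], to = ends[, 2],
               weight = vapply(edges, function(e) e$length, numeric(1)),
               eid = vapply(edges, function(e) e$id, character(1)),
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE))
  g
}

# Shortest (arc-length) path between two nodes restricted to `edge_ids`.
# Returns the ordered edge-id list, or NULL when no path exists.
shortest_edge_path <- function(graph, from, to, edge_ids = names(graph$edges)) {
  if (identical(from, to)) return(character(0))
  g <- as_igraph(graph, edge_ids)
  vn <- igraph::V(g)$name
  if (!(from %in% vn) || !(to %in% vn)) return(NULL)
  sp <- suppressWarnings(igraph::shortest_paths(g, from, to, output = "epath"))
  ep <- sp$epath[[1]]
  if (length(ep) == 0) return(NULL)
  igraph::edge_attr(g, "eid", ep)
}

# Ordered node sequence of an ordered edge path.  For a single edge the
# orientation is ambiguous; `start_hint` (a node id) disambiguates.
path_nodes <- function(graph, edge_ids, start_hint = NULL) {
  if (length(edge_ids) == 0) return(character(0))
  e1 <- graph$edges[[edge_ids[1]]]
  starts <- unique(e1$nodes)
  # prefer the hinted end, then the end NOT shared with the second edge
  if (length(edge_ids) >= 2) {
    shared <- intersect(e1$nodes, graph$edges[[edge_ids[2]]]$nodes)
    starts <- c(setdiff(starts, shared), shared)
  }
  if (!is.null(start_hint) && start_hint %in% e1$nodes)
    starts <- unique(c(start_hint, starts))
  for (start in starts) {
    seqv <- start; cur <- start; ok <- TRUE
    for (eid in edge_ids) {
      e <- graph$edges[[eid]]
      if (!(cur %in% e$nodes)) { ok <- FALSE; break }
      cur <- other_node(e, cur)
      seqv <- c(seqv, cur)
    }
    if (ok) return(seqv)
  }
  stop("edge ids do not form a connected path")
}
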