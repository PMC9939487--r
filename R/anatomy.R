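#' Arteries and bifurcations of the Circle of Willis
#'
#' The labeler targets 14 arteries around the Circle of Willis and the 6
#' bifurcations joining them.  Inner arteries (AComm, ACA 1 left/right,
#' A. basilaris) span two labeled bifurcations; outer arteries (ACA 2,
#' A. media, PCA) leave the circle; incoming arteries (ICA, A. vertebralis)
#' feed it.
#'
#' @return `cow_arteries()` returns a data frame with columns `artery` and
#'   `role` (one of `"incoming"`, `"inner"`, `"outer"`); `cow_bifurcations()`
#'   returns a named list mapping each bifurcation id to its three adjacent
#'   artery ids.
#' @export
cow_arteries <- function() {
  data.frame(
    artery = c("ICA_L", "ICA_R", "VERT_L", "VERT_R",
               "BASILAR", "ACA1_L", "ACA1_R", "ACOMM",
               "MCA_L", "MCA_R", "PCA_L", "PCA_R", "ACA2_L", "ACA2_R"),
    role = c("incoming", "incoming", "incoming", "incoming",
             "inner", "inner", "inner", "inner",
             "outer", "outer", "outer", "outer", "outer", "outer"),
    stringsAsFactors = FALSE
  )
}

#' @rdname cow_arteries
#' @export
cow_bifurcations <- function() {
  list(
    VERTEBRAL = c("VERT_L", "VERT_R", "BASILAR"),
    POSTERIOR = c("BASILAR", "PCA_L", "PCA_R"),
    MEDIA_L   = c("ICA_L", "MCA_L", "ACA1_L"),
    MEDIA_R   = c("ICA_R", "MCA_R", "ACA1_R"),
    ACA_L     = c("ACA1_L", "ACA2_L", "ACOMM"),
    ACA_R     = c("ACA1_R", "ACA2_R", "ACOMM")
  )
}

# Canonical landmark/centerline orientation per artery: which bifurcation sits
# at the first and at the last point of the ordered polyline.  NA marks a free
# end (incoming/outgoing arteries have exactly one bifurcation end, inner
# arteries two).
cow_artery_ends <- function() {
  list(
    ICA_L   = c("MEDIA_L", NA),   ICA_R   = c("MEDIA_R", NA),
    VERT_L  = c("VERTEBRAL", NA), VERT_R  = c("VERTEBRAL", NA),
    BASILAR = c("VERTEBRAL", "POSTERIOR"),
    ACA1_L  = c("MEDIA_L", "ACA_L"), ACA1_R = c("MEDIA_R", "ACA_R"),
    ACOMM   = c("ACA_L", "ACA_R"),
    MCA_L   = c("MEDIA_L", NA),  MCA_R  = c("MEDIA_R", NA),
    PCA_L   = c("POSTERIOR", NA), PCA_R = c("POSTERIOR", NA),
    ACA2_L  = c("ACA_L", NA),    ACA2_R = c("ACA_R", NA)
  )
}

artery_role <- function(artery) {
  tab <- cow_arteries()
  role <- tab$role[match(artery, tab$artery)]
  if (anyNA(role)) stop("unknown artery id: ", paste(artery[is.na(role)], collapse = ", "))
  role
}

#' Algorithm parameters
#'
#' All tunable constants of the labeling pipeline in one place.  Distances are
#' millimeters.
#'
#' @param candidate_threshold Distance-score cutoff below which an edge enters
#'   an artery's candidate sub-graph (default 20 mm).
#' @param node_radius Radius around a bifurcation-end landmark within which
#'   graph nodes are considered candidate bifurcation nodes (default 15 mm).
#' @param delta Radius influence in the edge cost, dimensionless per mm of
#'   mean radius (default 0.1).
#' @param weight_floor Lower end of the transition-weight range; a straight
#'   continuation maps to 1, a full reversal to this floor (default 0.2).
#' @param distance_floor Floor applied to the distance score inside the edge
#'   cost to avoid division by zero (default 0.1 mm).
#' @param max_path_edges Recursion depth guard for the path score (default 64).
#' @param trace_min_dot Outer-artery tracing continues only across transitions
#'   whose direction dot product exceeds this value; 0.5 corresponds to a
#'   transition angle above 120 degrees (straight = 180 degrees).
#' @param anterior_ratio Runner-up score ratio above which a doubly assigned
#'   anterior bifurcation is reassigned to its second-best node (default 0.8).
#' @param bifurcation_tolerance Geodesic displacement under which a misplaced
#'   bifurcation is still rated "within 5 mm" (default 5 mm).
#' @param eval_extent Evaluation extent for outgoing vessels, measured along
#'   the centerline from the true bifurcation (default 20 mm).
#' @param icp_max_iter,icp_tol Iteration cap and RMS-change tolerance (mm) for
#'   the rigid landmark alignment.
#' @param direction_chord Arc length (mm) of the chord used to measure edge
#'   direction at a node; capped at half the edge length.
#' @return A named list of class `cow_params`.
#' @export
cow_params <- function(candidate_threshold = 20,
                       node_radius = 15,
                       delta = 0.1,
                       weight_floor = 0.2,
                       distance_floor = 0.1,
                       max_path_edges = 64,
                       trace_min_dot = 0.5,
                       anterior_ratio = 0.8,
                       bifurcation_tolerance = 5,
                       eval_extent = 20,
                       icp_max_iter = 50,
                       icp_tol = 1e-3,
                       direction_chord = 3) {
  stopifnot(delta >= 0, weight_floor > 0, weight_floor <= 1,
            candidate_threshold > 0, node_radius > 0)
  structure(list(
    candidate_threshold = candidate_threshold,
    node_radius = node_radius,
    delta = delta,
    weight_floor = weight_floor,
    distance_floor = distance_floor,
    max_path_edges = max_path_edges,
    trace_min_dot = trace_min_dot,
    anterior_ratio = anterior_ratio,
    bifurcation_tolerance = bifurcation_tolerance,
    eval_extent = eval_extent,
    icp_max_iter = icp_max_iter,
    icp_tol = icp_tol,
    direction_chord = direction_chord
  ), class = "cow_params")
}
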