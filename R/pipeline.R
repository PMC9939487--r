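#' Label a cerebrovascular graph end to end
#'
#' Runs the full pipeline: rigid ICP alignment of the landmark atlas onto
#' the centerlines, per-artery candidate graphs, recursive bifurcation
#' matching for the six bifurcations, and fusion into one consistent
#' labeling.
#'
#' @param graph A [vessel_graph()].
#' @param atlas A [landmark_atlas()] roughly pre-aligned to the patient
#'   frame.
#' @param params A [cow_params()].
#' @param verbose Print per-stage summaries.
#' @return A `cow_labeling` with attributes `matches` (the six
#'   `bifurcation_match` objects) and `icp_rms` (mm).
#' @export
label_cow <- function(graph, atlas, params = cow_params(), verbose = FALSE) {
  empty <- length(graph$edges) == 0
  if (empty) {
    warning("empty graph: returning an all-empty labeling")
    matches <- stats::setNames(vector("list", 6), names(cow_bifurcations()))
    lab <- fuse_matches(list(), graph, params)
    attr(lab, "icp_rms") <- NA_real_
    return(lab)
  }
  ali <- icp_align(atlas, graph, params$icp_max_iter, params$icp_tol)
  if (verbose) message(sprintf("ICP residual: %.3f mm", ali$rms))
  cands <- build_candidates(graph, ali$atlas, params$candidate_threshold)
  if (verbose)
    message("candidate edges per artery: ",
            paste(sprintf("%s=%d", names(cands), lengths(lapply(cands, `[[`, "edges"))),
                  collapse = " "))
  bifs <- names(cow_bifurcations())
  matches <- stats::setNames(lapply(bifs, function(b)
    match_bifurcation(graph, ali$atlas, b, cands, params)), bifs)
  for (b in bifs)
    if (!isTRUE(matches[[b]]$matched) && verbose)
      message("warning: bifurcation ", b, " unmatched")
  lab <- fuse_matches(matches, graph, params)
  attr(lab, "matches") <- matches
  attr(lab, "icp_rms") <- ali$rms
  lab
}

#' Command-style wrappers over the pipeline
#'
#' File-to-file entry points mirroring the `simulate`, `label`, `baseline`
#' and `evaluate` subcommands of the shipped command-line script
#' (`system.file("cli", "cowlabel.R", package = "cowlabel")`).
#'
#' @param graph_path,landmarks_path,out_path,truth_path,pred_path,report_path
#'   File paths (graph/landmark/labeling JSON as documented in
#'   [read_vessel_graph()], [read_landmarks()], [read_labeling()]).
#' @param spec_path YAML file whose fields mirror the [phantom_spec()]
#'   arguments.
#' @param params A [cow_params()].
#' @return Each wrapper invisibly returns its main in-memory result.
#' @export
cmd_label <- function(graph_path, landmarks_path, out_path,
                      params = cow_params()) {
  graph <- read_vessel_graph(graph_path)
  atlas <- read_landmarks(landmarks_path)
  lab <- label_cow(graph, atlas, params, verbose = TRUE)
  write_labeling(lab, out_path)
  invisible(lab)
}

#' @rdname cmd_label
#' @export
cmd_baseline <- function(graph_path, landmarks_path, out_path,
                         params = cow_params()) {
  graph <- read_vessel_graph(graph_path)
  atlas <- read_landmarks(landmarks_path)
  lab <- baseline_label(graph, atlas, params)
  write_labeling(lab, out_path)
  invisible(lab)
}

#' @rdname cmd_label
#' @export
cmd_simulate <- function(spec_path = NULL, out_path, landmarks_path,
                         truth_path) {
  args <- if (is.null(spec_path)) list() else yaml::read_yaml(spec_path)
  if (!is.null(args$artifacts)) args$artifacts <- unlist(args$artifacts)
  spec <- do.call(phantom_spec, args)
  ph <- generate_phantom(spec)
  write_vessel_graph(ph$graph, out_path,
                     labels = labeling_as_edge_labels(ph$truth))
  write_landmarks(ph$atlas, landmarks_path)
  write_labeling(ph$truth, truth_path)
  invisible(ph)
}

#' @rdname cmd_label
#' @export
cmd_evaluate <- function(pred_path, truth_path, graph_path, report_path,
                         params = cow_params()) {
  ev <- evaluate_labeling(read_labeling(pred_path), read_labeling(truth_path),
                          read_vessel_graph(graph_path), params)
  rep <- aggregate_reports(list(ev))
  write_report(rep, csv_path = report_path)
  invisible(rep)
}

# Per-edge label map (edge id -> artery) from a labeling.
labeling_as_edge_labels <- function(labeling) {
  out <- character(0)
  for (a in names(labeling$assignments))
    for (eid in labeling$assignments[[a]]) out[eid] <- a
  out
}
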