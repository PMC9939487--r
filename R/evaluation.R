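vessel_categories <- c("TP_star", "TP_minus", "TP_plus", "TP_pm",
                       "TN", "FN", "FP_plus", "FP_minus")
tp_categories <- c("TP_star", "TP_minus", "TP_plus", "TP_pm")

path_arclength <- function(graph, edge_ids) {
  if (length(edge_ids) == 0) return(0)
  sum(vapply(graph$edges[edge_ids], function(e) e$length, numeric(1)))
}

# Orient an edge path to start from the end nearest `ref_node` and keep the
# edges whose cumulative upstream arc length is below `extent`.
clip_path <- function(graph, edge_ids, ref_node, extent) {
  if (length(edge_ids) == 0) return(edge_ids)
  nds <- path_nodes(graph, edge_ids, ref_node)
  first <- nds[1]; last <- nds[length(nds)]
  if (!identical(first, ref_node)) {
    NP <- node_positions(graph)
    ref <- if (ref_node %in% rownames(NP)) NP[ref_node, ] else NULL
    d_first <- if (is.null(ref)) 0 else sqrt(sum((NP[first, ] - ref)^2))
    d_last <- if (is.null(ref)) 1 else sqrt(sum((NP[last, ] - ref)^2))
    if (d_last < d_first) edge_ids <- rev(edge_ids)
  }
  lens <- vapply(graph$edges[edge_ids], function(e) e$length, numeric(1))
  before <- cumsum(c(0, lens[-length(lens)]))
  edge_ids[before < extent]
}

#' Categorize one predicted artery path against ground truth
#'
#' Applies the eight-class verdict taxonomy.  Outgoing (outer) arteries
#' branch quickly, so prediction and truth are first clipped, with the same
#' rule, to `params$eval_extent` (2 cm) of arc length from the true
#' bifurcation node; incoming and inner arteries are compared over their
#' whole length.  Classes: both empty = `TN` (vessel absent and dismissed);
#' prediction without truth = `FP_minus`; truth without prediction = `FN`;
#' arc-length overlap below half the truth = `FP_plus` (wrong vessel);
#' otherwise `TP_star` (exact), `TP_minus` (subset of truth), `TP_plus`
#' (superset of truth) or `TP_pm` (both deviations).  The half-overlap
#' boundary operationalizes "main part of the vessel" for automatic scoring.
#'
#' @param pred,truth Ordered edge-id vectors.
#' @param artery Artery id (decides whether clipping applies).
#' @param graph A [vessel_graph()].
#' @param true_bifurcation_node Node id of the artery's true bifurcation end
#'   (`NA` to skip clipping).
#' @param params A [cow_params()].
#' @return List with `artery`, `category`, `overlap_fraction` and
#'   `excess_length` (mm of prediction outside the truth).
#' @export
evaluate_vessel <- function(pred, truth, artery, graph,
                            true_bifurcation_node = NA, params = cow_params()) {
  if (identical(artery_role(artery), "outer") && !is.na(true_bifurcation_node)) {
    truth <- clip_path(graph, truth, true_bifurcation_node, params$eval_extent)
    pred <- clip_path(graph, pred, true_bifurcation_node, params$eval_extent)
  }
  both <- intersect(pred, truth)
  overlap <- if (length(truth) == 0) NA_real_
             else path_arclength(graph, both) / path_arclength(graph, truth)
  excess <- path_arclength(graph, setdiff(pred, truth))
  category <-
    if (length(truth) == 0 && length(pred) == 0) "TN"
    else if (length(truth) == 0) "FP_minus"
    else if (length(pred) == 0) "FN"
    else if (overlap < 0.5) "FP_plus"
    else if (setequal(pred, truth)) "TP_star"
    else if (all(pred %in% truth)) "TP_minus"
    else if (all(truth %in% pred)) "TP_plus"
    else "TP_pm"
  list(artery = artery, category = category, overlap_fraction = overlap,
       excess_length = excess)
}

#' Categorize a predicted bifurcation node
#'
#' `correct` iff predicted and true node coincide (both absent also counts
#' as correct: a variant without the bifurcation, properly dismissed);
#' `within_5mm` iff the along-centerline (geodesic) distance between the
#' nodes is at most `params$bifurcation_tolerance` *and* the predicted node
#' lies on at least two of the bifurcation's true arteries -- slightly off,
#' but still between correct vessels; otherwise `false`.
#'
#' @param pred_node,truth_node Node ids (`NA` = unmatched/absent).
#' @param bifurcation Bifurcation id.
#' @param graph A [vessel_graph()].
#' @param truth A ground-truth `cow_labeling` (supplies the true artery edge
#'   sets for the two-correct-arteries condition).
#' @param params A [cow_params()].
#' @return List with `bifurcation`, `category` and `displacement` (mm along
#'   the vessels; `Inf` when unmatched or disconnected).
#' @export
evaluate_bifurcation <- function(pred_node, truth_node, bifurcation, graph,
                                 truth, params = cow_params()) {
  if (is.na(truth_node) && is.na(pred_node))
    return(list(bifurcation = bifurcation, category = "correct",
                displacement = 0))
  if (is.na(truth_node) || is.na(pred_node))
    return(list(bifurcation = bifurcation, category = "false",
                displacement = Inf))
  if (identical(pred_node, truth_node))
    return(list(bifurcation = bifurcation, category = "correct",
                displacement = 0))
  g <- as_igraph(graph)
  disp <- tryCatch(as.numeric(igraph::distances(g, pred_node, truth_node)),
                   error = function(e) Inf)
  arts <- cow_bifurcations()[[bifurcation]]
  inc <- incident_edges(graph, pred_node)
  on_true <- sum(vapply(arts, function(a)
    any(inc %in% truth$assignments[[a]]), logical(1)))
  category <- if (is.finite(disp) && disp <= params$bifurcation_tolerance &&
                  on_true >= 2) "within_5mm" else "false"
  list(bifurcation = bifurcation, category = category, displacement = disp)
}

#' Score a full labeling against ground truth
#'
#' @param pred,truth `cow_labeling` objects on the same graph (`truth` from a
#'   phantom).
#' @param graph The [vessel_graph()].
#' @param params A [cow_params()].
#' @return List with data frames `vessels` (artery, category,
#'   overlap_fraction, excess_length) and `bifurcations` (bifurcation,
#'   category, displacement).
#' @export
evaluate_labeling <- function(pred, truth, graph, params = cow_params()) {
  arteries <- cow_arteries()$artery
  ends <- cow_artery_ends()
  vs <- lapply(arteries, function(a) {
    bif <- ends[[a]][1]
    evaluate_vessel(pred$assignments[[a]], truth$assignments[[a]], a, graph,
                    true_bifurcation_node = truth$bifurcation_nodes[[bif]],
                    params = params)
  })
  bifs <- names(cow_bifurcations())
  bs <- lapply(bifs, function(b)
    evaluate_bifurcation(pred$bifurcation_nodes[[b]],
                         truth$bifurcation_nodes[[b]], b, graph, truth, params))
  list(
    vessels = data.frame(
      artery = arteries,
      category = vapply(vs, `[[`, character(1), "category"),
      overlap_fraction = vapply(vs, `[[`, numeric(1), "overlap_fraction"),
      excess_length = vapply(vs, `[[`, numeric(1), "excess_length"),
      stringsAsFactors = FALSE),
    bifurcations = data.frame(
      bifurcation = bifs,
      category = vapply(bs, `[[`, character(1), "category"),
      displacement = vapply(bs, `[[`, numeric(1), "displacement"),
      stringsAsFactors = FALSE))
}

#' Aggregate verdicts over a phantom suite
#'
#' @param evals List of [evaluate_labeling()] results.
#' @return List with `vessel_rates` (per-artery fraction in each of the eight
#'   classes), `bifurcation_rates` (per-bifurcation `correct`, `le_5mm` =
#'   correct or within 5 mm, and `false` rates), and the two headline
#'   aggregates `detection_rate` (detected or correctly dismissed:
#'   TP classes + TN) and `complete_rate` (exactly right: TP* + TN), both
#'   over all artery verdicts pooled.
#' @export
aggregate_reports <- function(evals) {
  stopifnot(length(evals) >= 1)
  vdf <- do.call(rbind, lapply(evals, `[[`, "vessels"))
  bdf <- do.call(rbind, lapply(evals, `[[`, "bifurcations"))
  vessel_rates <- do.call(rbind, lapply(split(vdf, vdf$artery), function(d) {
    counts <- table(factor(d$category, levels = vessel_categories))
    data.frame(artery = d$artery[1], t(as.matrix(counts / nrow(d))),
               stringsAsFactors = FALSE)
  }))
  rownames(vessel_rates) <- NULL
  bifurcation_rates <- do.call(rbind, lapply(split(bdf, bdf$bifurcation),
                                             function(d) {
    data.frame(bifurcation = d$bifurcation[1],
               correct = mean(d$category == "correct"),
               le_5mm = mean(d$category %in% c("correct", "within_5mm")),
               false = mean(d$category == "false"),
               stringsAsFactors = FALSE)
  }))
  rownames(bifurcation_rates) <- NULL
  list(vessel_rates = vessel_rates,
       bifurcation_rates = bifurcation_rates,
       detection_rate = mean(vdf$category %in% c(tp_categories, "TN")),
       complete_rate = mean(vdf$category %in% c("TP_star", "TN")))
}

#' Write an aggregated report
#'
#' @param report Output of [aggregate_reports()].
#' @param csv_path,json_path Optional file paths; each is written when
#'   non-`NULL`.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$vessel_rates, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
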