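#' Per-artery landmark sets
#'
#' A landmark atlas holds, for each artery of interest, an ordered list of
#' 3-D template points roughly following the artery's course.  The first and
#' last points of each set are its *end landmarks*; by the package's fixed
#' orientation convention (see `cow_artery_ends()`) the first landmark of an
#' incoming or outgoing artery sits at its bifurcation end, and inner
#' arteries run from one labeled bifurcation to the other.
#'
#' @param sets Named list mapping artery ids to numeric M x 3 matrices
#'   (M >= 2), millimeters.
#' @return An object of class `landmark_atlas`.
#' @export
landmark_atlas <- function(sets) {
  known <- cow_arteries()$artery
  bad <- setdiff(names(sets), known)
  if (length(bad) > 0) stop("unknown artery id(s): ", paste(bad, collapse = ", "))
  sets <- lapply(sets, function(m) {
    m <- as.matrix(m)
    if (!is.numeric(m) || ncol(m) != 3 || nrow(m) < 2)
      stop("each landmark set must be a numeric M x 3 matrix with M >= 2")
    dimnames(m) <- NULL
    m
  })
  structure(list(sets = sets), class = "landmark_atlas")
}

# The three bifurcation-end landmarks of a bifurcation: for each adjacent
# artery, its first or last landmark depending on the orientation convention.
bifurcation_end_landmarks <- function(atlas, bifurcation) {
  arts <- cow_bifurcations()[[bifurcation]]
  if (is.null(arts)) stop("unknown bifurcation id: ", bifurcation)
  ends <- cow_artery_ends()
  out <- matrix(NA_real_, nrow = 0, ncol = 3)
  for (a in arts) {
    m <- atlas$sets[[a]]
    if (is.null(m)) next
    i <- if (identical(ends[[a]][1], bifurcation)) 1 else nrow(m)
    out <- rbind(out, m[i, ])
  }
  out
}

atlas_points <- function(atlas) {
  do.call(rbind, unname(atlas$sets))
}

transform_atlas <- function(atlas, R, t) {
  atlas$sets <- lapply(atlas$sets, function(m) m %*% t(R) + rep(t, each = nrow(m)))
  atlas
}

#' Read and write landmark atlases as JSON
#'
#' Dialect: `{"arteries":[{"artery":"ACA1_L","points":[[x,y,z],...]}]}`;
#' point order is meaningful (end landmarks are the first and last points).
#'
#' @param path File path.
#' @param atlas A [landmark_atlas()].
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$arteries))
    stop("parse error in '", path, "': missing field 'arteries'")
  sets <- list()
  for (a in obj$arteries) {
    if (is.null(a$artery) || is.null(a$points))
      stop("parse error in '", path, "': artery entry needs 'artery' and 'points'")
    sets[[a$artery]] <- do.call(rbind, lapply(a$points, as.numeric))
  }
  landmark_atlas(sets)
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(atlas, path) {
  arteries <- lapply(names(atlas$sets), function(a) {
    m <- atlas$sets[[a]]
    list(artery = a, points = lapply(seq_len(nrow(m)), function(i) m[i, ]))
  })
  jsonlite::write_json(list(arteries = arteries), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Closed-form least-squares rigid fit (rotation + translation, no scale)
# mapping rows of P onto rows of Q, via SVD with reflection correction.
rigid_fit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(P - rep(cp, each = nrow(P))) %*% (Q - rep(cq, each = nrow(Q)))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cq - as.vector(R %*% cp)
  list(R = R, t = t)
}

# Index of the nearest row of `ref` for each row of `query` (brute force).
nearest_rows <- function(query, ref) {
  qn <- rowSums(query^2); rn <- rowSums(ref^2)
  D2 <- outer(qn, rn, "+") - 2 * query %*% t(ref)
  max.col(-D2, ties.method = "first")
}

#' Rigid ICP alignment of a landmark atlas onto a vessel graph
#'
#' Aligns all atlas points with a single rigid transform (rotation +
#' translation, no scale) minimizing the summed squared distance to the
#' nearest centerline point of the graph, by iterating point-to-point
#' iterative-closest-point steps: nearest-neighbor correspondences over the
#' pooled centerline points, then a closed-form rigid fit.  Iteration stops
#' when the RMS residual changes by less than `tol` or after `max_iter`
#' iterations.
#'
#' @param atlas A [landmark_atlas()], roughly pre-aligned to the patient
#'   frame (upstream non-rigid atlas registration is assumed).
#' @param graph A [vessel_graph()] with at least 3 non-collinear centerline
#'   points.
#' @param max_iter,tol Iteration cap and RMS-change tolerance (mm).
#' @return A list with `atlas` (the transformed atlas), `transform`
#'   (`list(R, t)`), `rms` (final RMS nearest-point residual, mm) and
#'   `rms_history` (per-iteration residuals, non-increasing).
#' @export
icp_align <- function(atlas, graph, max_iter = 50, tol = 1e-3) {
  P <- atlas_points(atlas)
  if (is.null(P) || nrow(P) == 0) stop("empty atlas")
  Q <- all_centerline_points(graph)
  if (nrow(Q) < 3) stop("alignment error: graph has fewer than 3 centerline points")
  sv <- svd(scale(Q, scale = FALSE))
  if (sum(sv$d > 1e-9 * max(sv$d, 1e-12)) < 2)
    stop("alignment error: degenerate (collinear or coincident) point cloud")
  R <- diag(3); t <- c(0, 0, 0)
  rms_history <- numeric(0)
  prev <- Inf
  for (iter in seq_len(max_iter)) {
    Pc <- P %*% t(R) + rep(t, each = nrow(P))
    idx <- nearest_rows(Pc, Q)
    fit <- rigid_fit(P, Q[idx, , drop = FALSE])
    R <- fit$R; t <- fit$t
    Pc <- P %*% t(R) + rep(t, each = nrow(P))
    res <- Pc - Q[idx, , drop = FALSE]
    rms <- sqrt(mean(rowSums(res^2)))
    rms_history <- c(rms_history, rms)
    if (abs(prev - rms) < tol) break
    prev <- rms
  }
  # residual against the *final* correspondences
  idx <- nearest_rows(Pc, Q)
  rms <- sqrt(mean(rowSums((Pc - Q[idx, , drop = FALSE])^2)))
  list(atlas = transform_atlas(atlas, R, t), transform = list(R = R, t = t),
       rms = rms, rms_history = rms_history)
}
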