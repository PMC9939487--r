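#' Specification of a synthetic Circle-of-Willis phantom
#'
#' Phantoms are schematic but geometrically plausible cerebrovascular graphs
#' (14 arteries meeting at 6 bifurcations inside a ~120 mm cube, millimeter
#' coordinates, anatomically plausible radii) with ground-truth labels and a
#' matching landmark atlas.  The atlas is always sampled from the *normal*
#' template -- it plays the role of a population atlas -- and then rigidly
#' displaced and jittered to emulate the residual error of an upstream
#' atlas-to-patient registration.
#'
#' @param seed Integer seed; identical seed and spec give a bit-identical
#'   phantom.
#' @param variant One of `"normal"`, `"fetal_pca_left"`, `"fetal_pca_right"`
#'   (the PCA originates from the ipsilateral ICA instead of the basilar
#'   tip), `"missing_acomm"`, `"single_aca2"` (both ACA 1 converge on one
#'   anterior bifurcation with a single ACA 2 and no AComm).
#' @param occlusions List of `list(artery=, fraction=)`: the given arc-length
#'   fraction of the artery, measured from its bifurcation end, is removed
#'   from the graph (fraction in (0, 1]; 1 deletes the artery, emulating
#'   e.g. an M1 occlusion).
#' @param artifacts Named integer vector with any of `shortcut` (extra edge
#'   between non-adjacent nodes), `loop` (duplicated parallel edge),
#'   `spurious_branch` (unlabeled random branch) and `split_edge` (subdivide
#'   an edge, geometry preserved).
#' @param landmark_rotation,landmark_translation Magnitude of the rigid
#'   misalignment applied to the atlas (degrees / mm); defaults 8 and 6.
#' @param landmark_jitter Per-landmark isotropic Gaussian jitter sd, mm
#'   (default 1).
#' @param noise_sd Centerline jitter sd applied to interior points, mm
#'   (default 0.3, of the order of CTA centerline extraction error).
#' @param sample_spacing Centerline resampling step, mm.
#' @param landmark_spacing Approximate landmark spacing along each template
#'   artery, mm (default 5).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(seed = 0L,
                         variant = c("normal", "fetal_pca_left",
                                     "fetal_pca_right", "missing_acomm",
                                     "single_aca2"),
                         occlusions = list(),
                         artifacts = c(shortcut = 0, loop = 0,
                                       spurious_branch = 0, split_edge = 0),
                         landmark_rotation = 8,
                         landmark_translation = 6,
                         landmark_jitter = 1,
                         noise_sd = 0.3,
                         sample_spacing = 1.25,
                         landmark_spacing = 5) {
  variant <- match.arg(variant)
  full <- c(shortcut = 0, loop = 0, spurious_branch = 0, split_edge = 0)
  full[names(artifacts)] <- artifacts
  for (o in occlusions) {
    if (is.null(o$artery) || is.null(o$fraction) ||
        o$fraction <= 0 || o$fraction > 1)
      stop("spec error: occlusion needs an artery and a fraction in (0, 1]")
    artery_role(o$artery)  # validates the id
  }
  structure(list(seed = as.integer(seed), variant = variant,
                 occlusions = occlusions, artifacts = full,
                 landmark_rotation = landmark_rotation,
                 landmark_translation = landmark_translation,
                 landmark_jitter = landmark_jitter,
                 noise_sd = noise_sd, sample_spacing = sample_spacing,
                 landmark_spacing = landmark_spacing),
            class = "phantom_spec")
}

mirror_x <- function(m) { m[, 1] <- -m[, 1]; m }

# Control polygons of the normal template, ordered by the package's artery
# orientation convention (first point = bifurcation anchor of
# cow_artery_ends()[,1]).  Radii taper linearly from r0 to r1.
cow_template <- function() {
  A <- list(
    ICA_L   = list(ctrl = rbind(c(25, 0, 0), c(28, 4, -8), c(24, 10, -20),
                                c(28, 12, -32), c(30, 14, -48)),
                   r0 = 3.6, r1 = 4.4),
    VERT_L  = list(ctrl = rbind(c(0, 32, -38), c(6, 34, -48), c(8, 38, -60),
                                c(7, 42, -72)),
                   r0 = 2.6, r1 = 2.4),
    BASILAR = list(ctrl = rbind(c(0, 32, -38), c(1, 28, -28), c(0, 25, -18),
                                c(0, 22, -8)),
                   r0 = 3.2, r1 = 3.0),
    MCA_L   = list(ctrl = rbind(c(25, 0, 0), c(34, 3, 2), c(44, 6, 4),
                                c(54, 10, 5)),
                   r0 = 3.0, r1 = 2.6),
    ACA1_L  = list(ctrl = rbind(c(25, 0, 0), c(18, -8, 4), c(12, -14, 8),
                                c(8, -18, 10)),
                   r0 = 2.4, r1 = 2.2),
    ACA2_L  = list(ctrl = rbind(c(8, -18, 10), c(6, -24, 18), c(5, -26, 30),
                                c(4, -22, 44)),
                   r0 = 2.3, r1 = 2.0),
    ACOMM   = list(ctrl = rbind(c(8, -18, 10), c(0, -19, 10.5),
                                c(-8, -18, 10)),
                   r0 = 1.5, r1 = 1.5),
    PCA_L   = list(ctrl = rbind(c(0, 22, -8), c(10, 26, -6), c(20, 32, -2),
                                c(30, 40, 2)),
                   r0 = 2.3, r1 = 2.0)
  )
  for (a in c("ICA", "VERT", "MCA", "ACA1", "ACA2", "PCA")) {
    l <- A[[paste0(a, "_L")]]
    A[[paste0(a, "_R")]] <- list(ctrl = mirror_x(l$ctrl), r0 = l$r0, r1 = l$r1)
  }
  A
}

# Anchor positions of the six bifurcations in the template frame.
cow_template_anchors <- function() {
  rbind(VERTEBRAL = c(0, 32, -38), POSTERIOR = c(0, 22, -8),
        MEDIA_L = c(25, 0, 0), MEDIA_R = c(-25, 0, 0),
        ACA_L = c(8, -18, 10), ACA_R = c(-8, -18, 10))
}

# Natural-spline resampling of a control polygon at ~`spacing` mm steps.
resample_curve <- function(ctrl, spacing) {
  d <- diff(ctrl)
  t <- c(0, cumsum(sqrt(rowSums(d * d))))
  n <- max(2L, as.integer(round(t[length(t)] / spacing)) + 1L)
  xout <- seq(0, t[length(t)], length.out = n)
  sapply(seq_len(3), function(k)
    stats::spline(t, ctrl[, k], xout = xout, method = "natural")$y)
}

# Smoothly varying radii (+-10% sinusoid, random phase) over a linear taper.
taper_radii <- function(n, r0, r1) {
  base <- seq(r0, r1, length.out = n)
  u <- seq(0, 1, length.out = n)
  base * (1 + 0.1 * sin(2 * pi * (1.5 * u + stats::runif(1))))
}

rotation_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# The unperturbed landmark atlas sampled from the normal template.
template_atlas <- function(sample_spacing = 1.25, landmark_spacing = 5) {
  tmpl <- cow_template()
  sets <- lapply(tmpl, function(art) {
    pts <- resample_curve(art$ctrl, sample_spacing)
    d <- diff(pts)
    len <- sum(sqrt(rowSums(d * d)))
    # evenly spaced sample indices, endpoints included, ~landmark_spacing apart
    m <- max(2L, as.integer(round(len / landmark_spacing)) + 1L)
    idx <- unique(round(seq(1L, nrow(pts), length.out = m)))
    pts[idx, , drop = FALSE]
  })
  landmark_atlas(sets)
}

#' Generate a ground-truth-labeled phantom
#'
#' Builds the template geometry, applies the anatomical variant, removes
#' occluded sub-paths, injects segmentation artifacts, jitters centerlines,
#' and emits the perturbed landmark atlas.  All randomness flows through a
#' single generator seeded from `spec$seed`; the caller's RNG state is
#' preserved.
#'
#' @param spec A [phantom_spec()].
#' @return A `cow_phantom`: list with `graph` (a [vessel_graph()]), `truth`
#'   (a `cow_labeling` with the true per-edge artery labels and bifurcation
#'   nodes), `atlas` (the perturbed [landmark_atlas()]) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  tmpl <- cow_template()
  anchors <- cow_template_anchors()

  # --- sampled artery pieces: list(artery, points, radii) -------------------
  pieces <- list()
  add_piece <- function(artery, points, radii)
    pieces[[length(pieces) + 1L]] <<- list(artery = artery, points = points,
                                           radii = radii)
  arteries <- names(tmpl)
  drop <- switch(spec$variant,
                 missing_acomm = "ACOMM",
                 single_aca2 = c("ACOMM", "ACA2_R"),
                 character(0))
  fetal <- switch(spec$variant, fetal_pca_left = "L", fetal_pca_right = "R", NULL)

  for (a in setdiff(arteries, drop)) {
    art <- tmpl[[a]]
    if (!is.null(fetal) && a == paste0("ICA_", fetal)) {
      pts <- resample_curve(art$ctrl, spec$sample_spacing)
      d <- diff(pts); cum <- c(0, cumsum(sqrt(rowSums(d * d))))
      j <- which.min(abs(cum - 0.55 * cum[length(cum)]))
      r <- taper_radii(nrow(pts), art$r0, art$r1)
      add_piece(a, pts[1:j, , drop = FALSE], r[1:j])
      add_piece(a, pts[j:nrow(pts), , drop = FALSE], r[j:nrow(pts)])
      # fetal PCA: redrawn from the ICA junction to the normal PCA free end
      side <- if (fetal == "L") 1 else -1
      pca <- paste0("PCA_", fetal)
      ctrl <- rbind(pts[j, ], c(side * 24, 22, -16), c(side * 27, 32, -6),
                    utils::tail(tmpl[[pca]]$ctrl, 1))
      ppts <- resample_curve(ctrl, spec$sample_spacing)
      add_piece(pca, ppts, taper_radii(nrow(ppts), tmpl[[pca]]$r0,
                                       tmpl[[pca]]$r1))
      next
    }
    if (!is.null(fetal) && a == paste0("PCA_", fetal)) next  # handled above
    ctrl <- art$ctrl
    if (spec$variant == "single_aca2" && a == "ACA1_R")
      ctrl <- rbind(c(-25, 0, 0), c(-12, -14, 8), c(0, -17, 9.5), anchors["ACA_L", ])
    pts <- resample_curve(ctrl, spec$sample_spacing)
    add_piece(a, pts, taper_radii(nrow(pts), art$r0, art$r1))
  }

  # --- occlusions -----------------------------------------------------------
  for (o in spec$occlusions) {
    idx <- which(vapply(pieces, function(p) identical(p$artery, o$artery),
                        logical(1)))
    if (length(idx) == 0) next
    total <- sum(vapply(pieces[idx], function(p) polyline_length(p$points),
                        numeric(1)))
    cut <- o$fraction * total
    if (o$fraction >= 1) { pieces[idx] <- NULL; next }
    done <- 0
    for (i in idx) {
      p <- pieces[[i]]
      len <- polyline_length(p$points)
      if (done + len <= cut + 1e-9) { pieces[[i]] <- NA; done <- done + len; next }
      if (done >= cut) break
      d <- diff(p$points); cum <- c(0, cumsum(sqrt(rowSums(d * d))))
      j <- which(cum >= cut - done)[1]
      j <- max(j, 2L)
      if (j >= nrow(p$points)) { pieces[[i]] <- NA } else {
        pieces[[i]]$points <- p$points[j:nrow(p$points), , drop = FALSE]
        pieces[[i]]$radii <- p$radii[j:nrow(p$points)]
      }
      break
    }
    pieces <- pieces[!vapply(pieces, function(p) identical(p, NA), logical(1))]
  }

  # --- artifacts ------------------------------------------------------------
  n_art <- spec$artifacts
  for (k in seq_len(n_art[["split_edge"]])) {
    ok <- which(vapply(pieces, function(p) nrow(p$points) >= 4, logical(1)))
    if (length(ok) == 0) break
    i <- ok[sample.int(length(ok), 1)]
    p <- pieces[[i]]
    j <- sample(2:(nrow(p$points) - 1), 1)
    first <- list(artery = p$artery, points = p$points[1:j, , drop = FALSE],
                  radii = p$radii[1:j])
    second <- list(artery = p$artery,
                   points = p$points[j:nrow(p$points), , drop = FALSE],
                   radii = p$radii[j:nrow(p$points)])
    pieces <- append(pieces[-i], list(first, second), after = i - 1L)
  }
  for (k in seq_len(n_art[["loop"]])) {
    i <- which(vapply(pieces, function(p) nrow(p$points) >= 5, logical(1)))
    if (length(i) == 0) break
    i <- i[sample.int(length(i), 1)]
    p <- pieces[[i]]
    pts <- p$points
    chord <- pts[nrow(pts), ] - pts[1, ]
    perp <- pracma_cross(chord, random_unit_vector())
    if (sqrt(sum(perp^2)) < 1e-6) perp <- c(0, 0, 1) else perp <- perp / sqrt(sum(perp^2))
    bump <- sin(seq(0, pi, length.out = nrow(pts)))
    dup <- pts + outer(2.5 * bump, perp)
    add_piece(NA_character_, dup, p$radii * 0.8)
  }
  # endpoints available so far, for shortcut/branch attachment
  endpoint_mat <- function() {
    do.call(rbind, lapply(pieces, function(p)
      rbind(p$points[1, ], p$points[nrow(p$points), ])))
  }
  for (k in seq_len(n_art[["shortcut"]])) {
    ep <- unique(round(endpoint_mat(), 6))
    if (nrow(ep) < 2) break
    found <- FALSE
    for (try in 1:20) {
      ij <- sample.int(nrow(ep), 2)
      d <- sqrt(sum((ep[ij[1], ] - ep[ij[2], ])^2))
      if (d > 8 && d < 60) { found <- TRUE; break }
    }
    if (!found) next
    a <- ep[ij[1], ]; b <- ep[ij[2], ]
    mid <- (a + b) / 2 + 3 * random_unit_vector()
    pts <- resample_curve(rbind(a, mid, b), spec$sample_spacing)
    add_piece(NA_character_, pts, rep(1.2, nrow(pts)))
  }
  for (k in seq_len(n_art[["spurious_branch"]])) {
    ep <- unique(round(endpoint_mat(), 6))
    a <- ep[sample.int(nrow(ep), 1), ]
    dir <- random_unit_vector()
    len <- stats::runif(1, 10, 25)
    ctrl <- rbind(a, a + dir * len / 2 + 3 * random_unit_vector(), a + dir * len)
    pts <- resample_curve(ctrl, spec$sample_spacing)
    add_piece(NA_character_, pts, rep(stats::runif(1, 1.0, 1.5), nrow(pts)))
  }

  # --- centerline noise (interior points only) ------------------------------
  if (spec$noise_sd > 0) {
    pieces <- lapply(pieces, function(p) {
      n <- nrow(p$points)
      if (n > 2)
        p$points[2:(n - 1), ] <- p$points[2:(n - 1), ] +
          matrix(stats::rnorm(3 * (n - 2), 0, spec$noise_sd), ncol = 3)
      p
    })
  }

  # --- assemble the graph ---------------------------------------------------
  key_of <- function(p) {
    p <- round(p, 6)
    p[p == 0] <- 0  # -0 and 0 must intern to the same node
    paste(sprintf("%.6f", p), collapse = ",")
  }
  node_key <- character(0); node_pos <- list()
  intern <- function(p) {
    k <- key_of(p)
    i <- match(k, node_key)
    if (is.na(i)) {
      node_key <<- c(node_key, k)
      node_pos[[length(node_pos) + 1L]] <<- p
      i <- length(node_key)
    }
    sprintf("n%03d", i)
  }
  edges <- list()
  edge_artery <- character(0)
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]
    n1 <- intern(p$points[1, ]); n2 <- intern(p$points[nrow(p$points), ])
    eid <- sprintf("e%03d", i)
    edges[[eid]] <- vessel_segment(eid, c(n1, n2), p$points, p$radii)
    edge_artery[eid] <- p$artery
  }
  nodes <- data.frame(id = sprintf("n%03d", seq_along(node_pos)),
                      x = vapply(node_pos, `[`, numeric(1), 1),
                      y = vapply(node_pos, `[`, numeric(1), 2),
                      z = vapply(node_pos, `[`, numeric(1), 3),
                      stringsAsFactors = FALSE)
  graph <- vessel_graph(nodes, edges)

  # --- ground truth ---------------------------------------------------------
  all_arteries <- cow_arteries()$artery
  assignments <- stats::setNames(rep(list(character(0)), length(all_arteries)),
                                 all_arteries)
  for (eid in names(edge_artery)) {
    a <- edge_artery[[eid]]
    if (!is.na(a)) assignments[[a]] <- c(assignments[[a]], eid)
  }
  bn <- stats::setNames(rep(NA_character_, nrow(anchors)), rownames(anchors))
  for (b in rownames(anchors)) {
    k <- key_of(anchors[b, ])
    i <- match(k, node_key)
    if (!is.na(i)) {
      id <- sprintf("n%03d", i)
      if (length(incident_edges(graph, id)) >= 2) bn[b] <- id
    }
  }
  if (spec$variant == "single_aca2") bn["ACA_R"] <- NA_character_
  prov <- stats::setNames(ifelse(lengths(assignments) > 0, "truth", "absent"),
                          all_arteries)
  # the fetal PCA leaves the ICA, not the posterior bifurcation
  if (!is.null(fetal)) prov[paste0("PCA_", fetal)] <- "variant"
  truth <- structure(list(assignments = assignments, bifurcation_nodes = bn,
                          provenance = prov),
                     class = "cow_labeling")

  # --- perturbed landmark atlas --------------------------------------------
  atlas <- template_atlas(spec$sample_spacing, spec$landmark_spacing)
  R <- rotation_about_axis(random_unit_vector(), spec$landmark_rotation)
  tr <- random_unit_vector() * spec$landmark_translation
  ctr <- colMeans(atlas_points(atlas))
  atlas$sets <- lapply(atlas$sets, function(m) {
    m <- (m - rep(ctr, each = nrow(m))) %*% t(R) +
      rep(ctr + tr, each = nrow(m))
    if (spec$landmark_jitter > 0)
      m <- m + matrix(stats::rnorm(length(m), 0, spec$landmark_jitter),
                      ncol = 3)
    m
  })

  structure(list(graph = graph, truth = truth, atlas = atlas, spec = spec),
            class = "cow_phantom")
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Fixed scenario mixture for acceptance-style testing
#'
#' For each seed `0..n_seeds-1`, one spec per scenario class: clean normal
#' anatomy, a full A. media occlusion (side alternating with the seed), an
#' artifact-laden graph (shortcuts, a loop, spurious branches, split edges),
#' the fetal-PCA and missing-AComm and single-ACA 2 variants.  Deterministic
#' in `n_seeds`.
#'
#' @param n_seeds Number of seeds (>= 1).
#' @return Named list of [phantom_spec()] objects; names carry the scenario
#'   class.
#' @export
scenario_suite <- function(n_seeds) {
  stopifnot(n_seeds >= 1)
  out <- list()
  for (s in seq_len(n_seeds) - 1L) {
    side <- if (s %% 2 == 0) "MCA_L" else "MCA_R"
    out[[sprintf("clean_%02d", s)]] <- phantom_spec(seed = s * 10L + 1L)
    out[[sprintf("media_occlusion_%02d", s)]] <-
      phantom_spec(seed = s * 10L + 2L,
                   occlusions = list(list(artery = side, fraction = 1)))
    out[[sprintf("artifacts_%02d", s)]] <-
      phantom_spec(seed = s * 10L + 3L,
                   artifacts = c(shortcut = 2, loop = 1,
                                 spurious_branch = 2, split_edge = 2))
    out[[sprintf("fetal_%02d", s)]] <-
      phantom_spec(seed = s * 10L + 4L, variant = "fetal_pca_right")
    out[[sprintf("missing_acomm_%02d", s)]] <-
      phantom_spec(seed = s * 10L + 5L, variant = "missing_acomm")
    out[[sprintf("single_aca2_%02d", s)]] <-
      phantom_spec(seed = s * 10L + 6L, variant = "single_aca2")
  }
  out
}
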