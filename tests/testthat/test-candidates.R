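# A landmark array along the x axis: M points spaced 5 mm, first and last are
# the end landmarks.
line_landmarks <- function(M = 7) cbind(seq(0, by = 5, length.out = M), 0, 0)

test_that("distance score is zero on interior-landmark-coincident points", {
  L <- line_landmarks()
  # centerline points sitting exactly on interior landmarks 2..4
  seg <- vessel_segment("e", c("A", "B"), L[2:4, ], rep(1, 3))
  expect_identical(distance_score(seg, L)$value, 0)
})

test_that("constant point distances give zero spread", {
  L <- line_landmarks()
  pts <- L[2:5, ]; pts[, 2] <- 3  # parallel offset by 3 mm
  seg <- vessel_segment("e", c("A", "B"), pts, rep(1, 4))
  expect_equal(distance_score(seg, L)$value, 3, tolerance = 1e-12)
})

test_that("the spread term penalizes perpendicular segments", {
  L <- line_landmarks(5)
  # retained distances exactly (1, 4, 9): perpendicular-ish fan-out
  perp <- vessel_segment("e", c("A", "B"),
                         rbind(c(5, 1, 0), c(10, 4, 0), c(15, 9, 0)),
                         rep(1, 3))
  dsp <- distance_score(perp, L)
  expect_equal(dsp$s, c(1, 4, 9))
  expect_equal(dsp$value, 14 / 3 + sqrt(73 / 3), tolerance = 1e-12)
  # parallel segment at constant 4 mm scores lower
  par <- vessel_segment("e", c("A", "B"),
                        rbind(c(5, 4, 0), c(10, 4, 0), c(15, 4, 0)),
                        rep(1, 3))
  expect_equal(distance_score(par, L)$value, 4, tolerance = 1e-12)
  expect_gt(dsp$value, distance_score(par, L)$value)
})

test_that("points nearest an end landmark are omitted; thin support -> Inf", {
  L <- line_landmarks(5)  # ends at x = 0 and x = 20
  # all points cluster past the far end: every nearest landmark is an end
  seg <- vessel_segment("e", c("A", "B"),
                        rbind(c(25, 1, 0), c(28, 1, 0), c(31, 1, 0)),
                        rep(1, 3))
  ds <- distance_score(seg, L)
  expect_false(any(ds$retained))
  expect_identical(ds$value, Inf)
  # one stray interior-matched point among many end-matched ones is not
  # enough support either
  pts <- rbind(c(10, 0.5, 0), matrix(rep(c(25, 1, 0), 9), ncol = 3,
                                     byrow = TRUE))
  pts[, 1] <- pts[, 1] + seq(0, 0.9, length.out = 10)  # distinct points
  seg2 <- vessel_segment("e", c("A", "B"), pts, rep(1, 10))
  expect_identical(distance_score(seg2, L)$value, Inf)
  expect_error(distance_score(seg, matrix(numeric(0), ncol = 3)), "empty")
})

test_that("distance score equals the brute-force double loop", {
  set.seed(101)
  for (i in 1:50) {
    M <- sample(4:10, 1); N <- sample(5:30, 1)
    L <- cbind(seq(0, by = 5, length.out = M), stats::rnorm(M), stats::rnorm(M))
    pts <- cbind(stats::runif(N, -5, 5 * M), stats::runif(N, -10, 10),
                 stats::runif(N, -10, 10))
    seg <- vessel_segment("e", c("A", "B"), pts, rep(1, N))
    expect_equal(distance_score(seg, L)$value, brute_distance_score(pts, L),
                 tolerance = 1e-12)
  }
})

test_that("moving a segment away from the landmarks never lowers its score", {
  L <- line_landmarks()
  base <- rbind(c(10, 2, 0), c(13, 2, 0), c(16, 2, 0), c(19, 2, 0))
  prev <- -Inf
  for (off in seq(0, 12, by = 1.5)) {
    pts <- base; pts[, 2] <- pts[, 2] + off
    seg <- vessel_segment("e", c("A", "B"), pts, rep(1, 4))
    val <- distance_score(seg, L)$value
    expect_gte(val, prev - 1e-12)
    prev <- val
  }
})

test_that("candidate inclusion uses a strict threshold", {
  sets <- list(ICA_L = line_landmarks())
  atlas <- landmark_atlas(sets)
  make_graph_at <- function(offset) {
    # 4 samples sitting exactly above interior landmarks: s is constant
    A <- c(5, offset, 0); B <- c(20, offset, 0)
    vessel_graph(make_nodes(list(A = A, B = B)),
                 list(straight_segment("e1", c("A", "B"), A, B, n = 4)))
  }
  # parallel segment: score equals the offset exactly
  inc <- build_candidates(make_graph_at(19.9), atlas, threshold = 20)
  expect_identical(inc$ICA_L$edges, "e1")
  exc <- build_candidates(make_graph_at(20.0), atlas, threshold = 20)
  expect_identical(exc$ICA_L$edges, character(0))
  # far away: empty candidate set is a legal outcome
  far <- build_candidates(make_graph_at(500), atlas, threshold = 20)
  expect_length(far$ICA_L$edges, 0)
})

test_that("clean phantoms keep every true edge in its artery's candidates", {
  ph <- generate_phantom(phantom_spec(seed = 31))
  ali <- icp_align(ph$atlas, ph$graph)
  cands <- build_candidates(ph$graph, ali$atlas)
  for (a in cow_arteries()$artery)
    expect_true(all(ph$truth$assignments[[a]] %in% cands[[a]]$edges),
                info = a)
})

test_that("candidate bifurcation nodes respect the 1.5 cm radius", {
  sets <- list(
    VERT_L = rbind(c(0, 0, 0), c(0, 5, -10)),
    VERT_R = rbind(c(0, 0, 0), c(0, -5, -10)),
    BASILAR = rbind(c(0, 0, 0), c(0, 0, 20)))
  atlas <- landmark_atlas(sets)
  g <- vessel_graph(make_nodes(list(P = c(14, 0, 0), Q = c(16, 0, 0),
                                    R = c(0, 0, 14.5))))
  nodes <- candidate_bifurcation_nodes(g, atlas, "VERTEBRAL", radius = 15)
  expect_setequal(nodes, c("P", "R"))
  ph <- generate_phantom(phantom_spec(seed = 32))
  ali <- icp_align(ph$atlas, ph$graph)
  for (b in names(cow_bifurcations()))
    expect_true(ph$truth$bifurcation_nodes[[b]] %in%
                  candidate_bifurcation_nodes(ph$graph, ali$atlas, b),
                info = b)
})
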