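test_that("edge cost reproduces the closed form", {
  seg <- straight_segment("e", c("A", "B"), c(0, 0, 0), c(10, 0, 0), n = 5,
                          radius = 2)
  expect_equal(edge_cost(seg, weights = 1, score = 5), 2.4, tolerance = 1e-12)
  # delta = 0 removes the radius influence
  p0 <- cow_params(delta = 0)
  expect_equal(edge_cost(seg, 1, 5, p0), 2.0, tolerance = 1e-12)
  # appending a poor weight lowers the cost relative to a perfect one
  expect_lt(edge_cost(seg, c(1, 0.2), 5), edge_cost(seg, c(1, 1), 5))
  # zero distance is floored, not divided by
  expect_equal(edge_cost(seg, 1, 0), edge_cost(seg, 1, 0.1), tolerance = 1e-12)
  expect_error(edge_cost(seg, 1, Inf), "candidate")
  expect_error(edge_cost(seg, numeric(0), 5), "non-empty")
})

test_that("path score unrolls the recursion on simple chains", {
  chain <- make_chain(2)
  cand <- list(artery = "ICA_L", edges = c("e1", "e2"),
               scores = c(e1 = 5, e2 = 4))
  c1 <- edge_cost(chain$edges$e1, 1, 5)
  c2 <- edge_cost(chain$edges$e2, c(1, 1), 4)
  # single candidate edge, no continuation
  single <- list(artery = "ICA_L", edges = "e1", scores = c(e1 = 5))
  expect_identical(path_score(chain, "e1", "A", single)$score, c1)
  # straight two-edge chain: weights [1], then [1, 1]
  res <- path_score(chain, "e1", "A", cand)
  expect_identical(res$score, c1 + c2)
  expect_identical(res$path, c("e1", "e2"))
  expect_error(path_score(chain, "e2", "B", single), "candidate")
})

test_that("path score equals exhaustive path enumeration on random graphs", {
  set.seed(202)
  params <- cow_params()
  for (i in 1:40) {
    g <- random_toy_graph(sample(4:7, 1), sample(3:10, 1))
    cand <- random_candidate(g)
    eid <- sample(names(g$edges), 1)
    vid <- sample(g$edges[[eid]]$nodes, 1)
    got <- path_score(g, eid, vid, cand, params = params)
    want <- enumerate_path_score(g, eid, vid, cand, params)
    expect_identical(got$score, want$score)
  }
})

test_that("configuration enumeration counts match the node degree", {
  expect_length(cowlabel:::enumerate_configs(c("a", "b", "c")), 6)
  cfg2 <- cowlabel:::enumerate_configs(c("a", "b"))
  expect_length(cfg2, 6)  # 3 artery pairs x 2 orders, one artery unassigned
  expect_true(all(vapply(cfg2, function(x) sum(is.na(x)) == 1, logical(1))))
  expect_length(cowlabel:::enumerate_configs("a"), 3)
  # degree 4: ordered 3-subsets
  expect_length(cowlabel:::enumerate_configs(letters[1:4]), 24)
})

test_that("clean phantoms are matched at the true bifurcation nodes", {
  ph <- generate_phantom(phantom_spec(seed = 41))
  ali <- icp_align(ph$atlas, ph$graph)
  cands <- build_candidates(ph$graph, ali$atlas)
  for (b in names(cow_bifurcations())) {
    m <- match_bifurcation(ph$graph, ali$atlas, b, cands)
    expect_true(m$matched)
    expect_identical(m$node, unname(ph$truth$bifurcation_nodes[[b]]))
    # consistency: all non-empty paths start at the chosen node
    for (p in m$artery_paths)
      if (length(p) > 0)
        expect_true(m$node %in% cowlabel:::path_nodes(ph$graph, p, m$node))
  }
})

test_that("an occluded A. media still leaves its bifurcation matchable", {
  ph <- generate_phantom(phantom_spec(
    seed = 42, occlusions = list(list(artery = "MCA_L", fraction = 1))))
  ali <- icp_align(ph$atlas, ph$graph)
  cands <- build_candidates(ph$graph, ali$atlas)
  m <- match_bifurcation(ph$graph, ali$atlas, "MEDIA_L", cands)
  expect_true(m$matched)
  expect_identical(m$node, unname(ph$truth$bifurcation_nodes[["MEDIA_L"]]))
  expect_length(m$artery_paths$MCA_L, 0)
  expect_gt(m$artery_scores[["ICA_L"]], 0)
  expect_gt(m$artery_scores[["ACA1_L"]], 0)
})

test_that("matching is deterministic and ignores unreachable edges", {
  ph <- generate_phantom(phantom_spec(seed = 43))
  ali <- icp_align(ph$atlas, ph$graph)
  cands <- build_candidates(ph$graph, ali$atlas)
  m1 <- match_bifurcation(ph$graph, ali$atlas, "POSTERIOR", cands)
  m2 <- match_bifurcation(ph$graph, ali$atlas, "POSTERIOR", cands)
  expect_identical(m1, m2)
  # score monotonicity: an unreachable extra candidate edge changes nothing
  chain <- make_chain(2)
  iso_pos <- list(A = c(0, 0, 0), B = c(10, 0, 0), C = c(20, 0, 0),
                  X = c(0, 50, 0), Y = c(10, 50, 0))
  g2 <- vessel_graph(make_nodes(iso_pos), list(
    straight_segment("e1", c("A", "B"), iso_pos$A, iso_pos$B, n = 5, radius = 1),
    straight_segment("e2", c("B", "C"), iso_pos$B, iso_pos$C, n = 5, radius = 1),
    straight_segment("e9", c("X", "Y"), iso_pos$X, iso_pos$Y, n = 5, radius = 1)))
  cand_small <- list(artery = "ICA_L", edges = c("e1", "e2"),
                     scores = c(e1 = 5, e2 = 4))
  cand_big <- list(artery = "ICA_L", edges = c("e1", "e2", "e9"),
                   scores = c(e1 = 5, e2 = 4, e9 = 1))
  expect_identical(path_score(g2, "e1", "A", cand_small)$score,
                   path_score(g2, "e1", "A", cand_big)$score)
  # a reachable positive-cost extension never decreases the score
  cand_one <- list(artery = "ICA_L", edges = "e1", scores = c(e1 = 5))
  expect_gt(path_score(g2, "e1", "A", cand_small)$score,
            path_score(g2, "e1", "A", cand_one)$score)
})

test_that("the recursion guard trips on pathologically deep walks", {
  chain <- make_chain(6)
  ids <- paste0("e", 1:6)
  cand <- list(artery = "ICA_L", edges = ids,
               scores = stats::setNames(rep(5, 6), ids))
  params <- cow_params(max_path_edges = 3)
  expect_error(path_score(chain, "e1", "A", cand, params = params),
               "recursion")
})
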