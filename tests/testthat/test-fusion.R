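mk_match <- function(bif, node, paths, scores = NULL, mean_score = 1,
                     runner_up = NULL) {
  arts <- cow_bifurcations()[[bif]]
  ap <- stats::setNames(rep(list(character(0)), 3), arts)
  for (a in names(paths)) ap[[a]] <- paths[[a]]
  if (is.null(scores)) scores <- stats::setNames(rep(1, 3), arts)
  structure(list(bifurcation = bif, matched = !is.na(node), node = node,
                 artery_paths = ap, artery_scores = scores,
                 mean_score = mean_score, runner_up = runner_up),
            class = "bifurcation_match")
}

test_that("inner merging honors overlap and bridges disjoint paths", {
  # chain A-e1-B-e2-C-e3-D-e4-E; basilar between VERTEBRAL at A, POSTERIOR at E
  chain <- make_chain(4)
  mA <- mk_match("VERTEBRAL", "A", list(BASILAR = c("e1", "e2")))
  mB <- mk_match("POSTERIOR", "E", list(BASILAR = c("e4", "e3", "e2")))
  # overlapping: shortest path A..E inside the union
  expect_identical(merge_inner(mA, mB, "BASILAR", chain),
                   c("e1", "e2", "e3", "e4"))
  # identical paths from both sides
  mA2 <- mk_match("VERTEBRAL", "A", list(BASILAR = c("e1", "e2", "e3", "e4")))
  mB2 <- mk_match("POSTERIOR", "E", list(BASILAR = c("e4", "e3", "e2", "e1")))
  expect_identical(merge_inner(mA2, mB2, "BASILAR", chain),
                   c("e1", "e2", "e3", "e4"))
  # disjoint: e1 from the left, e4 from the right, bridged through e2, e3
  mA3 <- mk_match("VERTEBRAL", "A", list(BASILAR = "e1"))
  mB3 <- mk_match("POSTERIOR", "E", list(BASILAR = "e4"))
  expect_identical(merge_inner(mA3, mB3, "BASILAR", chain),
                   c("e1", "e2", "e3", "e4"))
  # unmatched far side: near path returned unchanged
  mB4 <- mk_match("POSTERIOR", NA_character_, list())
  expect_identical(merge_inner(mA3, mB4, "BASILAR", chain), "e1")
  # disconnected graph: both partial paths kept, marked interrupted
  two <- vessel_graph(
    make_nodes(list(A = c(0, 0, 0), B = c(10, 0, 0),
                    D = c(30, 0, 0), E = c(40, 0, 0))),
    list(straight_segment("e1", c("A", "B"), c(0, 0, 0), c(10, 0, 0)),
         straight_segment("e4", c("D", "E"), c(30, 0, 0), c(40, 0, 0))))
  mer <- merge_inner(mk_match("VERTEBRAL", "A", list(BASILAR = "e1")),
                     mk_match("POSTERIOR", "E", list(BASILAR = "e4")),
                     "BASILAR", two)
  expect_true(isTRUE(attr(mer, "interrupted")))
  expect_setequal(as.character(mer), c("e1", "e4"))
})

test_that("outer tracing follows smooth continuations and stops at branches", {
  # straight chain with a perpendicular side branch at C
  pos <- list(A = c(0, 0, 0), B = c(10, 0, 0), C = c(20, 0, 0),
              D = c(30, 0, 0), S = c(20, 10, 0))
  g <- vessel_graph(make_nodes(pos), list(
    straight_segment("e1", c("A", "B"), pos$A, pos$B, n = 5),
    straight_segment("e2", c("B", "C"), pos$B, pos$C, n = 5),
    straight_segment("e3", c("C", "D"), pos$C, pos$D, n = 5),
    straight_segment("s1", c("C", "S"), pos$C, pos$S, n = 5)))
  # from e1 the trace runs straight through e2, e3 and ignores the 90-degree
  # side branch
  expect_identical(trace_outer(g, "e1", "A"), c("e1", "e2", "e3"))
  # tracing never removes edges: input is a prefix of the output
  ext <- trace_outer(g, c("e1", "e2"), "A")
  expect_identical(ext[1:2], c("e1", "e2"))
  # labeled edges stop the trace
  expect_identical(trace_outer(g, "e1", "A", labeled = "e3"), c("e1", "e2"))
  # a free end with no incident edges leaves the path unchanged
  expect_identical(trace_outer(g, "e3", "C"), "e3")
  # sharp-angle-only continuations are never taken
  sharp <- vessel_graph(
    make_nodes(list(A = c(0, 0, 0), B = c(10, 0, 0), Z = c(5, 8, 0))),
    list(straight_segment("e1", c("A", "B"), c(0, 0, 0), c(10, 0, 0), n = 5),
         straight_segment("z", c("B", "Z"), c(10, 0, 0), c(5, 8, 0), n = 5)))
  expect_identical(trace_outer(sharp, "e1", "A"), "e1")
})

test_that("anterior double assignments are resolved by the 80% rule", {
  mL <- mk_match("ACA_L", "n1", list(), mean_score = 10)
  mR <- mk_match("ACA_R", "n2", list(), mean_score = 12)
  # different nodes: untouched
  expect_identical(resolve_anterior(mL, mR), list(mL, mR))
  # shared node, strong runner-up at 85%: reassigned to it
  ru <- mk_match("ACA_L", "n9", list(), mean_score = 8.5)
  mLs <- mk_match("ACA_L", "n2", list(), mean_score = 10, runner_up = ru)
  out <- resolve_anterior(mLs, mR)
  expect_identical(out[[1]]$node, "n9")
  expect_identical(out[[2]]$node, "n2")
  # weak runner-up at 50%: single-ACA2 reading, lower side unmatched
  ru2 <- mk_match("ACA_L", "n9", list(), mean_score = 5)
  mLw <- mk_match("ACA_L", "n2", list(), mean_score = 10, runner_up = ru2)
  out2 <- resolve_anterior(mLw, mR)
  expect_false(out2[[1]]$matched)
  expect_true(out2[[2]]$matched)
  # no runner-up at all behaves like the weak case
  mLn <- mk_match("ACA_L", "n2", list(), mean_score = 10)
  expect_false(resolve_anterior(mLn, mR)[[1]]$matched)
})

test_that("fusing clean-phantom matches reproduces the ground truth", {
  ph <- generate_phantom(phantom_spec(seed = 51))
  lab <- label_cow(ph$graph, ph$atlas)
  validate_labeling(lab, ph$graph)
  for (a in cow_arteries()$artery)
    expect_setequal(lab$assignments[[a]], ph$truth$assignments[[a]])
  expect_identical(lab$bifurcation_nodes, ph$truth$bifurcation_nodes)
})

test_that("fusion tolerates entirely unmatched inputs", {
  ph <- generate_phantom(phantom_spec(seed = 52))
  lab <- fuse_matches(list(), ph$graph)
  expect_true(all(lengths(lab$assignments) == 0))
  expect_true(all(is.na(lab$bifurcation_nodes)))
  validate_labeling(lab, ph$graph)
})

test_that("no edge ever carries two artery labels after fusion", {
  for (s in c(61, 62, 63)) {
    ph <- generate_phantom(phantom_spec(
      seed = s, artifacts = c(shortcut = 2, loop = 1, spurious_branch = 2,
                              split_edge = 2)))
    lab <- label_cow(ph$graph, ph$atlas)
    all_edges <- unlist(lab$assignments, use.names = FALSE)
    expect_identical(anyDuplicated(all_edges), 0L)
    validate_labeling(lab, ph$graph)
  }
})
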