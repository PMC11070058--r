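mk_track_tree <- function(f, frames, x0 = 20, y0 = 20, id = 1L) {
  f <- new_tree(f, rect_cell(frames[1], id, x0 + 2 * frames[1], y0))
  b <- f$last_branch_id
  for (t in frames[-1]) f <- add_node(f, b, rect_cell(t, id, x0 + 2 * t, y0))
  f
}

test_that("prune_singletons drops exactly the one-node trees", {
  f <- new_forest()
  f <- mk_track_tree(f, 0:9)
  f <- new_tree(f, rect_cell(4, 99, 200, 200))   # singleton
  r <- prune_singletons(f)
  expect_length(r$forest$branches, 1)
  expect_length(r$pruned, 1)
  expect_equal(r$pruned[[1]]$instance_id, 99L)
  # no singletons: identity
  r2 <- prune_singletons(r$forest)
  expect_length(r2$pruned, 0)
  expect_identical(export_lineage(r2$forest), export_lineage(r$forest))
  # generator fixture: exactly the injected single-frame blobs are pruned
  sim <- simulate_timelapse(simulation_config(n_cells = 4, n_frames = 30,
                                              seed = 17))
  cor <- corrupt_dropout_fp(sim$frames, fp_count = 5, seed = 18)
  raw <- track(cor$frames, tracker_config())
  r3 <- prune_singletons(raw)
  expect_length(r3$pruned, 5)
  expect_true(all(vapply(r3$pruned, function(ci) ci$instance_id > 10000L,
                         logical(1))))
})

test_that("link_fragments joins splits within 3 frames, not beyond", {
  cfg <- tracker_config()
  # same location, gap 2 (frames 0-10 and 13-20): joined into one track
  f <- new_forest()
  f <- mk_track_tree(f, 0:10)
  f <- mk_track_tree(f, 13:20)
  r <- link_fragments(f, cfg)
  expect_equal(r$n_linked, 1)
  expect_length(r$forest$branches, 1)
  fr <- vapply(r$forest$branches[[1]]$nodes, function(n) n$cell$frame,
               integer(1))
  expect_equal(fr, c(0:10, 13:20))
  # 4 frames apart: not linked
  g <- new_forest()
  g <- mk_track_tree(g, 0:10)
  g <- mk_track_tree(g, 15:20)
  expect_equal(link_fragments(g, cfg)$n_linked, 0)
  # two candidate predecessors: the geometrically identical one is chosen
  h <- new_forest()
  h <- mk_track_tree(h, 0:10, x0 = 20, y0 = 20)            # identical shape
  h <- new_tree(h, rect_cell(8, 2, 40, 26, 10, 5))          # half the area
  h <- add_node(h, h$last_branch_id, rect_cell(9, 2, 40, 26, 10, 5))
  h <- add_node(h, h$last_branch_id, rect_cell(10, 2, 40, 26, 10, 5))
  h <- mk_track_tree(h, 12:20, x0 = 21, y0 = 20, id = 3L)
  r3 <- link_fragments(h, cfg)
  expect_equal(r3$n_linked, 1)
  joined <- Filter(function(b) length(b$nodes) > 15, r3$forest$branches)
  expect_length(joined, 1)
  ids <- vapply(joined[[1]]$nodes, function(n) n$cell$instance_id, integer(1))
  expect_true(all(ids %in% c(1L, 3L)))
})

test_that("discard_short_trees keeps the boundary and still-open exceptions", {
  f <- new_forest()
  f <- mk_track_tree(f, 20:28)   # span 9: discarded
  f <- mk_track_tree(f, 20:29, x0 = 100)  # span 10: kept
  f <- mk_track_tree(f, 95:99, x0 = 200)  # open at final frame: kept
  r <- discard_short_trees(f, 10, n_frames = 100)
  expect_equal(r$n_discarded, 1)
  tids <- getFromNamespace("forest_tree_ids", "trackforest")(r$forest)
  expect_length(tids, 2)
  # movies shorter than the threshold keep frame-0 roots
  g <- new_forest()
  g <- mk_track_tree(g, 0:5)
  r2 <- discard_short_trees(g, 10, n_frames = 9)
  expect_equal(r2$n_discarded, 0)
})

test_that("fill_gaps imputes missing frames by copying the cached node", {
  f <- new_forest()
  f <- new_tree(f, rect_cell(3, 1, 20, 20))
  f <- add_node(f, f$last_branch_id, rect_cell(6, 1, 26, 20))
  f$n_frames <- 10L
  r <- fill_gaps(f)
  expect_equal(r$n_filled, 2)
  nodes <- r$forest$branches[[1]]$nodes
  expect_equal(vapply(nodes, function(n) n$cell$frame, integer(1)), 3:6)
  expect_equal(vapply(nodes, function(n) n$is_gap_fill, logical(1)),
               c(FALSE, TRUE, TRUE, FALSE))
  # gap-fill geometry copies the preceding real node
  expect_equal(nodes[[2]]$cell$centroid, nodes[[1]]$cell$centroid)
  expect_equal(nodes[[3]]$cell$area, nodes[[1]]$cell$area)
  # contiguous branch: identity
  g <- new_forest(); g <- mk_track_tree(g, 0:9); g$n_frames <- 10L
  expect_equal(fill_gaps(g)$n_filled, 0)
})

test_that("refine restores truth structure on a corrupted movie", {
  sim <- simulate_timelapse(simulation_config(n_cells = 6, n_frames = 40,
                                              seed = 23))
  cor <- corrupt_dropout_fp(sim$frames, p = 0.05, fp_count = 3, seed = 24,
                            max_gap = 3)
  raw <- track(cor$frames, tracker_config())
  ref <- refine_forest(raw, tracker_config(), c(512, 512))
  expect_equal(ref$n_pruned, 3)
  tids <- getFromNamespace("forest_tree_ids", "trackforest")(ref$forest)
  expect_length(tids, 6)   # exact ground-truth track count restored
  # all branches frame-contiguous; no real node lost
  for (br in ref$forest$branches) {
    fr <- vapply(br$nodes, function(n) n$cell$frame, integer(1))
    expect_equal(diff(fr), rep(1L, length(fr) - 1))
  }
  n_real <- getFromNamespace("forest_n_nodes", "trackforest")(ref$forest)
  n_input_real <- sum(vapply(cor$frames, function(fs)
    sum(vapply(fs$instances, function(ci) ci$instance_id < 10000L,
               logical(1))), integer(1)))
  expect_equal(n_real, n_input_real)
})

test_that("fragment linking must precede the short-track discard", {
  cfg <- tracker_config()
  f <- new_forest()
  f <- mk_track_tree(f, 0:5)        # 6-frame fragment
  f <- mk_track_tree(f, 8:13)       # 6-frame fragment, same cell
  f$n_frames <- 50L
  # stated order: link first, then discard -> one 14-frame track survives
  good <- discard_short_trees(link_fragments(f, cfg)$forest, 10, 50)
  expect_length(getFromNamespace("forest_tree_ids", "trackforest")(
    good$forest), 1)
  # reversed order loses everything
  bad <- link_fragments(discard_short_trees(f, 10, 50)$forest, cfg)
  expect_length(bad$forest$branches, 0)
})
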