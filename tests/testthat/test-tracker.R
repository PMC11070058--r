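test_that("link_by_overlap partitions instances into unique/contested/orphan", {
  # one drifting cell: unique link
  tip <- rect_cell(0, 1, 10, 10)
  cur <- rect_cell(1, 1, 12, 10)
  r <- link_by_overlap(list(tip), list(cur))
  expect_equal(nrow(r$unique), 1)
  expect_length(r$contested, 0)
  expect_length(r$orphans, 0)
  # two crossing cells: one 2x2 contested group
  tips <- list(rect_cell(0, 1, 10, 10), rect_cell(0, 2, 18, 10))
  curs <- list(rect_cell(1, 1, 13, 10), rect_cell(1, 2, 16, 10))
  r2 <- link_by_overlap(tips, curs)
  expect_equal(nrow(r2$unique), 0)
  expect_length(r2$contested, 1)
  expect_equal(r2$contested[[1]]$tips, c(1L, 2L))
  expect_equal(r2$contested[[1]]$instances, c(1L, 2L))
  # a jumped cell: orphan
  r3 <- link_by_overlap(list(tip), list(rect_cell(1, 1, 60, 60)))
  expect_equal(r3$orphans, 1L)
  # every instance lands in exactly one bucket
  r4 <- link_by_overlap(tips, list(curs[[1]], curs[[2]],
                                   rect_cell(1, 3, 200, 200)))
  n <- nrow(r4$unique) +
    sum(vapply(r4$contested, function(g) length(g$instances), integer(1))) +
    length(r4$orphans)
  expect_equal(n, 3)
})

test_that("resolve_contested pairs greedily by similarity with id tie-break", {
  # each instance nearest its own tip: correct pairing (verified against
  # both possible pairings by total similarity)
  tips <- list(rect_cell(0, 1, 10, 10), rect_cell(0, 2, 19, 10))
  curs <- list(rect_cell(1, 1, 11, 10), rect_cell(1, 2, 20, 10))
  r <- resolve_contested(tips, curs)
  expect_equal(r$pairs[order(r$pairs[, 1]), , drop = FALSE],
               matrix(c(1L, 1L, 2L, 2L), 2, 2, byrow = TRUE),
               ignore_attr = TRUE)
  s_straight <- similarity_index(tips[[1]], curs[[1]])$total +
    similarity_index(tips[[2]], curs[[2]])$total
  s_crossed <- similarity_index(tips[[1]], curs[[2]])$total +
    similarity_index(tips[[2]], curs[[1]])$total
  expect_gt(s_straight, s_crossed)
  # 2 tips, 1 instance: the higher-similarity tip wins
  r2 <- resolve_contested(tips, curs[1])
  expect_equal(r2$pairs[1, ], c(1L, 1L), ignore_attr = TRUE)
  expect_equal(r2$unmatched_tips, 2L)
  # exact tie: lower instance id first
  sym_tips <- list(rect_cell(0, 1, 20, 10))
  sym_curs <- list(rect_cell(1, 5, 24, 10), rect_cell(1, 3, 16, 10))
  r3 <- resolve_contested(sym_tips, sym_curs)
  expect_equal(sym_curs[[r3$pairs[1, 2]]]$instance_id, 3L)
})

test_that("expanded_search_candidates uses centroid-in-expanded-box", {
  orphan <- rect_cell(1, 1, 40, 40)  # bbox [40,49] -> Ec x in [26.5, 62.5]
  inside <- rect_cell(0, 1, 23, 40)       # centroid 27.5, just inside
  outside <- rect_cell(0, 2, 12, 40)      # centroid 16.5, outside
  expect_equal(expanded_search_candidates(orphan, list(inside)), 1L)
  expect_length(expanded_search_candidates(orphan, list(outside)), 0)
  # three inside, best similarity first (nearest wins, all else equal)
  tips <- list(rect_cell(0, 1, 56, 40), rect_cell(0, 2, 42, 40),
               rect_cell(0, 3, 52, 40))
  idx <- expanded_search_candidates(orphan, tips)
  expect_equal(idx, c(2L, 3L, 1L))
})

test_that("detect_division enforces the four mitosis rules", {
  cfg <- tracker_config()
  orphan <- rect_cell(10, 2, 40, 40, 10, 10)         # area 100
  mother_ok <- list(cell = rect_cell(9, 1, 38, 36, 13, 10),   # area 130
                    last_division_frame = -Inf, branch_id = 7L)
  expect_equal(detect_division(orphan, list(mother_ok), cfg, 10), 7L)
  # ratio 1.25 < 1.3 rejected
  mother_small <- mother_ok
  mother_small$cell <- rect_cell(9, 1, 38, 36, 25, 5)  # area 125
  expect_null(detect_division(orphan, list(mother_small), cfg, 10))
  # cooldown: division 10 frames ago rejected, 60 frames ago accepted
  m_cool <- mother_ok; m_cool$last_division_frame <- 0
  expect_null(detect_division(orphan, list(m_cool), cfg, 10))
  m_old <- mother_ok; m_old$last_division_frame <- 10
  expect_equal(detect_division(orphan, list(m_old), cfg, 70), 7L)
  # centroid outside the expanded box rejected
  m_far <- mother_ok
  m_far$cell <- rect_cell(9, 1, 150, 150, 13, 10)
  expect_null(detect_division(orphan, list(m_far), cfg, 10))
  # class-aware mode: non-M mother rejected, M mother accepted
  m_g1 <- mother_ok
  m_g1$cell$class_label <- "G1/G2"
  expect_null(detect_division(orphan, list(m_g1), cfg, 10, use_class = TRUE))
  m_m <- mother_ok
  m_m$cell$class_label <- "M"
  expect_equal(detect_division(orphan, list(m_m), cfg, 10, use_class = TRUE),
               7L)
})

test_that("cache_match reaches back at most cache_depth frames", {
  cfg <- tracker_config()
  mk_forest <- function(last_frame) {
    f <- new_forest()
    f <- new_tree(f, rect_cell(0, 1, 40, 40))
    for (t in seq_len(last_frame)) {
      f <- add_node(f, f$last_branch_id, rect_cell(t, 1, 40, 40))
    }
    f
  }
  orphan10 <- rect_cell(10, 9, 41, 40)
  expect_equal(cache_match(orphan10, mk_forest(7), cfg, 10), 1L)  # gap 3
  expect_equal(cache_match(orphan10, mk_forest(5), cfg, 10), 1L)  # gap 5
  expect_null(cache_match(orphan10, mk_forest(4), cfg, 10))       # gap 6
  # two stalled branches in range: higher similarity wins
  f <- mk_forest(7)
  f <- new_tree(f, rect_cell(7, 2, 46, 44, 10, 5))  # different shape/area
  pick <- cache_match(orphan10, f, cfg, 10)
  expect_equal(pick, 1L)
})

test_that("track recovers clean drifting, dividing and gapped movies", {
  cfg <- tracker_config()
  # 2 well-separated drifting cells x 10 frames: all unique links
  mv <- drift_movie(10, list(c(20, 20), c(200, 200)))
  f <- track(mv, cfg)
  dec <- attr(f, "decisions")
  expect_length(getFromNamespace("forest_tree_ids", "trackforest")(f), 2)
  expect_equal(sum(dec$outcome == "linked_unique"), 18)
  expect_equal(sum(dec$outcome == "new_tree"), 2)
  # division fixture via the generator: 1 tree, 1 division, 2 leaves
  sim <- simulate_timelapse(simulation_config(n_cells = 1, n_frames = 40,
                                              n_divisions = 1, seed = 9))
  fd <- track(sim$frames, cfg)
  expect_length(getFromNamespace("forest_tree_ids", "trackforest")(fd), 1)
  div <- getFromNamespace("forest_divisions", "trackforest")(fd)
  expect_length(div, 1)
  expect_equal(div[[1]]$frame, sim$divisions[[1]]$frame)
  # dropped frames 4-5, slow drift: the cell still overlaps its branch's
  # cached tip, so a single branch resumes at frame 6 via the overlap stage
  mv2 <- drift_movie(10, list(c(20, 20)))
  mv2[[5]] <- fseg(4, list())
  mv2[[6]] <- fseg(5, list())
  fg <- track(mv2, cfg)
  expect_length(fg$branches, 1)
  fr <- vapply(fg$branches[[1]]$nodes, function(n) n$cell$frame, integer(1))
  expect_equal(fr, c(0:3, 6:9))
  # same gap but fast drift (no overlap left): resumes via cache matching
  mv3 <- drift_movie(10, list(c(20, 20)), step = 5)
  mv3[[5]] <- fseg(4, list())
  mv3[[6]] <- fseg(5, list())
  fc <- track(mv3, cfg)
  expect_length(fc$branches, 1)
  dec3 <- attr(fc, "decisions")
  expect_equal(sum(dec3$outcome == "cache_relinked"), 1)
  fr3 <- vapply(fc$branches[[1]]$nodes, function(n) n$cell$frame, integer(1))
  expect_equal(fr3, c(0:3, 6:9))
})

test_that("track is exhaustive and deterministic; no divisions without dividers", {
  sim <- simulate_timelapse(simulation_config(n_cells = 5, n_frames = 25,
                                              n_divisions = 0, seed = 13))
  f1 <- track(sim$frames, tracker_config())
  f2 <- track(sim$frames, tracker_config())
  expect_identical(export_lineage(f1), export_lineage(f2))
  dec <- attr(f1, "decisions")
  n_inst <- sum(vapply(sim$frames, function(fs) length(fs$instances),
                       integer(1)))
  expect_equal(nrow(dec), n_inst)                       # exhaustive
  expect_equal(anyDuplicated(dec[c("frame", "instance_id")]), 0)
  expect_length(getFromNamespace("forest_divisions", "trackforest")(f1), 0)
  expect_length(track(list(), tracker_config())$branches, 0)  # empty input
})
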