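mk_tracks <- function(spec) {
  # spec: list of list(frames=, xs=, id=) rectangles of size 10 at y = 10
  out <- list()
  for (k in seq_along(spec)) {
    s <- spec[[k]]
    out[[as.character(k)]] <- list(
      id = k, frames = s$frames,
      cells = lapply(seq_along(s$frames), function(i)
        rect_cell(s$frames[i], if (is.null(s$id)) k else s$id,
                  s$xs[i], if (is.null(s$y)) 10 else s$y)))
  }
  out
}

test_that("hungarian assignment equals brute-force enumeration", {
  am <- getFromNamespace("assignment_max", "trackforest")
  set.seed(41)
  for (k in 1:30) {
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    sc <- matrix(sample(0:20, n * m, replace = TRUE), n, m)
    expect_equal(am(sc)$score, brute_assignment_max(sc))
  }
  # rectangular, with ties
  sc <- matrix(c(5, 5, 5, 5, 0, 3), 2, 3)
  expect_equal(am(sc)$score, brute_assignment_max(sc))
})

test_that("match_detections thresholds and one-to-one greedy behaviour", {
  a <- rect_cell(0, 1, 10, 10)
  b <- rect_cell(0, 2, 40, 10)
  expect_equal(nrow(match_detections(list(a, b), list(a, b))), 2)
  expect_equal(nrow(match_detections(list(a), list(b))), 0)
  # one pred overlapping two gt at IoU ~0.54/0.18: matched to the better gt
  g1 <- rect_cell(0, 1, 10, 10)
  g2 <- rect_cell(0, 2, 24, 10)
  p <- rect_cell(0, 1, 13, 10)   # IoU(g1, p) = 7/13; IoU(g2, p) = 0? shift
  mm <- match_detections(list(g1, g2), list(p), iou_min = 0.5)
  expect_equal(mm[, "gt"], 1L, ignore_attr = TRUE)
})

test_that("idf1 matches hand-computed splits and the brute-force oracle", {
  gt <- mk_tracks(list(list(frames = 0:9, xs = 10 + 2 * (0:9))))
  # identical prediction
  expect_equal(idf1(gt, gt)$idf1, 1)
  # one 10-frame track predicted as two 5-frame halves
  pred <- mk_tracks(list(list(frames = 0:4, xs = 10 + 2 * (0:4)),
                         list(frames = 5:9, xs = 10 + 2 * (5:9))))
  r <- idf1(gt, pred)
  expect_equal(r$IDTP, 5L); expect_equal(r$IDFP, 5L); expect_equal(r$IDFN, 5L)
  expect_equal(r$idf1, 0.5)
  # empty prediction
  expect_equal(idf1(gt, list())$idf1, 0)
  expect_equal(idf1(list(), list())$idf1, 1)
  # oracle equivalence on random small instances (<= 5 tracks, <= 10 frames)
  set.seed(43)
  for (k in 1:8) {
    ng <- sample(2:4, 1); np <- sample(2:5, 1)
    gt_s <- mk_tracks(lapply(seq_len(ng), function(i)
      list(frames = sort(sample(0:9, sample(3:8, 1))),
           xs = 10 + 30 * i + (0:9), y = 10 + 25 * i)))
    pr_s <- mk_tracks(lapply(seq_len(np), function(i) {
      src <- ((i - 1) %% ng) + 1
      fr <- sort(sample(0:9, sample(3:8, 1)))
      list(frames = fr, xs = 10 + 30 * src + fr + sample(0:2, 1),
           y = 10 + 25 * src)
    }))
    expect_equal(idf1(gt_s, pr_s)$idf1, brute_idf1(gt_s, pr_s))
  }
})

test_that("mota counts FP, FN and identity switches per the formula", {
  gt <- mk_tracks(list(list(frames = 0:9, xs = 10 + 2 * (0:9))))
  expect_equal(mota(gt, gt)$mota, 1)
  # empty prediction: 1 - 10/10 = 0
  expect_equal(mota(gt, list())$mota, 0)
  # a split track costs exactly one identity switch
  pred <- mk_tracks(list(list(frames = 0:4, xs = 10 + 2 * (0:4)),
                         list(frames = 5:9, xs = 10 + 2 * (5:9))))
  r <- mota(gt, pred)
  expect_equal(r$IDsw, 1L)
  expect_equal(r$mota, 1 - 1 / 10)
  # 1 FN + 1 FP + 1 IDsw over GT 10 -> 0.7
  pred2 <- mk_tracks(list(
    list(frames = 0:3, xs = 10 + 2 * (0:3)),      # miss frame 4 later
    list(frames = 5:9, xs = 10 + 2 * (5:9)),      # resumes as new id
    list(frames = 7, xs = 300, y = 300)))          # far-away FP
  r2 <- mota(gt, pred2)
  expect_equal(r2$FN, 1L); expect_equal(r2$FP, 1L); expect_equal(r2$IDsw, 1L)
  expect_equal(r2$mota, 0.7)
  # undefined with empty ground truth
  expect_true(is.na(mota(list(), pred)$mota))
  # agreement with the independent implementation on random instances
  set.seed(47)
  for (k in 1:5) {
    ng <- sample(2:4, 1)
    gt_s <- mk_tracks(lapply(seq_len(ng), function(i)
      list(frames = 0:9, xs = 10 + 30 * i + 2 * (0:9), y = 10 + 25 * i)))
    pr_s <- mk_tracks(lapply(seq_len(ng), function(i) {
      fr <- sort(sample(0:9, 8))
      list(frames = fr, xs = 10 + 30 * i + 2 * fr, y = 10 + 25 * i)
    }))
    expect_equal(mota(gt_s, pr_s)$mota, brute_mota(gt_s, pr_s))
  }
})

test_that("metric scores are invariant to track relabelling", {
  gt <- mk_tracks(list(list(frames = 0:9, xs = 10 + 2 * (0:9)),
                       list(frames = 0:9, xs = 200 + 2 * (0:9), y = 100)))
  pred <- gt
  shuffled <- pred[c(2, 1)]
  names(shuffled) <- c("17", "4")
  shuffled[[1]]$id <- 17; shuffled[[2]]$id <- 4
  expect_equal(idf1(gt, shuffled)$idf1, idf1(gt, pred)$idf1)
  expect_equal(mota(gt, shuffled)$mota, mota(gt, pred)$mota)
})

test_that("cdf1 arithmetic matches enumerated event sets", {
  # build forests: truth with 2 divisions; prediction recovers both, then
  # corrupt the prediction stepwise
  mk_div_forest <- function(drop_daughter = FALSE, wrong_mother = FALSE) {
    f <- new_forest()
    for (i in 1:2) {
      f <- new_tree(f, rect_cell(0, i, 20 + 100 * (i - 1), 20))
      b <- f$last_branch_id
      for (t in 1:4) f <- add_node(f, b,
        rect_cell(t, i, 20 + 100 * (i - 1) + 2 * t, 20))
      da <- rect_cell(5, i, 14 + 100 * (i - 1), 12, 7, 7)
      db <- rect_cell(5, i + 10L, 34 + 100 * (i - 1), 28, 7, 7)
      if (wrong_mother && i == 2) {
        # swap the daughters between the two mothers
        da <- rect_cell(5, i, 14, 12, 7, 7)
      }
      f <- open_division(f, b, da, db, 5)
      d <- f$last_daughter_ids
      for (t in 6:9) {
        f <- add_node(f, d[1], rect_cell(t, i,
          14 + 100 * (i - 1) + t, 12, 7, 7))
        if (!(drop_daughter && i == 2)) {
          f <- add_node(f, d[2], rect_cell(t, i + 10L,
            34 + 100 * (i - 1) + t, 28, 7, 7))
        }
      }
      f
    }
    f$n_frames <- 10L
    f
  }
  fd <- getFromNamespace("forest_divisions", "trackforest")
  gt <- mk_div_forest()
  gt_div <- fd(gt); gt_tr <- forest_tracks(gt)
  expect_length(gt_div, 2)
  expect_equal(cdf1(gt_div, gt_div, gt_tr, gt_tr)$cdf1, 1)
  # prediction missing both divisions entirely
  r0 <- cdf1(gt_div, list(), gt_tr, list())
  expect_equal(r0$cdf1, 0); expect_equal(r0$CDFN, 2L)
  # CDTP 2, CDFP 1, CDFN 1 -> 4/6 by direct substitution
  extra <- gt_div[[1]]; extra$frame <- 8L; extra$daughters <- c(98L, 99L)
  fake_tracks <- c(gt_tr, list(
    `98` = list(id = 98, frames = 8:9,
                cells = list(rect_cell(8, 98, 400, 400),
                             rect_cell(9, 98, 401, 400))),
    `99` = list(id = 99, frames = 8:9,
                cells = list(rect_cell(8, 99, 440, 440),
                             rect_cell(9, 99, 441, 440)))))
  gt3 <- c(gt_div, list(modifyList(gt_div[[2]], list(frame = 9L))))
  r1 <- cdf1(gt3, c(gt_div, list(extra)), gt_tr, fake_tracks)
  expect_equal(r1$CDTP, 2L); expect_equal(r1$CDFP, 1L)
  expect_equal(r1$CDFN, 1L)
  expect_equal(r1$cdf1, 2 * 2 / (2 * 2 + 1 + 1))
  # undefined with no divisions anywhere
  expect_true(is.na(cdf1(list(), list(), gt_tr, gt_tr)$cdf1))
  # daughters swapped between lineages never match
  wrong <- mk_div_forest(wrong_mother = TRUE)
  r2 <- cdf1(gt_div, fd(wrong), gt_tr, forest_tracks(wrong))
  expect_equal(r2$CDTP, 1L)
})

test_that("division matching respects the frame tolerance", {
  f <- new_forest()
  f <- new_tree(f, rect_cell(0, 1, 20, 20))
  b <- f$last_branch_id
  for (t in 1:4) f <- add_node(f, b, rect_cell(t, 1, 20 + 2 * t, 20))
  f <- open_division(f, b, rect_cell(5, 1, 14, 12, 7, 7),
                     rect_cell(5, 11, 34, 28, 7, 7), 5)
  d5 <- f$last_daughter_ids
  for (t in 6:8) {
    f <- add_node(f, d5[1], rect_cell(t, 1, 9 + t, 12, 7, 7))
    f <- add_node(f, d5[2], rect_cell(t, 11, 29 + t, 28, 7, 7))
  }
  g <- new_forest()
  g <- new_tree(g, rect_cell(0, 1, 20, 20))
  b2 <- g$last_branch_id
  for (t in 1:5) g <- add_node(g, b2, rect_cell(t, 1, 20 + 2 * t, 20))
  g <- open_division(g, b2, rect_cell(6, 1, 15, 12, 7, 7),
                     rect_cell(6, 11, 35, 28, 7, 7), 6)
  d6 <- g$last_daughter_ids
  for (t in 7:8) {
    g <- add_node(g, d6[1], rect_cell(t, 1, 9 + t, 12, 7, 7))
    g <- add_node(g, d6[2], rect_cell(t, 11, 29 + t, 28, 7, 7))
  }
  fd <- getFromNamespace("forest_divisions", "trackforest")
  m1 <- division_frame_tolerance(fd(f), fd(g), forest_tracks(f),
                                 forest_tracks(g), tol = 1)
  expect_equal(nrow(m1), 1)
  m0 <- division_frame_tolerance(fd(f), fd(g), forest_tracks(f),
                                 forest_tracks(g), tol = 0)
  expect_equal(nrow(m0), 0)
})

test_that("class_f1 computes one-vs-rest precision/recall/F1", {
  gt <- c(rep("A", 10), rep("B", 10))
  expect_equal(class_f1(gt, gt)$f1, c(1, 1))
  pred <- gt
  pred[c(1, 2)] <- "B"        # A: TP 8, FN 2; B: FP 2
  pred[c(11, 12)] <- "A"      # A: FP 2;      B: TP 8, FN 2
  r <- class_f1(gt, pred)
  expect_equal(r$precision, c(0.8, 0.8))
  expect_equal(r$recall, c(0.8, 0.8))
  expect_equal(r$f1, c(0.8, 0.8))
  expect_equal(class_f1(gt, rev(gt))$f1, c(0, 0))
})
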