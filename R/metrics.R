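# Tracking evaluation: detection matching, identity F1 (IDF1), multiple
# object tracking accuracy (MOTA), division-event F1 and per-class label F1.
# Identity assignment for IDF1 is solved exactly with a rectangular
# Hungarian algorithm (validated against exhaustive enumeration in the test
# suite). Gap-fill nodes are imputations, not detections, and are excluded
# from all detection-level counting.

# --- assignment solver -----------------------------------------------------

# exact min-cost rectangular assignment (rows <= cols), O(n^2 m)
hungarian_min <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)        # p[j+1] = row assigned to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1)
    used <- logical(m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_row <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) assign_row[p[j + 1]] <- j
  list(assignment = assign_row,
       cost = sum(cost[cbind(seq_len(n), assign_row)]))
}

# maximize total score over one-to-one assignments (rectangular allowed)
assignment_max <- function(score) {
  n <- nrow(score); m <- ncol(score)
  if (n == 0 || m == 0) return(list(assignment = integer(n), score = 0))
  flip <- n > m
  s <- if (flip) t(score) else score
  res <- hungarian_min(max(s) - s)
  sc <- sum(s[cbind(seq_len(nrow(s)), res$assignment)])
  if (flip) {
    a <- integer(n)
    a[res$assignment] <- seq_len(nrow(s))
    list(assignment = a, score = sc)
  } else {
    list(assignment = res$assignment, score = sc)
  }
}

# --- track containers ------------------------------------------------------

#' Convert a forest to per-branch tracks for evaluation
#'
#' Each branch becomes one track (a division hands both daughters new
#' identities, in both ground truth and prediction, so branch-level
#' identities compare like for like). Gap-fill nodes are dropped unless
#' requested.
#'
#' @param forest a `track_forest`.
#' @param include_gap_fill keep imputated nodes (default `FALSE`).
#' @return Named list of tracks; each track is a list with `id`, `frames`
#'   (integer vector) and `cells` (list of [cell_instance()]).
#' @export
forest_tracks <- function(forest, include_gap_fill = FALSE) {
  out <- list()
  for (br in forest$branches) {
    nodes <- br$nodes
    if (!include_gap_fill) {
      nodes <- Filter(function(nd) !nd$is_gap_fill, nodes)
    }
    if (length(nodes) == 0) next
    out[[as.character(br$branch_id)]] <- list(
      id = br$branch_id,
      frames = vapply(nodes, function(nd) nd$cell$frame, integer(1)),
      cells = lapply(nodes, function(nd) nd$cell))
  }
  out
}

# detections of all tracks at one frame: list of (track_pos, cell)
frame_detections <- function(tracks, frame) {
  out <- list()
  for (k in seq_along(tracks)) {
    hit <- which(tracks[[k]]$frames == frame)
    if (length(hit) == 1) {
      out[[length(out) + 1L]] <- list(track = k,
                                      cell = tracks[[k]]$cells[[hit]])
    }
  }
  out
}

# do two detections correspond? mode "iou": mask IoU >= iou_min;
# mode "id": equal instance ids (lineage-CSV evaluation, same segmentation)
det_match <- function(a, b, iou_min, mode = "iou") {
  if (mode == "id") {
    return(!is.na(a$instance_id) && !is.na(b$instance_id) &&
           a$instance_id == b$instance_id)
  }
  mask_iou(a, b) >= iou_min
}

det_score <- function(a, b, mode = "iou") {
  if (mode == "id") {
    return(as.numeric(!is.na(a$instance_id) && !is.na(b$instance_id) &&
                      a$instance_id == b$instance_id))
  }
  if (!bbox_intersects(a$bbox, b$bbox)) return(0)
  mask_iou(a, b)
}

#' Greedy one-to-one detection matching within a frame
#'
#' Pairs are taken in descending IoU, ties broken by `(gt_id, pred_id)`;
#' pairs below `iou_min` remain unmatched.
#'
#' @param gt_cells,pred_cells lists of [cell_instance()] from one frame.
#' @param iou_min IoU threshold (default 0.5, the MOT convention).
#' @param mode `"iou"` (default) or `"id"` (match by instance id, for
#'   lineage-CSV inputs that share a segmentation source).
#' @return 2-column matrix of `(gt, pred)` indices.
#' @export
match_detections <- function(gt_cells, pred_cells, iou_min = 0.5,
                             mode = "iou") {
  ng <- length(gt_cells); np <- length(pred_cells)
  if (ng == 0 || np == 0) return(matrix(integer(0), ncol = 2,
                                        dimnames = list(NULL, c("gt", "pred"))))
  sc <- matrix(0, ng, np)
  for (i in seq_len(ng)) for (j in seq_len(np)) {
    sc[i, j] <- det_score(gt_cells[[i]], pred_cells[[j]], mode)
  }
  thr <- if (mode == "id") 1 else iou_min
  idx <- which(sc >= thr, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(integer(0), ncol = 2,
                                    dimnames = list(NULL, c("gt", "pred"))))
  gid <- vapply(gt_cells, function(c) c$instance_id, integer(1))
  pid <- vapply(pred_cells, function(c) c$instance_id, integer(1))
  ord <- order(-sc[idx], gid[idx[, 1]], pid[idx[, 2]])
  idx <- idx[ord, , drop = FALSE]
  used_g <- logical(ng); used_p <- logical(np)
  out <- NULL
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (used_g[i] || used_p[j]) next
    used_g[i] <- TRUE; used_p[j] <- TRUE
    out <- rbind(out, c(i, j))
  }
  colnames(out) <- c("gt", "pred")
  out
}

# --- IDF1 ------------------------------------------------------------------

#' Identity F1 under the optimal global track assignment
#'
#' `IDF1 = 2 IDTP / (2 IDTP + IDFP + IDFN)` where `IDTP` is maximized over
#' one-to-one assignments of predicted to ground-truth track identities:
#' a frame contributes to `IDTP` for an assigned pair when both tracks have
#' a detection there and the detections correspond.
#'
#' @param gt_tracks,pred_tracks track lists from [forest_tracks()].
#' @param iou_min correspondence threshold.
#' @param mode `"iou"` or `"id"` (see [match_detections()]).
#' @return List with `idf1`, `IDTP`, `IDFP`, `IDFN`. Empty ground truth and
#'   empty prediction give `idf1 = 1`.
#' @export
idf1 <- function(gt_tracks, pred_tracks, iou_min = 0.5, mode = "iou") {
  total_gt <- sum(vapply(gt_tracks, function(tr) length(tr$frames), integer(1)))
  total_pred <- sum(vapply(pred_tracks, function(tr) length(tr$frames),
                           integer(1)))
  if (total_gt == 0 && total_pred == 0) {
    return(list(idf1 = 1, IDTP = 0L, IDFP = 0L, IDFN = 0L))
  }
  ng <- length(gt_tracks); np <- length(pred_tracks)
  overlap <- matrix(0L, ng, np)
  for (i in seq_len(ng)) {
    g <- gt_tracks[[i]]
    for (j in seq_len(np)) {
      p <- pred_tracks[[j]]
      common <- intersect(g$frames, p$frames)
      cnt <- 0L
      for (f in common) {
        a <- g$cells[[which(g$frames == f)]]
        b <- p$cells[[which(p$frames == f)]]
        if (det_match(a, b, iou_min, mode)) cnt <- cnt + 1L
      }
      overlap[i, j] <- cnt
    }
  }
  idtp <- if (ng == 0 || np == 0) 0 else assignment_max(overlap)$score
  idfp <- total_pred - idtp
  idfn <- total_gt - idtp
  list(idf1 = 2 * idtp / (2 * idtp + idfp + idfn),
       IDTP = as.integer(idtp), IDFP = as.integer(idfp),
       IDFN = as.integer(idfn))
}

# --- MOTA ------------------------------------------------------------------

#' Multiple object tracking accuracy
#'
#' `MOTA = 1 - sum_t(FN_t + FP_t + IDsw_t) / sum_t GT_t`, with per-frame
#' matching via [match_detections()] and an identity switch counted
#' whenever a ground-truth track's matched predicted identity changes
#' between its matched frames. Can be negative; undefined (`NA`) when the
#' ground truth has no detections.
#'
#' @inheritParams idf1
#' @return List with `mota`, `FP`, `FN`, `IDsw`, `GT`.
#' @export
mota <- function(gt_tracks, pred_tracks, iou_min = 0.5, mode = "iou") {
  frames <- sort(unique(c(unlist(lapply(gt_tracks, `[[`, "frames")),
                          unlist(lapply(pred_tracks, `[[`, "frames")))))
  gt_total <- 0L; fp <- 0L; fn <- 0L; idsw <- 0L
  last_match <- rep(NA_integer_, length(gt_tracks))
  for (f in frames) {
    gd <- frame_detections(gt_tracks, f)
    pd <- frame_detections(pred_tracks, f)
    gt_total <- gt_total + length(gd)
    mm <- match_detections(lapply(gd, `[[`, "cell"),
                           lapply(pd, `[[`, "cell"), iou_min, mode)
    fn <- fn + length(gd) - nrow(mm)
    fp <- fp + length(pd) - nrow(mm)
    for (k in seq_len(nrow(mm))) {
      gtrack <- gd[[mm[k, 1]]]$track
      ptrack <- pd[[mm[k, 2]]]$track
      if (!is.na(last_match[gtrack]) && last_match[gtrack] != ptrack) {
        idsw <- idsw + 1L
      }
      last_match[gtrack] <- ptrack
    }
  }
  if (gt_total == 0L) {
    return(list(mota = NA_real_, FP = fp, FN = fn, IDsw = idsw, GT = 0L))
  }
  list(mota = 1 - (fn + fp + idsw) / gt_total,
       FP = fp, FN = fn, IDsw = idsw, GT = gt_total)
}

# --- CDF1 ------------------------------------------------------------------

#' Match division events between truth and prediction
#'
#' A predicted division matches a ground-truth division when their frames
#' differ by at most `tol` and each of the two predicted daughters' first
#' detections corresponds to a detection of a distinct ground-truth
#' daughter branch (so both daughters sit in the correct lineage).
#'
#' @param gt_divisions,pred_divisions division lists (fields `frame`,
#'   `mother_branch`, `daughters`) as produced internally from a forest.
#' @param gt_tracks,pred_tracks track lists keyed by branch id, including
#'   at least the daughter branches.
#' @param tol frame tolerance (default 1).
#' @param iou_min correspondence threshold.
#' @param mode `"iou"` or `"id"`.
#' @return 2-column matrix of `(gt, pred)` division indices.
#' @export
division_frame_tolerance <- function(gt_divisions, pred_divisions,
                                     gt_tracks, pred_tracks, tol = 1L,
                                     iou_min = 0.5, mode = "iou") {
  daughters_agree <- function(g, p) {
    # score[a, b]: does pred daughter b's first detection lie in gt
    # daughter a's branch?
    hit <- matrix(FALSE, 2, 2)
    for (b in 1:2) {
      ptr <- pred_tracks[[as.character(p$daughters[b])]]
      if (is.null(ptr)) return(FALSE)
      pc <- ptr$cells[[1]]
      pf <- ptr$frames[1]
      for (a in 1:2) {
        gtr <- gt_tracks[[as.character(g$daughters[a])]]
        if (is.null(gtr)) next
        w <- which(gtr$frames == pf)
        if (length(w) == 1 && det_match(gtr$cells[[w]], pc, iou_min, mode)) {
          hit[a, b] <- TRUE
        }
      }
    }
    (hit[1, 1] && hit[2, 2]) || (hit[1, 2] && hit[2, 1])
  }
  out <- NULL
  used_g <- logical(length(gt_divisions))
  for (j in seq_along(pred_divisions)) {
    p <- pred_divisions[[j]]
    cand <- which(!used_g & vapply(gt_divisions, function(g)
      abs(g$frame - p$frame) <= tol, logical(1)))
    if (length(cand) > 1) {
      cand <- cand[order(vapply(gt_divisions[cand], function(g)
        abs(g$frame - p$frame), numeric(1)), cand)]
    }
    for (i in cand) {
      if (daughters_agree(gt_divisions[[i]], p)) {
        used_g[i] <- TRUE
        out <- rbind(out, c(i, j))
        break
      }
    }
  }
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  colnames(out) <- c("gt", "pred")
  out
}

#' Division-event F1 score
#'
#' `CDF1 = 2 CDTP / (2 CDTP + CDFP + CDFN)`: a predicted division is a true
#' positive iff both its daughters are assigned to the correct ground-truth
#' lineage (see [division_frame_tolerance()]); unmatched predicted
#' divisions are false positives, unmatched ground-truth divisions false
#' negatives. With no divisions on either side the score is undefined
#' (`NA`, reported as a dash).
#'
#' @inheritParams division_frame_tolerance
#' @return List with `cdf1`, `CDTP`, `CDFP`, `CDFN`.
#' @export
cdf1 <- function(gt_divisions, pred_divisions, gt_tracks, pred_tracks,
                 tol = 1L, iou_min = 0.5, mode = "iou") {
  if (length(gt_divisions) == 0 && length(pred_divisions) == 0) {
    return(list(cdf1 = NA_real_, CDTP = 0L, CDFP = 0L, CDFN = 0L))
  }
  mm <- division_frame_tolerance(gt_divisions, pred_divisions,
                                 gt_tracks, pred_tracks, tol, iou_min, mode)
  tp <- nrow(mm)
  fp <- length(pred_divisions) - tp
  fn <- length(gt_divisions) - tp
  list(cdf1 = 2 * tp / (2 * tp + fp + fn),
       CDTP = as.integer(tp), CDFP = as.integer(fp), CDFN = as.integer(fn))
}

# --- per-class F1 ----------------------------------------------------------

#' One-vs-rest precision, recall and F1 per class
#'
#' Expects label vectors already aligned by detection correspondence (for
#' forests over the same segmentation, by `(frame, instance_id)`).
#'
#' @param gt_labels,pred_labels aligned character vectors.
#' @return `data.frame` with one row per class present in either vector:
#'   `class`, `precision`, `recall`, `f1`, `support`. A class absent from
#'   both is not listed; degenerate denominators yield `NA`.
#' @export
class_f1 <- function(gt_labels, pred_labels) {
  stopifnot(length(gt_labels) == length(pred_labels))
  classes <- sort(unique(c(gt_labels[!is.na(gt_labels)],
                           pred_labels[!is.na(pred_labels)])))
  rows <- lapply(classes, function(cl) {
    tp <- sum(gt_labels == cl & pred_labels == cl, na.rm = TRUE)
    fp <- sum(pred_labels == cl & (is.na(gt_labels) | gt_labels != cl),
              na.rm = TRUE)
    fn <- sum(gt_labels == cl & (is.na(pred_labels) | pred_labels != cl),
              na.rm = TRUE)
    p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else
      if (identical(tp + fp + fn, 0L)) NA_real_ else 0
    data.frame(class = cl, precision = p, recall = r, f1 = f1,
               support = sum(gt_labels == cl, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# align labels of two forests over the same segmentation by
# (frame, instance_id); returns data.frame(gt, pred) label columns
align_forest_labels <- function(gt_forest, pred_forest,
                                pred_which = c("smoothed", "raw")) {
  pred_which <- match.arg(pred_which)
  tab <- function(forest, col) {
    rec <- export_lineage(forest)
    rec <- rec[!rec$is_gap_fill, c("frame", "instance_id", col)]
    names(rec)[3] <- "label"
    rec
  }
  g <- tab(gt_forest, "raw_class")
  p <- tab(pred_forest,
           if (pred_which == "smoothed") "smoothed_class" else "raw_class")
  m <- merge(g, p, by = c("frame", "instance_id"),
             suffixes = c("_gt", "_pred"))
  data.frame(gt = m$label_gt, pred = m$label_pred, stringsAsFactors = FALSE)
}
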