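# Fixture builders and independent oracles. Everything is generated in
# code; no binary data.

# a filled w x h rectangle instance at pixel (x, y) top-left
rect_cell <- function(frame, id, x, y, w = 10, h = 10, class_label = NULL,
                      intensity_value = NULL) {
  mask <- matrix(TRUE, h, w)
  intens <- if (!is.null(intensity_value)) {
    matrix(intensity_value, h, w) + outer(seq_len(h), seq_len(w)) * 0
  }
  instance_from_mask <- getFromNamespace("instance_from_mask", "trackforest")
  instance_from_mask(mask, c(x, y), frame, id, intensity = intens,
                     class_label = class_label)
}

# an ellipse-shaped instance (centre cx, cy)
ell_cell <- function(frame, id, cx, cy, a = 8, b = 6, theta = 0,
                     class_label = NULL, shape = c(512, 512)) {
  ras <- getFromNamespace("rasterize_ellipse", "trackforest")(
    cx, cy, a, b, theta, shape)
  getFromNamespace("instance_from_mask", "trackforest")(
    ras$mask, ras$offset, frame, id, class_label = class_label)
}

fseg <- function(frame, instances, shape = c(512, 512)) {
  frame_segmentation(frame, instances, shape)
}

# a movie of drifting rectangles: cells[[i]] = c(x0, y0); step px/frame
drift_movie <- function(n_frames, cells, step = 2, w = 10, h = 10,
                        shape = c(512, 512), classes = NULL) {
  lapply(seq_len(n_frames) - 1L, function(t) {
    insts <- lapply(seq_along(cells), function(i) {
      rect_cell(t, i, cells[[i]][1] + step * t, cells[[i]][2],
                w = w, h = h,
                class_label = if (!is.null(classes)) classes[[i]][t + 1L])
    })
    fseg(t, insts, shape)
  })
}

# --- independent metric oracles -------------------------------------------

perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# brute-force IDF1: enumerate every injective pred->gt identity assignment
brute_idf1 <- function(gt_tracks, pred_tracks, iou_min = 0.5) {
  det_match <- getFromNamespace("det_match", "trackforest")
  ng <- length(gt_tracks); np <- length(pred_tracks)
  total_gt <- sum(vapply(gt_tracks, function(tr) length(tr$frames), integer(1)))
  total_pred <- sum(vapply(pred_tracks, function(tr) length(tr$frames),
                           integer(1)))
  if (total_gt == 0 && total_pred == 0) return(1)
  overlap <- matrix(0L, ng, np)
  for (i in seq_len(ng)) for (j in seq_len(np)) {
    g <- gt_tracks[[i]]; p <- pred_tracks[[j]]
    for (f in intersect(g$frames, p$frames)) {
      a <- g$cells[[which(g$frames == f)]]
      b <- p$cells[[which(p$frames == f)]]
      if (det_match(a, b, iou_min, "iou")) overlap[i, j] <- overlap[i, j] + 1L
    }
  }
  n <- max(ng, np)
  pad <- matrix(0L, n, n)
  pad[seq_len(ng), seq_len(np)] <- overlap
  best <- 0L
  pp <- perms(n)
  for (r in seq_len(nrow(pp))) {
    best <- max(best, sum(pad[cbind(seq_len(n), pp[r, ])]))
  }
  2 * best / (2 * best + (total_pred - best) + (total_gt - best))
}

# independent MOTA: direct per-frame greedy counting, no shared code paths
brute_mota <- function(gt_tracks, pred_tracks, iou_min = 0.5) {
  frames <- sort(unique(c(unlist(lapply(gt_tracks, `[[`, "frames")),
                          unlist(lapply(pred_tracks, `[[`, "frames")))))
  fp <- fn <- idsw <- gt_total <- 0L
  last <- rep(NA_integer_, length(gt_tracks))
  for (f in frames) {
    gd <- list(); pd <- list()
    for (k in seq_along(gt_tracks)) {
      w <- which(gt_tracks[[k]]$frames == f)
      if (length(w)) gd[[length(gd) + 1L]] <- list(k = k,
        cell = gt_tracks[[k]]$cells[[w]])
    }
    for (k in seq_along(pred_tracks)) {
      w <- which(pred_tracks[[k]]$frames == f)
      if (length(w)) pd[[length(pd) + 1L]] <- list(k = k,
        cell = pred_tracks[[k]]$cells[[w]])
    }
    gt_total <- gt_total + length(gd)
    # greedy by descending IoU, ties by (gt instance id, pred instance id)
    cand <- NULL
    for (i in seq_along(gd)) for (j in seq_along(pd)) {
      v <- mask_iou(gd[[i]]$cell, pd[[j]]$cell)
      if (v >= iou_min) cand <- rbind(cand, c(i, j, v,
        gd[[i]]$cell$instance_id, pd[[j]]$cell$instance_id))
    }
    nm <- 0L
    if (!is.null(cand)) {
      cand <- cand[order(-cand[, 3], cand[, 4], cand[, 5]), , drop = FALSE]
      ug <- logical(length(gd)); up <- logical(length(pd))
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (ug[i] || up[j]) next
        ug[i] <- TRUE; up[j] <- TRUE
        nm <- nm + 1L
        gk <- gd[[i]]$k; pk <- pd[[j]]$k
        if (!is.na(last[gk]) && last[gk] != pk) idsw <- idsw + 1L
        last[gk] <- pk
      }
    }
    fn <- fn + length(gd) - nm
    fp <- fp + length(pd) - nm
  }
  1 - (fn + fp + idsw) / gt_total
}

# brute-force maximum-score assignment by permutation enumeration
brute_assignment_max <- function(score) {
  n <- nrow(score); m <- ncol(score)
  nn <- max(n, m)
  pad <- matrix(0, nn, nn)
  pad[seq_len(n), seq_len(m)] <- score
  best <- -Inf
  pp <- perms(nn)
  for (r in seq_len(nrow(pp))) {
    best <- max(best, sum(pad[cbind(seq_len(nn), pp[r, ])]))
  }
  best
}

read_b64_fixture <- function(name) {
  jsonlite::base64_dec(readChar(test_path("fixtures", name),
                                nchars = 1e7))
}
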