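# Post-tracking repair. Order matters and is tested: singleton pruning ->
# fragment linking -> short-track filtering -> gap filling. Fragment linking
# runs before the short-track filter so two short fragments that join into a
# long track survive it.

#' Remove single-node trees (false-positive detections)
#'
#' A tree whose total node count is 1 had no linkable detection in any
#' neighbouring frame and is taken to be a spurious detection.
#'
#' @param forest a `track_forest`.
#' @return List with `forest` (pruned) and `pruned` (the removed
#'   [cell_instance()]s).
#' @export
prune_singletons <- function(forest) {
  pruned <- list()
  for (tid in forest_tree_ids(forest)) {
    brs <- tree_branches(forest, tid)
    n <- sum(vapply(brs, function(b) length(b$nodes), integer(1)))
    if (n == 1) {
      pruned[[length(pruned) + 1L]] <- brs[[1]]$nodes[[1]]$cell
      forest$branches[[as.character(brs[[1]]$branch_id)]] <- NULL
    }
  }
  list(forest = forest, pruned = pruned)
}

# candidate fragment pairs: (leaf branch A ending t_e, tree root B starting
# t_s), 0 < t_s - t_e <= gap, A's tip centroid inside B's first instance's
# expanded box
fragment_candidates <- function(forest, config, image_shape = NULL) {
  kids <- vapply(forest$branches, function(b)
    ifelse(is.na(b$parent_branch_id), -1L, b$parent_branch_id), integer(1))
  leaves <- Filter(function(b) !(b$branch_id %in% kids), forest$branches)
  roots <- Filter(function(b) is.na(b$parent_branch_id), forest$branches)
  out <- NULL
  for (a in leaves) {
    ta <- branch_tip_frame(a)
    tip <- branch_tip(a)$cell
    for (b in roots) {
      if (b$tree_id == a$tree_id) next
      ts <- branch_first_frame(b)
      gap <- ts - ta
      if (gap <= 0 || gap > config$fragment_link_gap) next
      head_cell <- b$nodes[[1]]$cell
      ec <- expand_bbox(head_cell$bbox, config$alpha, image_shape)
      if (!point_in_bbox(tip$centroid[1], tip$centroid[2], ec)) next
      out <- rbind(out, data.frame(
        a = a$branch_id, b = b$branch_id, t_s = ts,
        total = sim_total(tip, head_cell, config$weights)))
    }
  }
  out
}

#' Link track fragments across short gaps
#'
#' For a tree A ending at frame `t_e` and a tree B starting at `t_s` with
#' `0 < t_s - t_e <= fragment_link_gap` and A's last centroid inside B's
#' first instance's expanded search box, B is appended onto A's terminal
#' branch. Competing candidates are resolved one-to-one by the similarity of
#' the terminal instances, processing in ascending `t_s`.
#'
#' @param forest a `track_forest` (singletons pruned).
#' @param config a [tracker_config()].
#' @param image_shape optional `c(height, width)` for box clipping.
#' @return List with `forest` and `n_linked`.
#' @export
link_fragments <- function(forest, config = tracker_config(),
                           image_shape = NULL) {
  cand <- fragment_candidates(forest, config, image_shape)
  n_linked <- 0L
  if (!is.null(cand)) {
    cand <- cand[order(cand$t_s, -cand$total, cand$a, cand$b), , drop = FALSE]
    used_a <- integer(0); used_b <- integer(0)
    for (k in seq_len(nrow(cand))) {
      a_id <- cand$a[k]; b_id <- cand$b[k]
      if (a_id %in% used_a || b_id %in% used_b) next
      a <- forest$branches[[as.character(a_id)]]
      b <- forest$branches[[as.character(b_id)]]
      # the chain a <- b may itself have been relabelled by an earlier merge
      if (is.null(a) || is.null(b)) next
      old_tree <- b$tree_id
      # splice B's root nodes onto A's terminal branch
      a$nodes <- c(a$nodes, b$nodes)
      a$closed <- b$closed
      a$last_division_frame <- max(a$last_division_frame,
                                   b$last_division_frame)
      forest$branches[[as.character(a_id)]] <- a
      forest$branches[[as.character(b_id)]] <- NULL
      # re-home the rest of B's tree
      for (key in names(forest$branches)) {
        br <- forest$branches[[key]]
        if (br$tree_id == old_tree) {
          br$tree_id <- a$tree_id
          if (!is.na(br$parent_branch_id) && br$parent_branch_id == b_id) {
            br$parent_branch_id <- a_id
          }
          forest$branches[[key]] <- br
        }
      }
      used_a <- c(used_a, a_id); used_b <- c(used_b, b_id)
      n_linked <- n_linked + 1L
    }
  }
  list(forest = forest, n_linked = n_linked)
}

#' Discard short tracks
#'
#' Trees spanning fewer than `min_track_span` frames are discarded as false
#' detections, except trees still open at the movie's final frame (they may
#' simply have entered late) and, in movies shorter than the span threshold,
#' trees rooted at frame 0.
#'
#' @param forest a `track_forest`.
#' @param min_track_span span threshold in frames.
#' @param n_frames movie length; defaults to `forest$n_frames`.
#' @return List with `forest` and `n_discarded`.
#' @export
discard_short_trees <- function(forest, min_track_span = 10L,
                                n_frames = forest$n_frames) {
  stopifnot(!is.na(n_frames))
  n_discarded <- 0L
  for (tid in forest_tree_ids(forest)) {
    rng <- tree_frame_range(forest, tid)
    span <- rng[2] - rng[1] + 1L
    if (span >= min_track_span) next
    if (rng[2] == n_frames - 1L) next                       # still open at end
    if (n_frames < min_track_span && rng[1] == 0L) next     # short movie
    for (b in tree_branches(forest, tid)) {
      forest$branches[[as.character(b$branch_id)]] <- NULL
    }
    n_discarded <- n_discarded + 1L
  }
  list(forest = forest, n_discarded = n_discarded)
}

#' Fill intra-branch frame gaps with cached segmentations
#'
#' Every missing frame inside a branch receives a copy of the nearest
#' preceding real node's geometry and class, flagged `is_gap_fill`, making
#' all branches frame-contiguous. No real node is ever altered.
#'
#' @param forest a `track_forest`.
#' @return List with `forest` and `n_filled`.
#' @export
fill_gaps <- function(forest) {
  n_filled <- 0L
  for (key in names(forest$branches)) {
    br <- forest$branches[[key]]
    if (length(br$nodes) < 2) next
    out <- list(br$nodes[[1]])
    for (k in 2:length(br$nodes)) {
      prev <- out[[length(out)]]
      nxt <- br$nodes[[k]]
      gap_frames <- seq(prev$cell$frame + 1L, nxt$cell$frame - 1L,
                        length.out = max(0, nxt$cell$frame - prev$cell$frame - 1L))
      for (f in gap_frames) {
        filler <- prev
        filler$cell$frame <- as.integer(f)
        filler$is_gap_fill <- TRUE
        out[[length(out) + 1L]] <- filler
        n_filled <- n_filled + 1L
      }
      out[[length(out) + 1L]] <- nxt
    }
    br$nodes <- out
    forest$branches[[key]] <- br
  }
  list(forest = forest, n_filled = n_filled)
}

#' Run all four refinement passes in order
#'
#' @param forest raw forest from [track()].
#' @param config a [tracker_config()].
#' @param image_shape optional `c(height, width)`.
#' @return List with `forest` and the per-pass counts `n_pruned`,
#'   `n_linked`, `n_discarded`, `n_filled`.
#' @export
refine_forest <- function(forest, config = tracker_config(),
                          image_shape = NULL) {
  p <- prune_singletons(forest)
  l <- link_fragments(p$forest, config, image_shape)
  d <- discard_short_trees(l$forest, config$min_track_span)
  g <- fill_gaps(d$forest)
  list(forest = g$forest, n_pruned = length(p$pruned),
       n_linked = l$n_linked, n_discarded = d$n_discarded,
       n_filled = g$n_filled)
}
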