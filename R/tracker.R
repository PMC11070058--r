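# Hierarchical linking cascade. Per frame, in order: unique-overlap links ->
# similarity resolution of contested links -> expanded-box search ->
# division detection -> cache matching -> new-tree initialization. Every
# instance receives exactly one link decision; all tie-breaks are total
# orders, so the tracker is deterministic.

sim_total <- function(ci, cj, weights) {
  suppressMessages(similarity_index(ci, cj, weights)$total)
}

#' Partition current-frame instances by overlap with previous-frame tips
#'
#' An instance overlapping (mask IoU > 0) exactly one tip, that tip itself
#' overlapping no other instance, is a high-confidence unique link.
#' Instances and tips in many-to-many overlap form contested groups
#' (connected components of the overlap graph). Instances with no overlap
#' are orphans. Every instance lands in exactly one of the three outputs.
#'
#' @param tips list of [cell_instance()]: the cached tips of the open
#'   branches (the previous frame's instances, plus tips that have aged up
#'   to the cache horizon while their cell went undetected).
#' @param instances list of [cell_instance()] (current frame).
#' @return List with `unique` (2-column matrix of `(tip, instance)`
#'   indices), `contested` (list of groups, each with `tips` and
#'   `instances` index vectors) and `orphans` (instance indices).
#' @export
link_by_overlap <- function(tips, instances) {
  nt <- length(tips); ni <- length(instances)
  ov <- matrix(FALSE, nrow = nt, ncol = ni)
  if (nt > 0 && ni > 0) {
    for (i in seq_len(nt)) {
      for (j in seq_len(ni)) {
        if (bbox_intersects(tips[[i]]$bbox, instances[[j]]$bbox) &&
            mask_overlap_area(tips[[i]]$mask, tips[[i]]$offset,
                              instances[[j]]$mask, instances[[j]]$offset) > 0) {
          ov[i, j] <- TRUE
        }
      }
    }
  }
  inst_deg <- colSums(ov)
  tip_deg <- rowSums(ov)
  uniq <- NULL
  for (j in seq_len(ni)) {
    if (inst_deg[j] == 1) {
      i <- which(ov[, j])
      if (tip_deg[i] == 1) uniq <- rbind(uniq, c(i, j))
    }
  }
  if (is.null(uniq)) uniq <- matrix(integer(0), ncol = 2)
  colnames(uniq) <- c("tip", "instance")
  # contested: connected components of the remaining overlap graph
  rem <- ov
  if (nrow(uniq) > 0) {
    rem[uniq[, 1], ] <- FALSE
    rem[, uniq[, 2]] <- FALSE
  }
  contested <- list()
  seen_t <- logical(nt); seen_i <- logical(ni)
  for (j in seq_len(ni)) {
    if (seen_i[j] || sum(rem[, j]) == 0) next
    # grow component
    gi <- j; gt <- integer(0)
    repeat {
      new_t <- setdiff(which(apply(rem[, gi, drop = FALSE], 1, any)), gt)
      if (length(new_t) == 0) break
      gt <- sort(c(gt, new_t))
      new_i <- setdiff(which(apply(rem[gt, , drop = FALSE], 2, any)), gi)
      gi <- sort(c(gi, new_i))
      if (length(new_i) == 0) break
    }
    seen_i[gi] <- TRUE; seen_t[gt] <- TRUE
    contested[[length(contested) + 1L]] <- list(tips = gt, instances = gi)
  }
  orphans <- which(inst_deg == 0)
  list(unique = uniq, contested = contested, orphans = orphans)
}

#' Resolve a contested overlap group by similarity
#'
#' Greedy one-to-one assignment over all (tip, instance) pairs of the group
#' in descending similarity-index total; exact ties go to the smaller
#' instance id, then the smaller tip position. Leftover instances and tips
#' are returned unmatched.
#'
#' @param tips,instances lists of [cell_instance()] forming the group.
#' @param weights similarity weights, see [similarity_index()].
#' @return List with `pairs` (2-column matrix of `(tip, instance)` indices),
#'   `unmatched_tips`, `unmatched_instances`.
#' @export
resolve_contested <- function(tips, instances, weights = c(1, 1, 1, 1, 1)) {
  nt <- length(tips); ni <- length(instances)
  if (nt == 0 || ni == 0) {
    return(list(pairs = matrix(integer(0), ncol = 2),
                unmatched_tips = seq_len(nt),
                unmatched_instances = seq_len(ni)))
  }
  cand <- expand.grid(tip = seq_len(nt), instance = seq_len(ni))
  cand$total <- mapply(function(i, j)
    sim_total(tips[[i]], instances[[j]], weights), cand$tip, cand$instance)
  cand$iid <- vapply(instances[cand$instance], function(ci) ci$instance_id,
                     integer(1))
  cand <- cand[order(-cand$total, cand$iid, cand$tip), , drop = FALSE]
  used_t <- logical(nt); used_i <- logical(ni)
  pairs <- NULL
  for (k in seq_len(nrow(cand))) {
    i <- cand$tip[k]; j <- cand$instance[k]
    if (used_t[i] || used_i[j]) next
    used_t[i] <- TRUE; used_i[j] <- TRUE
    pairs <- rbind(pairs, c(i, j))
  }
  if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 2)
  colnames(pairs) <- c("tip", "instance")
  list(pairs = pairs,
       unmatched_tips = which(!used_t),
       unmatched_instances = which(!used_i))
}

#' Candidate tips inside an orphan's expanded search box
#'
#' Tips whose centroid lies inside the orphan's bounding box expanded by
#' `alpha` (clipped to the image), sorted best-similarity first.
#'
#' @param orphan a [cell_instance()] with no overlap link.
#' @param tips list of candidate [cell_instance()]s.
#' @param alpha expansion coefficient.
#' @param image_shape optional `c(height, width)` for clipping.
#' @param weights similarity weights.
#' @return Integer indices into `tips`, sorted by descending similarity.
#' @export
expanded_search_candidates <- function(orphan, tips, alpha = 1.5,
                                       image_shape = NULL,
                                       weights = c(1, 1, 1, 1, 1)) {
  if (length(tips) == 0) return(integer(0))
  ec <- expand_bbox(orphan$bbox, alpha, image_shape)
  inside <- vapply(tips, function(tp)
    point_in_bbox(tp$centroid[1], tp$centroid[2], ec), logical(1))
  idx <- which(inside)
  if (length(idx) <= 1) return(idx)
  tot <- vapply(idx, function(i) sim_total(tips[[i]], orphan, weights),
                numeric(1))
  idx[order(-tot, idx)]
}

#' Test an orphan against candidate mother cells
#'
#' A mother qualifies iff (a) her previous-frame area is at least
#' `division_size_ratio` times the orphan's area, (b) her lineage has not
#' divided within the last `division_cooldown` frames, (c) her centroid lies
#' inside the orphan's expanded search box, and (d) when class labels are in
#' use, her raw class is `"M"` (mitosis). Among several qualifying mothers
#' the highest similarity to the orphan wins.
#'
#' @param orphan an unlinked [cell_instance()] at `frame`.
#' @param mothers list of candidate records, each
#'   `list(cell = <tip instance at frame - 1>, last_division_frame = <frame
#'   or -Inf>, branch_id = <id>)`.
#' @param config a [tracker_config()].
#' @param frame current frame index.
#' @param use_class whether the M-phase rule is active.
#' @param image_shape optional for box clipping.
#' @return The qualifying candidate's `branch_id`, or `NULL`.
#' @export
detect_division <- function(orphan, mothers, config, frame,
                            use_class = FALSE, image_shape = NULL) {
  if (length(mothers) == 0) return(NULL)
  ec <- expand_bbox(orphan$bbox, config$alpha, image_shape)
  ok <- vapply(mothers, function(m) {
    tip <- m$cell
    if (tip$area < config$division_size_ratio * orphan$area) return(FALSE)
    if (frame - m$last_division_frame <= config$division_cooldown) return(FALSE)
    if (!point_in_bbox(tip$centroid[1], tip$centroid[2], ec)) return(FALSE)
    if (use_class) {
      cls <- tip$class_label
      if (is.null(cls) || is.na(cls) || cls != "M") return(FALSE)
    }
    TRUE
  }, logical(1))
  idx <- which(ok)
  if (length(idx) == 0) return(NULL)
  if (length(idx) > 1) {
    tot <- vapply(idx, function(i)
      sim_total(mothers[[i]]$cell, orphan, config$weights), numeric(1))
    bid <- vapply(idx, function(i) mothers[[i]]$branch_id, integer(1))
    idx <- idx[order(-tot, bid)]
  }
  mothers[[idx[1]]]$branch_id
}

#' Cache search for an orphan among recently stalled branches
#'
#' Among open branches whose tip ended between 2 and `cache_depth` frames
#' ago and whose tip centroid lies inside the orphan's expanded search box,
#' the branch with the highest tip similarity is returned.
#'
#' @param orphan an unlinked [cell_instance()] at `frame`.
#' @param forest the current `track_forest`.
#' @param config a [tracker_config()].
#' @param frame current frame index.
#' @param image_shape optional for box clipping.
#' @param exclude branch ids already consumed this frame.
#' @return A branch id, or `NULL`.
#' @export
cache_match <- function(orphan, forest, config, frame, image_shape = NULL,
                        exclude = integer(0)) {
  ec <- expand_bbox(orphan$bbox, config$alpha, image_shape)
  best_id <- NULL; best_tot <- -Inf
  for (br in forest$branches) {
    if (br$closed || br$branch_id %in% exclude) next
    tf <- branch_tip_frame(br)
    gap <- frame - tf
    if (gap < 2 || gap > config$cache_depth) next
    tip <- branch_tip(br)$cell
    if (!point_in_bbox(tip$centroid[1], tip$centroid[2], ec)) next
    tot <- sim_total(tip, orphan, config$weights)
    if (tot > best_tot ||
        (tot == best_tot && !is.null(best_id) && br$branch_id < best_id)) {
      best_tot <- tot; best_id <- br$branch_id
    }
  }
  best_id
}

#' Track a timelapse of frame segmentations into a lineage forest
#'
#' Initializes one tree per instance of the first frame, then applies the
#' hierarchical cascade frame by frame. The returned forest is raw: run
#' [refine_forest()] (and [apply_tcs()] for class labels) afterwards, or use
#' [run_pipeline()] for the whole thing.
#'
#' @param frames list of [frame_segmentation()] sorted by frame index; may
#'   contain empty frames.
#' @param config a [tracker_config()].
#' @param verbose emit one message per non-unique link decision.
#' @return The raw `track_forest`; the per-instance audit trail is attached
#'   as `attr(forest, "decisions")`, a `data.frame` with one row per input
#'   instance (`frame`, `instance_id`, `outcome`, `branch_id`,
#'   `similarity`).
#' @export
track <- function(frames, config = tracker_config(), verbose = FALSE) {
  forest <- new_forest()
  decisions <- list()
  say <- function(...) if (verbose) message(...)
  if (length(frames) == 0) return(forest)
  image_shape <- frames[[1]]$image_shape
  has_class <- any(vapply(frames, function(fs)
    any(vapply(fs$instances, function(ci) !is.null(ci$class_label), logical(1))),
    logical(1)))
  use_class <- if (identical(config$use_class_for_division, "auto")) has_class
               else isTRUE(config$use_class_for_division)
  record <- function(frame, iid, outcome, branch_id, similarity = NA_real_) {
    decisions[[length(decisions) + 1L]] <<- data.frame(
      frame = frame, instance_id = iid, outcome = outcome,
      branch_id = branch_id, similarity = similarity,
      stringsAsFactors = FALSE)
  }
  first <- TRUE
  for (fs in frames) {
    t <- fs$frame
    insts <- fs$instances
    if (first) {
      # every instance of the first (possibly empty) frame roots a tree;
      # later frames fall through to the cascade, whose new-tree stage
      # covers frame-0 dropouts as well
      first <- FALSE
      for (ci in insts) {
        forest <- new_tree(forest, ci)
        record(t, ci$instance_id, "new_tree", forest$last_branch_id)
      }
      next
    }
    # linking pool: open branches whose tips have aged at most cache_depth
    # frames. An aged tip is the branch's cached segmentation; a current
    # instance that still overlaps it is a high-confidence link, which keeps
    # briefly-dropped cells out of the reach of foreign tips. The expanded
    # search and the division rules below only consider previous-frame
    # (gap 1) tips; older ones fall to the cache stage.
    tip_ids <- integer(0); tip_cells <- list(); tip_gap <- integer(0)
    for (br in forest$branches) {
      if (!br$closed) {
        g <- t - branch_tip_frame(br)
        if (g >= 1L && g <= config$cache_depth) {
          tip_ids <- c(tip_ids, br$branch_id)
          tip_cells[[length(tip_cells) + 1L]] <- branch_tip(br)$cell
          tip_gap <- c(tip_gap, g)
        }
      }
    }
    linked_inst <- logical(length(insts))         # instance handled
    tip_taken <- logical(length(tip_ids))         # tip consumed this frame
    continuation <- rep(NA_integer_, length(tip_ids))  # instance linked to tip
    link <- function(ti, j, outcome, similarity = NA_real_) {
      forest <<- add_node(forest, tip_ids[ti], insts[[j]])
      tip_taken[ti] <<- TRUE
      continuation[ti] <<- j
      linked_inst[j] <<- TRUE
      record(t, insts[[j]]$instance_id, outcome, tip_ids[ti], similarity)
    }
    ov <- link_by_overlap(tip_cells, insts)
    for (k in seq_len(nrow(ov$unique))) {
      link(ov$unique[k, 1], ov$unique[k, 2], "linked_unique")
    }
    for (grp in ov$contested) {
      res <- resolve_contested(tip_cells[grp$tips], insts[grp$instances],
                               config$weights)
      for (k in seq_len(nrow(res$pairs))) {
        ti <- grp$tips[res$pairs[k, 1]]
        j <- grp$instances[res$pairs[k, 2]]
        tot <- sim_total(tip_cells[[ti]], insts[[j]], config$weights)
        link(ti, j, "linked_by_similarity", tot)
        say("frame ", t, ": instance ", insts[[j]]$instance_id,
            " linked by similarity to branch ", tip_ids[ti])
      }
    }
    # expanded search: orphans against unmatched active tips
    orphans <- which(!linked_inst)
    orphans <- orphans[order(vapply(insts[orphans], function(ci)
      ci$instance_id, integer(1)))]
    for (j in orphans) {
      free <- which(!tip_taken & tip_gap == 1L)
      if (length(free) == 0) break
      cand <- expanded_search_candidates(insts[[j]], tip_cells[free],
                                         config$alpha, image_shape,
                                         config$weights)
      if (length(cand) > 0) {
        ti <- free[cand[1]]
        tot <- sim_total(tip_cells[[ti]], insts[[j]], config$weights)
        link(ti, j, "linked_expanded", tot)
        say("frame ", t, ": instance ", insts[[j]]$instance_id,
            " linked via expanded search to branch ", tip_ids[ti])
      }
    }
    # division detection: remaining orphans against tips that found a
    # linked continuation this frame (a division needs two daughters)
    orphans <- which(!linked_inst)
    orphans <- orphans[order(vapply(insts[orphans], function(ci)
      ci$instance_id, integer(1)))]
    for (j in orphans) {
      cont <- which(!is.na(continuation) & tip_gap == 1L)
      if (length(cont) == 0) break
      mothers <- lapply(cont, function(ti) {
        br <- forest$branches[[as.character(tip_ids[ti])]]
        list(cell = tip_cells[[ti]],
             last_division_frame = br$last_division_frame,
             branch_id = tip_ids[ti])
      })
      mb <- detect_division(insts[[j]], mothers, config, t,
                            use_class = use_class, image_shape = image_shape)
      if (!is.null(mb)) {
        ti <- cont[match(mb, tip_ids[cont])]
        jcont <- continuation[ti]
        # retract the continuation link, then branch
        key <- as.character(mb)
        br <- forest$branches[[key]]
        br$nodes <- br$nodes[-length(br$nodes)]
        forest$branches[[key]] <- br
        d <- insts[c(jcont, j)]
        ord <- order(vapply(d, function(ci) ci$instance_id, integer(1)))
        forest <- open_division(forest, mb, d[[ord[1]]], d[[ord[2]]], t)
        did <- forest$last_daughter_ids
        continuation[ti] <- NA_integer_  # branch closed; no longer a mother
        linked_inst[j] <- TRUE
        # rewrite both decisions
        for (m in seq_along(decisions)) {
          dd <- decisions[[m]]
          if (dd$frame == t && dd$instance_id == insts[[jcont]]$instance_id) {
            decisions[[m]]$outcome <- "division_daughter"
            decisions[[m]]$branch_id <- did[which(ord == 1)]
          }
        }
        record(t, insts[[j]]$instance_id, "division_daughter",
               did[which(ord == 2)])
        say("frame ", t, ": division of branch ", mb, " into ",
            did[1], "/", did[2])
      }
    }
    # cache matching for the rest
    cache_used <- integer(0)
    orphans <- which(!linked_inst)
    orphans <- orphans[order(vapply(insts[orphans], function(ci)
      ci$instance_id, integer(1)))]
    for (j in orphans) {
      bid <- cache_match(insts[[j]], forest, config, t, image_shape,
                         exclude = cache_used)
      if (!is.null(bid)) {
        forest <- add_node(forest, bid, insts[[j]])
        cache_used <- c(cache_used, bid)
        linked_inst[j] <- TRUE
        record(t, insts[[j]]$instance_id, "cache_relinked", bid)
        say("frame ", t, ": instance ", insts[[j]]$instance_id,
            " cache-relinked to branch ", bid)
      }
    }
    # new trees for whatever is left
    for (j in which(!linked_inst)) {
      forest <- new_tree(forest, insts[[j]])
      record(t, insts[[j]]$instance_id, "new_tree", forest$last_branch_id)
      say("frame ", t, ": instance ", insts[[j]]$instance_id,
          " starts tree ", forest$last_tree_id)
    }
  }
  forest$n_frames <- max(vapply(frames, function(fs) fs$frame, integer(1))) + 1L
  dec <- if (length(decisions)) do.call(rbind, decisions) else
    data.frame(frame = integer(0), instance_id = integer(0),
               outcome = character(0), branch_id = integer(0),
               similarity = numeric(0))
  attr(forest, "decisions") <- dec
  forest
}
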