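#' Lineage forest of tracked cells
#'
#' A `track_forest` holds a set of lineage trees. Each tree is a set of
#' branches: a branch is a frame-ordered run of nodes (one segmented cell
#' instance per frame), and a division event closes the mother branch and
#' opens exactly two daughter branches. Branch and tree ids are assigned
#' from incrementing counters in processing order, so runs are reproducible.
#'
#' Branches are stored flat, keyed by branch id; each carries its `tree_id`
#' and `parent_branch_id` (`NA` for roots).
#'
#' @return An empty forest.
#' @export
new_forest <- function() {
  structure(list(branches = list(), next_branch_id = 1L, next_tree_id = 1L,
                 n_frames = NA_integer_),
            class = "track_forest")
}

new_track_node <- function(cell, is_gap_fill = FALSE) {
  list(cell = cell, is_gap_fill = is_gap_fill,
       raw_class = if (is.null(cell$class_label)) NA_character_ else cell$class_label,
       smoothed_class = NA_character_)
}

#' Start a new tree from a single cell instance
#'
#' @param forest a [new_forest()].
#' @param cell a [cell_instance()].
#' @return The modified forest; the new branch id is in
#'   `forest$last_branch_id` and the tree id in `forest$last_tree_id`.
#' @export
new_tree <- function(forest, cell) {
  bid <- forest$next_branch_id
  tid <- forest$next_tree_id
  forest$branches[[as.character(bid)]] <- list(
    branch_id = bid, tree_id = tid, parent_branch_id = NA_integer_,
    nodes = list(new_track_node(cell)), closed = FALSE,
    last_division_frame = -Inf)
  forest$next_branch_id <- bid + 1L
  forest$next_tree_id <- tid + 1L
  forest$last_branch_id <- bid
  forest$last_tree_id <- tid
  forest
}

branch_tip <- function(branch) branch$nodes[[length(branch$nodes)]]
branch_tip_frame <- function(branch) branch_tip(branch)$cell$frame
branch_first_frame <- function(branch) branch$nodes[[1]]$cell$frame

#' Append a cell instance to a branch
#'
#' @param forest a `track_forest`.
#' @param branch_id id of an existing branch.
#' @param cell a [cell_instance()] whose frame is strictly after the branch
#'   tip frame.
#' @param is_gap_fill flag for nodes synthesized by gap filling.
#' @return The modified forest.
#' @export
add_node <- function(forest, branch_id, cell, is_gap_fill = FALSE) {
  key <- as.character(branch_id)
  br <- forest$branches[[key]]
  if (is.null(br)) stop("no such branch: ", branch_id, call. = FALSE)
  if (length(br$nodes) > 0 && cell$frame <= branch_tip_frame(br)) {
    stop("ordering error: frame ", cell$frame, " not after branch tip frame ",
         branch_tip_frame(br), call. = FALSE)
  }
  br$nodes[[length(br$nodes) + 1L]] <- new_track_node(cell, is_gap_fill)
  forest$branches[[key]] <- br
  forest
}

#' Branch a tree at a division event
#'
#' Closes the mother branch at `frame - 1` and opens exactly two daughter
#' branches starting at `frame`, inheriting the mother's tree and recording
#' `frame` as the last division frame of both daughters (for the division
#' cooldown rule).
#'
#' @param forest a `track_forest`.
#' @param mother_branch_id branch whose tip must be at `frame - 1`.
#' @param daughter_a,daughter_b the two daughter [cell_instance()]s at
#'   `frame`.
#' @param frame the division frame.
#' @return The modified forest; the daughter branch ids are in
#'   `forest$last_daughter_ids`.
#' @export
open_division <- function(forest, mother_branch_id, daughter_a, daughter_b,
                          frame) {
  key <- as.character(mother_branch_id)
  mother <- forest$branches[[key]]
  if (is.null(mother)) stop("no such branch: ", mother_branch_id, call. = FALSE)
  if (mother$closed) stop("state error: mother branch already closed", call. = FALSE)
  if (branch_tip_frame(mother) != frame - 1L) {
    stop("state error: mother tip at frame ", branch_tip_frame(mother),
         ", division at frame ", frame, call. = FALSE)
  }
  mother$closed <- TRUE
  mother$last_division_frame <- frame
  forest$branches[[key]] <- mother
  ids <- integer(2)
  daughters <- list(daughter_a, daughter_b)
  for (k in 1:2) {
    bid <- forest$next_branch_id
    forest$branches[[as.character(bid)]] <- list(
      branch_id = bid, tree_id = mother$tree_id,
      parent_branch_id = mother$branch_id,
      nodes = list(new_track_node(daughters[[k]])), closed = FALSE,
      last_division_frame = frame)
    forest$next_branch_id <- bid + 1L
    ids[k] <- bid
  }
  forest$last_daughter_ids <- ids
  forest
}

forest_tree_ids <- function(forest) {
  sort(unique(vapply(forest$branches, function(b) b$tree_id, integer(1))))
}

tree_branches <- function(forest, tree_id) {
  Filter(function(b) b$tree_id == tree_id, forest$branches)
}

#' Frame span of a tree
#'
#' Last frame minus first frame plus one, over all nodes of all branches of
#' the tree.
#'
#' @param forest a `track_forest`.
#' @param tree_id tree id.
#' @return Integer frame count.
#' @export
tree_span <- function(forest, tree_id) {
  brs <- tree_branches(forest, tree_id)
  if (length(brs) == 0) stop("no such tree: ", tree_id, call. = FALSE)
  fr <- unlist(lapply(brs, function(b)
    vapply(b$nodes, function(n) n$cell$frame, integer(1))))
  max(fr) - min(fr) + 1L
}

tree_frame_range <- function(forest, tree_id) {
  brs <- tree_branches(forest, tree_id)
  fr <- unlist(lapply(brs, function(b)
    vapply(b$nodes, function(n) n$cell$frame, integer(1))))
  range(fr)
}

forest_n_nodes <- function(forest, real_only = TRUE) {
  sum(vapply(forest$branches, function(b) {
    if (real_only) sum(!vapply(b$nodes, function(n) n$is_gap_fill, logical(1)))
    else length(b$nodes)
  }, numeric(1)))
}

#' Flatten a forest to per-node lineage records
#'
#' One record per node, sorted by `(frame, tree_id, branch_id)`;
#' `parent_branch_id` is `NA` for root branches.
#'
#' @param forest a `track_forest`.
#' @return `data.frame` with columns `frame`, `tree_id`, `branch_id`,
#'   `parent_branch_id`, `instance_id`, `centroid_x`, `centroid_y`, `area`,
#'   `raw_class`, `smoothed_class`, `is_gap_fill`.
#' @export
export_lineage <- function(forest) {
  rows <- list()
  for (br in forest$branches) {
    for (nd in br$nodes) {
      rows[[length(rows) + 1L]] <- data.frame(
        frame = nd$cell$frame, tree_id = br$tree_id,
        branch_id = br$branch_id, parent_branch_id = br$parent_branch_id,
        instance_id = if (nd$is_gap_fill) NA_integer_ else nd$cell$instance_id,
        centroid_x = nd$cell$centroid[1], centroid_y = nd$cell$centroid[2],
        area = nd$cell$area,
        raw_class = nd$raw_class, smoothed_class = nd$smoothed_class,
        is_gap_fill = nd$is_gap_fill,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(frame = integer(0), tree_id = integer(0),
                      branch_id = integer(0), parent_branch_id = integer(0),
                      instance_id = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), area = numeric(0),
                      raw_class = character(0), smoothed_class = character(0),
                      is_gap_fill = logical(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$frame, out$tree_id, out$branch_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.track_forest <- function(x, ...) {
  tids <- forest_tree_ids(x)
  ndiv <- sum(vapply(x$branches, function(b) b$closed, logical(1)))
  cat(sprintf("track_forest: %d tree(s), %d branch(es), %d division(s), %d node(s)\n",
              length(tids), length(x$branches), ndiv,
              forest_n_nodes(x, real_only = FALSE)))
  invisible(x)
}

# divisions recorded in a forest: a closed branch with exactly two children
forest_divisions <- function(forest) {
  out <- list()
  kids <- split(
    vapply(forest$branches, function(b) b$branch_id, integer(1)),
    vapply(forest$branches, function(b)
      ifelse(is.na(b$parent_branch_id), -1L, b$parent_branch_id), integer(1)))
  for (key in names(kids)) {
    pid <- as.integer(key)
    if (pid < 0) next
    ids <- sort(unname(kids[[key]]))
    if (length(ids) == 2) {
      d1 <- forest$branches[[as.character(ids[1])]]
      out[[length(out) + 1L]] <- list(
        frame = branch_first_frame(d1),
        mother_branch = pid, daughters = ids,
        tree_id = d1$tree_id)
    }
  }
  # deterministic order
  if (length(out) > 1) {
    ord <- order(vapply(out, function(d) d$frame, integer(1)),
                 vapply(out, function(d) d$mother_branch, integer(1)))
    out <- out[ord]
  }
  out
}
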