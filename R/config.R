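#' Tracker configuration
#'
#' All tunable parameters of the tracking cascade, the refinement passes and
#' the class-smoothing step, with the published defaults. The design target
#' of the method is that none of these need adjusting across segmentation
#' qualities; the whole test suite runs at these defaults.
#'
#' @param alpha search-range coefficient: a cell's bounding box is expanded
#'   by `alpha` times its extent on every side when searching for candidates
#'   (default 1.5).
#' @param cache_depth how many preceding frames the cache search may reach
#'   back to re-link an orphan detection to a stalled branch (default 5).
#' @param fragment_link_gap maximum frame gap bridged when linking track
#'   fragments after tracking (default 3).
#' @param min_track_span tracks spanning fewer frames than this are
#'   discarded as false detections (default 10).
#' @param division_size_ratio a candidate mother must be at least this many
#'   times the area of the orphan daughter (default 1.3).
#' @param division_cooldown a lineage may not divide again within this many
#'   frames of its last division (default 50).
#' @param tcs_window forward search window, in nodes, of the class-smoothing
#'   rule (default 9).
#' @param tcs_threshold fraction of the window that must confirm a class
#'   change before it is adopted; strictly exceeded (default 0.60).
#' @param weights length-5 similarity weights `(iou, dis, sps, sas, delta)`,
#'   default all `+1`.
#' @param use_class_for_division `"auto"` (require an M-phase mother iff
#'   class labels are present), `TRUE` or `FALSE`.
#' @param hu_transform `"log"` (default) or `"raw"` Hu invariants.
#' @param seed integer seed recorded for reproducibility of any stochastic
#'   consumer; the tracker itself is deterministic.
#' @return Object of class `tracker_config`.
#' @export
tracker_config <- function(alpha = 1.5,
                           cache_depth = 5L,
                           fragment_link_gap = 3L,
                           min_track_span = 10L,
                           division_size_ratio = 1.3,
                           division_cooldown = 50L,
                           tcs_window = 9L,
                           tcs_threshold = 0.60,
                           weights = c(1, 1, 1, 1, 1),
                           use_class_for_division = "auto",
                           hu_transform = c("log", "raw"),
                           seed = 1L) {
  hu_transform <- match.arg(hu_transform)
  stopifnot(alpha >= 0, cache_depth >= 1, fragment_link_gap >= 0,
            min_track_span >= 1, division_size_ratio >= 1,
            division_cooldown >= 0, tcs_window >= 1,
            tcs_threshold >= 0, tcs_threshold <= 1,
            length(weights) == 5)
  stopifnot(identical(use_class_for_division, "auto") ||
            is.logical(use_class_for_division))
  structure(list(
    alpha = alpha, cache_depth = as.integer(cache_depth),
    fragment_link_gap = as.integer(fragment_link_gap),
    min_track_span = as.integer(min_track_span),
    division_size_ratio = division_size_ratio,
    division_cooldown = as.integer(division_cooldown),
    tcs_window = as.integer(tcs_window), tcs_threshold = tcs_threshold,
    weights = weights, use_class_for_division = use_class_for_division,
    hu_transform = hu_transform, seed = as.integer(seed)
  ), class = "tracker_config")
}
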