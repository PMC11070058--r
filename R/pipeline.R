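# Orchestration: features -> tracker -> refiner -> class smoothing ->
# export, plus a one-stop evaluation path.

#' Run the full tracking pipeline on a segmented movie
#'
#' Executes [track()], the four refinement passes ([prune_singletons()],
#' [link_fragments()], [discard_short_trees()], [fill_gaps()], in that
#' order) and, when class labels are present, [apply_tcs()]. Deterministic
#' given the input and config.
#'
#' @param frames nonempty list of [frame_segmentation()].
#' @param config a [tracker_config()].
#' @param verbose per-stage logging.
#' @return List with `forest` (refined, smoothed), `records` (lineage
#'   `data.frame` from [export_lineage()]) and `report` (per-stage counts
#'   and the config echo).
#' @export
run_pipeline <- function(frames, config = tracker_config(), verbose = FALSE) {
  if (length(frames) == 0) stop("empty input: no frames", call. = FALSE)
  n_in <- sum(vapply(frames, function(fs) length(fs$instances), integer(1)))
  forest <- track(frames, config, verbose = verbose)
  decisions <- attr(forest, "decisions")
  ref <- refine_forest(forest, config, frames[[1]]$image_shape)
  forest <- ref$forest
  has_class <- any(vapply(frames, function(fs)
    any(vapply(fs$instances, function(ci) !is.null(ci$class_label),
               logical(1))), logical(1)))
  n_corrected <- 0L
  if (has_class) {
    forest <- apply_tcs(forest, config)
    rec0 <- export_lineage(forest)
    n_corrected <- sum(!is.na(rec0$raw_class) & !is.na(rec0$smoothed_class) &
                       rec0$raw_class != rec0$smoothed_class)
  }
  records <- export_lineage(forest)
  tier <- table(factor(decisions$outcome,
                       levels = c("linked_unique", "linked_by_similarity",
                                  "linked_expanded", "division_daughter",
                                  "cache_relinked", "new_tree")))
  report <- list(n_instances = n_in, link_tiers = as.list(tier),
                 n_divisions = length(forest_divisions(forest)),
                 n_pruned = ref$n_pruned, n_fragments_linked = ref$n_linked,
                 n_trees_discarded = ref$n_discarded,
                 n_gaps_filled = ref$n_filled,
                 n_labels_corrected = n_corrected,
                 n_trees = length(forest_tree_ids(forest)),
                 config = unclass(config), seed = config$seed)
  if (verbose) {
    message(sprintf(
      "instances %d | unique %d similarity %d expanded %d division %d cache %d new %d",
      n_in, tier[1], tier[2], tier[3], tier[4], tier[5], tier[6]))
    message(sprintf(
      "pruned %d | fragments linked %d | short trees discarded %d | gaps filled %d | labels corrected %d",
      ref$n_pruned, ref$n_linked, ref$n_discarded, ref$n_filled, n_corrected))
  }
  list(forest = forest, records = records, report = report)
}

#' Score a predicted lineage against ground truth
#'
#' Computes IDF1, MOTA, CDF1 and (when labels are present) per-class F1 for
#' both raw and smoothed labels in one report. Inputs may be two
#' `track_forest` objects (detection correspondence by mask IoU) or two
#' lineage CSV paths / record frames (correspondence by shared
#' `(frame, instance_id)`).
#'
#' @param gt,pred `track_forest`, lineage CSV path, or lineage
#'   `data.frame`.
#' @param iou_min IoU threshold for detection correspondence.
#' @param div_tol division-frame matching tolerance.
#' @return Object of class `tracking_evaluation`: a list with `idf1`,
#'   `mota`, `cdf1` components (each the full count breakdown) and
#'   `class_f1` (`NULL` without labels). Undefined scores are `NA` and
#'   print as a dash.
#' @export
evaluate_tracking <- function(gt, pred, iou_min = 0.5, div_tol = 1L) {
  as_side <- function(x) {
    if (inherits(x, "track_forest")) {
      list(tracks = forest_tracks(x), divisions = forest_divisions(x),
           mode = "iou", forest = x)
    } else {
      rec <- if (is.character(x)) read_lineage_csv(x) else x
      list(tracks = tracks_from_records(rec),
           divisions = divisions_from_records(rec), mode = "id",
           records = rec)
    }
  }
  g <- as_side(gt); p <- as_side(pred)
  mode <- if (g$mode == "iou" && p$mode == "iou") "iou" else "id"
  gr <- range(unlist(lapply(g$tracks, `[[`, "frames")))
  pr <- range(unlist(lapply(p$tracks, `[[`, "frames")))
  if (pr[1] > gr[2] || gr[1] > pr[2]) {
    stop("frame-range mismatch between ground truth and prediction",
         call. = FALSE)
  }
  id <- idf1(g$tracks, p$tracks, iou_min, mode)
  mo <- mota(g$tracks, p$tracks, iou_min, mode)
  cd <- cdf1(g$divisions, p$divisions, g$tracks, p$tracks, div_tol,
             iou_min, mode)
  cf_raw <- cf_sm <- NULL
  if (!is.null(g$forest) && !is.null(p$forest)) {
    al_raw <- align_forest_labels(g$forest, p$forest, "raw")
    if (nrow(al_raw) > 0 && any(!is.na(al_raw$gt))) {
      cf_raw <- class_f1(al_raw$gt, al_raw$pred)
      al_sm <- align_forest_labels(g$forest, p$forest, "smoothed")
      cf_sm <- class_f1(al_sm$gt, al_sm$pred)
    }
  }
  structure(list(idf1 = id, mota = mo, cdf1 = cd,
                 class_f1_raw = cf_raw, class_f1_smoothed = cf_sm),
            class = "tracking_evaluation")
}

fmt_score <- function(x) if (is.na(x)) "\u2013" else sprintf("%.4f", x)

#' @export
print.tracking_evaluation <- function(x, ...) {
  cat("IDF1:", fmt_score(x$idf1$idf1),
      sprintf("(IDTP %d, IDFP %d, IDFN %d)\n",
              x$idf1$IDTP, x$idf1$IDFP, x$idf1$IDFN))
  cat("MOTA:", fmt_score(x$mota$mota),
      sprintf("(FP %d, FN %d, IDsw %d, GT %d)\n",
              x$mota$FP, x$mota$FN, x$mota$IDsw, x$mota$GT))
  cat("CDF1:", fmt_score(x$cdf1$cdf1),
      sprintf("(CDTP %d, CDFP %d, CDFN %d)\n",
              x$cdf1$CDTP, x$cdf1$CDFP, x$cdf1$CDFN))
  if (!is.null(x$class_f1_smoothed)) {
    cat("per-class F1 (smoothed vs raw):\n")
    for (k in seq_len(nrow(x$class_f1_smoothed))) {
      cl <- x$class_f1_smoothed$class[k]
      raw <- x$class_f1_raw$f1[x$class_f1_raw$class == cl]
      cat(sprintf("  %-6s %s (raw %s)\n", cl,
                  fmt_score(x$class_f1_smoothed$f1[k]),
                  fmt_score(if (length(raw)) raw else NA)))
    }
  }
  invisible(x)
}

#' Evaluation report as a flat data.frame
#'
#' @param ev a `tracking_evaluation`.
#' @return `data.frame` with `metric` and `value` columns (`NA` for
#'   undefined scores).
#' @export
evaluation_report <- function(ev) {
  rows <- data.frame(metric = c("IDF1", "MOTA", "CDF1"),
                     value = c(ev$idf1$idf1, ev$mota$mota, ev$cdf1$cdf1),
                     stringsAsFactors = FALSE)
  if (!is.null(ev$class_f1_smoothed)) {
    rows <- rbind(rows,
      data.frame(metric = paste0("F1_raw_", ev$class_f1_raw$class),
                 value = ev$class_f1_raw$f1, stringsAsFactors = FALSE),
      data.frame(metric = paste0("F1_smoothed_", ev$class_f1_smoothed$class),
                 value = ev$class_f1_smoothed$f1, stringsAsFactors = FALSE))
  }
  rows
}
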