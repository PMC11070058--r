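# VIA2 (VGG Image Annotator) polygon annotation JSON. The reader accepts
# either a flat export (top-level dict of image entries) or a project file
# with the entries under `_via_img_metadata`. The class of a region sits in
# its region_attributes under a configurable key (default "phase"); the
# attribute vocabulary (e.g. G1/G2, S, M cell-cycle phases) is the user's.

via_entries <- function(doc) {
  if (!is.null(doc[["_via_img_metadata"]])) doc <- doc[["_via_img_metadata"]]
  doc <- doc[!startsWith(names(doc), "_via")]
  doc[vapply(doc, function(e) is.list(e) && !is.null(e$regions), logical(1))]
}

#' Read VIA2 polygon annotations into frame segmentations
#'
#' One image entry per frame, frames ordered by natural filename sort.
#' Polygon areas use the shoelace formula; shape features (Hu moments, IoU
#' masks) come from rasterization.
#'
#' @param path VIA2 JSON file.
#' @param class_key region-attribute key carrying the class (default
#'   `"phase"`).
#' @param image_shape optional `c(height, width)`; defaults to per-file
#'   `file_attributes$height/width` or, failing that, the polygon extent.
#' @param hu_transform `"log"` or `"raw"`.
#' @return List of [frame_segmentation()].
#' @export
read_via_json <- function(path, class_key = "phase", image_shape = NULL,
                          hu_transform = "log") {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  entries <- via_entries(doc)
  if (length(entries) == 0) {
    stop("format error: no VIA image entries in ", path, call. = FALSE)
  }
  fnames <- vapply(entries, function(e)
    if (!is.null(e$filename)) e$filename else "", character(1))
  ord <- match(nat_sort(fnames), fnames)
  entries <- entries[ord]
  frames <- vector("list", length(entries))
  max_x <- 0; max_y <- 0
  for (f in seq_along(entries)) {
    e <- entries[[f]]
    insts <- list()
    for (r in seq_along(e$regions)) {
      reg <- e$regions[[r]]
      sa <- reg$shape_attributes
      xs <- unlist(sa$all_points_x)
      ys <- unlist(sa$all_points_y)
      if (is.null(xs) || is.null(ys)) {
        stop("format error: missing polygon coordinates (file ", e$filename,
             ", region ", r, ")", call. = FALSE)
      }
      if (length(xs) != length(ys)) {
        stop("format error: all_points_x/all_points_y length mismatch (file ",
             e$filename, ", region ", r, ")", call. = FALSE)
      }
      if (length(xs) < 3) {
        stop("format error: polygon with fewer than 3 points (file ",
             e$filename, ", region ", r, ")", call. = FALSE)
      }
      ra <- reg$region_attributes
      cls <- if (!is.null(ra) && !is.null(ra[[class_key]])) {
        as.character(ra[[class_key]])
      }
      iid <- if (!is.null(ra) && !is.null(ra$instance_id)) {
        as.integer(ra$instance_id)
      } else r
      insts[[length(insts) + 1L]] <- instance_from_polygon(
        cbind(xs, ys), frame = f - 1L, instance_id = iid,
        class_label = cls, hu_transform = hu_transform)
      max_x <- max(max_x, xs); max_y <- max(max_y, ys)
    }
    frames[[f]] <- insts
  }
  shape <- if (!is.null(image_shape)) image_shape else {
    fa <- entries[[1]]$file_attributes
    if (!is.null(fa$height) && !is.null(fa$width)) {
      c(as.integer(fa$height), as.integer(fa$width))
    } else c(ceiling(max_y) + 1, ceiling(max_x) + 1)
  }
  lapply(seq_along(frames), function(f)
    frame_segmentation(f - 1L, frames[[f]], shape))
}

#' Write frame segmentations or a tracked forest as VIA2 JSON
#'
#' Round-trips exactly through [read_via_json()]: contours, classes and
#' instance ids are preserved. Forest input additionally records tree and
#' branch ids (and the gap-fill flag) as region attributes.
#'
#' @param x list of [frame_segmentation()] or a `track_forest`.
#' @param path output JSON file.
#' @param class_key region-attribute key for the class.
#' @param image_shape required for forest input; inferred for frames.
#' @return `path`, invisibly.
#' @export
write_via_json <- function(x, path, class_key = "phase",
                           image_shape = NULL) {
  region_of <- function(cell, extra = list()) {
    ra <- c(list(instance_id = cell$instance_id), extra)
    if (!is.null(cell$class_label)) ra[[class_key]] <- cell$class_label
    list(shape_attributes = list(name = "polygon",
                                 all_points_x = as.numeric(cell$contour[, 1]),
                                 all_points_y = as.numeric(cell$contour[, 2])),
         region_attributes = ra)
  }
  if (inherits(x, "track_forest")) {
    stopifnot(!is.null(image_shape))
    nf <- x$n_frames
    per_frame <- lapply(seq_len(max(nf, 1L)), function(k) list())
    for (br in x$branches) {
      for (nd in br$nodes) {
        f <- nd$cell$frame + 1L
        per_frame[[f]][[length(per_frame[[f]]) + 1L]] <-
          region_of(nd$cell, list(tree_id = br$tree_id,
                                  branch_id = br$branch_id,
                                  gap_fill = nd$is_gap_fill))
      }
    }
  } else {
    if (is.null(image_shape)) image_shape <- x[[1]]$image_shape
    per_frame <- lapply(x, function(fs) lapply(fs$instances, region_of))
  }
  entries <- list()
  for (f in seq_along(per_frame)) {
    fname <- sprintf("frame_%06d.png", f - 1L)
    entries[[paste0(fname, "-1")]] <- list(
      filename = fname, size = -1,
      regions = per_frame[[f]],
      file_attributes = list(height = image_shape[1],
                             width = image_shape[2]))
  }
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}
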