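#' Hu moment invariants of a pixel set
#'
#' The seven Hu invariants computed from the binary pixel set of a cell.
#' Because the raw invariants span many orders of magnitude, the default
#' returns the signed log transform `sign(h) * log10(|h|)`; invariants that
#' are exactly zero are kept at zero (and skipped later in shape-distance
#' sums). Set `transform = "raw"` for the untransformed values.
#'
#' @param mask logical matrix of the filled region.
#' @param transform `"log"` (default) or `"raw"`.
#' @return Numeric vector of length 7.
#' @export
hu_moments <- function(mask, transform = c("log", "raw")) {
  transform <- match.arg(transform)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("degenerate contour: empty mask", call. = FALSE)
  x <- idx[, 2] - 1
  y <- idx[, 1] - 1
  m00 <- length(x)
  xb <- mean(x); yb <- mean(y)
  dx <- x - xb; dy <- y - yb
  mu <- function(p, q) sum(dx^p * dy^q)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
          ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
        (3 * n21 - n03) * (n21 + n03) *
          (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
        4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
          ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
        (n30 - 3 * n12) * (n21 + n03) *
          (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h <- c(h1, h2, h3, h4, h5, h6, h7)
  if (transform == "log") {
    h <- ifelse(h == 0, 0, sign(h) * log10(abs(h)))
  }
  h
}

#' A segmented cell in one frame
#'
#' Low-level constructor; most users build instances via
#' [extract_instances()], [read_via_json()] or the synthetic generator.
#'
#' @param frame 0-based frame index.
#' @param instance_id integer id, unique within the frame.
#' @param contour numeric matrix (>= 3 rows) of `(x, y)` vertices, pixel
#'   units.
#' @param centroid `c(x, y)`.
#' @param area area in squared pixels (> 0).
#' @param bb a [bbox()].
#' @param mask,offset cropped logical pixel mask and the pixel coordinate of
#'   `mask[1, 1]`.
#' @param hu 7 Hu shape invariants (see [hu_moments()]).
#' @param intensity_mean,intensity_var optional intensity statistics.
#' @param class_label optional categorical label (e.g. `"G1/G2"`, `"S"`,
#'   `"M"`).
#' @return Object of class `cell_instance`.
#' @export
cell_instance <- function(frame, instance_id, contour, centroid, area, bb,
                          mask, offset, hu,
                          intensity_mean = NULL, intensity_var = NULL,
                          class_label = NULL) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3) stop("degenerate contour: need >= 3 vertices", call. = FALSE)
  if (!(area > 0)) stop("cell_instance: area must be > 0", call. = FALSE)
  if (length(hu) != 7) stop("cell_instance: hu must have exactly 7 entries", call. = FALSE)
  if (!point_in_bbox(centroid[1], centroid[2], bb)) {
    stop("cell_instance: centroid outside bounding box", call. = FALSE)
  }
  structure(list(
    frame = as.integer(frame), instance_id = as.integer(instance_id),
    contour = contour, centroid = as.numeric(centroid), area = area,
    bbox = bb, mask = mask, offset = as.numeric(offset), hu = as.numeric(hu),
    intensity_mean = intensity_mean, intensity_var = intensity_var,
    class_label = class_label
  ), class = "cell_instance")
}

# bbox of a pixel set; widens single-pixel extents so x1 < x2 always holds
bbox_of_pixels <- function(px, py) {
  x1 <- min(px); x2 <- max(px); y1 <- min(py); y2 <- max(py)
  if (x1 == x2) x2 <- x2 + 1
  if (y1 == y2) y2 <- y2 + 1
  bbox(x1, x2, y1, y2)
}

# Build an instance from an offset pixel mask. `intensity` must be cropped
# identically to `mask` when given.
instance_from_mask <- function(mask, offset, frame, instance_id,
                               intensity = NULL, class_label = NULL,
                               hu_transform = "log") {
  pts <- mask_pixel_coords(mask, offset)
  if (nrow(pts) == 0) stop("degenerate contour: empty mask", call. = FALSE)
  centroid <- colMeans(pts)
  bb <- bbox_of_pixels(pts[, 1], pts[, 2])
  contour <- trace_contour(mask, offset)
  im <- iv <- NULL
  if (!is.null(intensity)) {
    vals <- intensity[mask]
    im <- mean(vals)
    iv <- stats::var(vals)
    if (is.na(iv)) iv <- 0
  }
  cell_instance(frame, instance_id, contour, centroid, area = sum(mask),
                bb = bb, mask = mask, offset = offset,
                hu = hu_moments(mask, transform = hu_transform),
                intensity_mean = im, intensity_var = iv,
                class_label = class_label)
}

# Build an instance from a polygon contour (VIA input). Area is the shoelace
# area of the polygon; the mask (for IoU and Hu moments) is its
# rasterization.
instance_from_polygon <- function(contour, frame, instance_id,
                                  class_label = NULL, hu_transform = "log") {
  area <- shoelace_area(contour)
  ras <- rasterize_polygon(contour)
  pts <- mask_pixel_coords(ras$mask, ras$offset)
  if (nrow(pts) == 0) stop("degenerate contour: rasterizes to zero pixels", call. = FALSE)
  centroid <- colMeans(pts)
  bb <- bbox_of_pixels(pts[, 1], pts[, 2])
  cell_instance(frame, instance_id, as.matrix(contour), centroid, area = area,
                bb = bb, mask = ras$mask, offset = ras$offset,
                hu = hu_moments(ras$mask, transform = hu_transform),
                class_label = class_label)
}

#' All segmented instances of one frame
#'
#' @param frame 0-based frame index.
#' @param instances list of [cell_instance()] (may be empty).
#' @param image_shape `c(height, width)` in pixels.
#' @return Object of class `frame_segmentation`.
#' @export
frame_segmentation <- function(frame, instances, image_shape) {
  ids <- vapply(instances, function(ci) ci$instance_id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate instance_ids within frame", call. = FALSE)
  for (ci in instances) {
    if (ci$frame != frame) stop("instance frame mismatch", call. = FALSE)
  }
  structure(list(frame = as.integer(frame), instances = instances,
                 image_shape = as.integer(image_shape)),
            class = "frame_segmentation")
}

#' Extract per-cell features from an integer label mask
#'
#' Every positive label in the mask becomes one [cell_instance()] carrying
#' its outer contour, centroid (mean of labelled pixel coordinates), area
#' (pixel count), bounding box, the 7 Hu shape invariants of the filled
#' region and, when `intensity_image` is given, the mean and variance of the
#' intensities under the label. Labels whose pixel set splits into several
#' 8-connected components keep only the largest component (with a warning).
#'
#' @param label_mask 2D integer matrix; 0 is background, each positive label
#'   one cell. Labels above 255 (16-bit masks) are accepted.
#' @param frame 0-based frame index.
#' @param intensity_image optional 2D numeric matrix of the same shape.
#' @param class_map optional named vector mapping label (as character) to a
#'   class string.
#' @param hu_transform `"log"` or `"raw"`, see [hu_moments()].
#' @return A [frame_segmentation()].
#' @export
extract_instances <- function(label_mask, frame, intensity_image = NULL,
                              class_map = NULL, hu_transform = "log") {
  if (!is.matrix(label_mask)) {
    stop("format error: label mask must be a 2D matrix", call. = FALSE)
  }
  if (any(label_mask < 0)) {
    stop("format error: negative labels in mask", call. = FALSE)
  }
  if (any(label_mask != floor(label_mask))) {
    stop("format error: non-integer labels in mask", call. = FALSE)
  }
  if (!is.null(intensity_image) &&
      !identical(dim(intensity_image), dim(label_mask))) {
    stop("format error: intensity image shape mismatch", call. = FALSE)
  }
  labels <- sort(unique(label_mask[label_mask > 0]))
  instances <- vector("list", length(labels))
  for (k in seq_along(labels)) {
    lab <- labels[k]
    idx <- which(label_mask == lab, arr.ind = TRUE)
    r1 <- min(idx[, 1]); r2 <- max(idx[, 1])
    c1 <- min(idx[, 2]); c2 <- max(idx[, 2])
    sub <- label_mask[r1:r2, c1:c2, drop = FALSE] == lab
    comps <- label_components(sub)
    ncomp <- max(comps)
    if (ncomp > 1) {
      warning("label ", lab, " in frame ", frame, " has ", ncomp,
              " components; keeping the largest", call. = FALSE)
      sizes <- tabulate(comps[comps > 0], nbins = ncomp)
      sub <- comps == which.max(sizes)
      # re-crop to the surviving component
      keep <- which(sub, arr.ind = TRUE)
      kr1 <- min(keep[, 1]); kr2 <- max(keep[, 1])
      kc1 <- min(keep[, 2]); kc2 <- max(keep[, 2])
      sub <- sub[kr1:kr2, kc1:kc2, drop = FALSE]
      r1 <- r1 + kr1 - 1; c1 <- c1 + kc1 - 1
      r2 <- r1 + nrow(sub) - 1; c2 <- c1 + ncol(sub) - 1
    }
    offset <- c(c1 - 1, r1 - 1)  # (x0, y0), 0-based
    intens <- if (!is.null(intensity_image)) {
      intensity_image[r1:r2, c1:c2, drop = FALSE]
    }
    cls <- if (!is.null(class_map)) {
      cl <- class_map[as.character(lab)]
      if (is.na(cl)) NULL else unname(cl)
    }
    instances[[k]] <- instance_from_mask(sub, offset, frame,
                                         instance_id = lab,
                                         intensity = intens,
                                         class_label = cls,
                                         hu_transform = hu_transform)
  }
  frame_segmentation(frame, instances, dim(label_mask))
}

#' Intersection-over-union of two cell instances
#'
#' Computed on the rasterized (filled) pixel sets; 1 for identical regions,
#' 0 for disjoint ones, symmetric.
#'
#' @param a,b [cell_instance()] objects.
#' @return Value in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  na <- sum(a$mask); nb <- sum(b$mask)
  if (na == 0 || nb == 0) stop("degenerate contour: zero-area instance", call. = FALSE)
  inter <- mask_overlap_area(a$mask, a$offset, b$mask, b$offset)
  inter / (na + nb - inter)
}
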