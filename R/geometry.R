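#' Axis-aligned bounding box
#'
#' Pixel coordinates, 0-based, `x` = column and `y` = row. `x1 < x2` and
#' `y1 < y2` are enforced strictly; degenerate (zero-width) boxes are
#' rejected.
#'
#' @param x1,x2 left/right pixel coordinates, `x1 < x2`.
#' @param y1,y2 top/bottom pixel coordinates, `y1 < y2`.
#' @return An object of class `bbox`.
#' @export
bbox <- function(x1, x2, y1, y2) {
  stopifnot(is.numeric(x1), is.numeric(x2), is.numeric(y1), is.numeric(y2))
  if (!(x1 < x2) || !(y1 < y2)) {
    stop("degenerate bounding box: require x1 < x2 and y1 < y2 (got [",
         x1, ",", x2, "] x [", y1, ",", y2, "])", call. = FALSE)
  }
  structure(list(x1 = x1, x2 = x2, y1 = y1, y2 = y2), class = "bbox")
}

# internal constructor without validation (clipped boxes may collapse)
new_bbox <- function(x1, x2, y1, y2) {
  structure(list(x1 = x1, x2 = x2, y1 = y1, y2 = y2), class = "bbox")
}

#' Expand a bounding box by a search-range coefficient
#'
#' Each side is pushed outward by `alpha` times the box extent in that
#' dimension, so the expanded width is `(1 + 2 * alpha)` times the original
#' width and the centre is unchanged. When `image_shape` is supplied the
#' result is clipped to `[0, width - 1] x [0, height - 1]`: search candidates
#' cannot exist outside the frame.
#'
#' @param bc a [bbox()].
#' @param alpha nonnegative expansion coefficient (default 1.5).
#' @param image_shape optional `c(height, width)` used for clipping.
#' @return A `bbox`.
#' @export
expand_bbox <- function(bc, alpha = 1.5, image_shape = NULL) {
  stopifnot(inherits(bc, "bbox"), alpha >= 0)
  w <- bc$x2 - bc$x1
  h <- bc$y2 - bc$y1
  out <- new_bbox(bc$x1 - alpha * w, bc$x2 + alpha * w,
                  bc$y1 - alpha * h, bc$y2 + alpha * h)
  if (!is.null(image_shape)) {
    stopifnot(length(image_shape) == 2)
    out$x1 <- max(out$x1, 0)
    out$y1 <- max(out$y1, 0)
    out$x2 <- min(out$x2, image_shape[2] - 1)
    out$y2 <- min(out$y2, image_shape[1] - 1)
  }
  out
}

point_in_bbox <- function(x, y, b) {
  x >= b$x1 & x <= b$x2 & y >= b$y1 & y <= b$y2
}

bbox_intersects <- function(a, b) {
  !(a$x2 < b$x1 || b$x2 < a$x1 || a$y2 < b$y1 || b$y2 < a$y1)
}

#' Polygon area by the shoelace formula
#'
#' `0.5 * |sum(x_i * y_{i+1} - y_i * x_{i+1})|`, the polygon being implicitly
#' closed (last vertex connects to the first). Orientation-independent.
#'
#' @param contour numeric matrix with >= 3 rows and columns `(x, y)`.
#' @return Nonnegative area in squared pixel units. A zero area (collinear
#'   vertices) is returned with a warning flagging the degenerate contour.
#' @export
shoelace_area <- function(contour) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3) {
    stop("degenerate contour: need at least 3 vertices", call. = FALSE)
  }
  x <- contour[, 1]
  y <- contour[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  a <- 0.5 * abs(sum(x * yn - y * xn))
  if (a == 0) warning("degenerate contour: zero shoelace area", call. = FALSE)
  a
}

# --- pixel-set (mask) utilities -------------------------------------------
#
# A mask is a logical matrix cropped to the instance, with `offset = c(x0,
# y0)` giving the pixel coordinates of mask[1, 1]; pixel (x, y) maps to
# mask[y - y0 + 1, x - x0 + 1].

mask_pixel_coords <- function(mask, offset) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1 + offset[1], y = idx[, 1] - 1 + offset[2])
}

# IoU of two offset masks; returns 0 when the windows are disjoint
mask_overlap_area <- function(mask_a, off_a, mask_b, off_b) {
  ax2 <- off_a[1] + ncol(mask_a) - 1; ay2 <- off_a[2] + nrow(mask_a) - 1
  bx2 <- off_b[1] + ncol(mask_b) - 1; by2 <- off_b[2] + nrow(mask_b) - 1
  x1 <- max(off_a[1], off_b[1]); x2 <- min(ax2, bx2)
  y1 <- max(off_a[2], off_b[2]); y2 <- min(ay2, by2)
  if (x1 > x2 || y1 > y2) return(0L)
  wa <- mask_a[(y1 - off_a[2] + 1):(y2 - off_a[2] + 1),
               (x1 - off_a[1] + 1):(x2 - off_a[1] + 1), drop = FALSE]
  wb <- mask_b[(y1 - off_b[2] + 1):(y2 - off_b[2] + 1),
               (x1 - off_b[1] + 1):(x2 - off_b[1] + 1), drop = FALSE]
  sum(wa & wb)
}

# --- boundary tracing ------------------------------------------------------
#
# The contour of a pixel set is traced along pixel *corners* (marching-
# squares style): pixel (x, y) occupies the square [x-0.5, x+0.5] x
# [y-0.5, y+0.5] and the contour is the outer boundary of the union of those
# squares. Consequence: shoelace_area(contour) equals the pixel count
# exactly, and rasterizing the contour recovers the exact pixel set (pixel
# centres are never on the polygon). Corners are computed in doubled integer
# coordinates to avoid float keys, then halved.

trace_contour <- function(mask, offset = c(0, 0)) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0) stop("degenerate contour: empty mask", call. = FALSE)
  px <- pts[, 2] - 1L  # local 0-based x
  py <- pts[, 1] - 1L
  nr <- nrow(mask); nc <- ncol(mask)
  inside <- function(x, y) {
    ok <- x >= 0L & x < nc & y >= 0L & y < nr
    res <- logical(length(ok))
    if (any(ok)) res[ok] <- mask[cbind(y[ok] + 1L, x[ok] + 1L)]
    res
  }
  # boundary edges in doubled coords; each edge from corner A to corner B,
  # oriented so the region lies consistently on one side
  edges_from <- new.env(hash = TRUE, parent = emptyenv())
  add_edge <- function(ax, ay, bx, by) {
    key <- paste(ax, ay, sep = ",")
    cur <- edges_from[[key]]
    edges_from[[key]] <- if (is.null(cur)) matrix(c(bx, by), ncol = 2) else
      rbind(cur, c(bx, by))
  }
  # pixel corners (doubled): TL (2x-1, 2y-1), TR (2x+1, 2y-1),
  # BR (2x+1, 2y+1), BL (2x-1, 2y+1). Orientation: walk clockwise in screen
  # coords (y down) so the region is on the right of travel; any consistent
  # choice works since we take |shoelace|.
  up    <- !inside(px, py - 1L)
  right <- !inside(px + 1L, py)
  down  <- !inside(px, py + 1L)
  left  <- !inside(px - 1L, py)
  dx2 <- 2L * px; dy2 <- 2L * py
  for (k in seq_along(px)) {
    if (up[k])    add_edge(dx2[k] - 1L, dy2[k] - 1L, dx2[k] + 1L, dy2[k] - 1L)
    if (right[k]) add_edge(dx2[k] + 1L, dy2[k] - 1L, dx2[k] + 1L, dy2[k] + 1L)
    if (down[k])  add_edge(dx2[k] + 1L, dy2[k] + 1L, dx2[k] - 1L, dy2[k] + 1L)
    if (left[k])  add_edge(dx2[k] - 1L, dy2[k] + 1L, dx2[k] - 1L, dy2[k] - 1L)
  }
  # outer loop starts at the topmost-leftmost corner, whose outgoing edge
  # (top edge of the topmost-left pixel) always exists
  top_row <- min(py)
  start_x <- 2L * min(px[py == top_row]) - 1L
  start_y <- 2L * top_row - 1L
  cx <- start_x; cy <- start_y
  path_x <- integer(0); path_y <- integer(0)
  prev_dx <- 0L; prev_dy <- 0L
  repeat {
    path_x <- c(path_x, cx); path_y <- c(path_y, cy)
    nxt <- edges_from[[paste(cx, cy, sep = ",")]]
    if (is.null(nxt)) stop("internal error: open contour", call. = FALSE)
    if (nrow(nxt) == 1L) {
      pick <- 1L
    } else {
      # saddle corner: prefer the sharpest right turn relative to incoming
      # direction, a consistent rule that keeps the loop from crossing itself
      dirs <- cbind(nxt[, 1] - cx, nxt[, 2] - cy) / 2L
      cross <- prev_dx * dirs[, 2] - prev_dy * dirs[, 1]
      dot <- prev_dx * dirs[, 1] + prev_dy * dirs[, 2]
      # exclude going straight back
      score <- ifelse(dot == -1, -Inf, cross)  # right turn has cross > 0 (y down)
      pick <- which.max(score)
    }
    nx <- nxt[pick, 1]; ny <- nxt[pick, 2]
    # consume the edge
    key <- paste(cx, cy, sep = ",")
    rem <- edges_from[[key]][-pick, , drop = FALSE]
    if (nrow(rem) == 0) rm(list = key, envir = edges_from) else
      edges_from[[key]] <- rem
    prev_dx <- (nx - cx) / 2L; prev_dy <- (ny - cy) / 2L
    cx <- nx; cy <- ny
    if (cx == start_x && cy == start_y) break
  }
  contour <- cbind(x = path_x / 2 + offset[1], y = path_y / 2 + offset[2])
  simplify_collinear(contour)
}

simplify_collinear <- function(contour) {
  n <- nrow(contour)
  if (n < 3) return(contour)
  keep <- logical(n)
  for (i in seq_len(n)) {
    p <- contour[if (i == 1) n else i - 1, ]
    q <- contour[i, ]
    r <- contour[if (i == n) 1 else i + 1, ]
    cross <- (q[1] - p[1]) * (r[2] - q[2]) - (q[2] - p[2]) * (r[1] - q[1])
    keep[i] <- cross != 0
  }
  contour[keep, , drop = FALSE]
}

# --- polygon rasterization -------------------------------------------------

# Pixel (x, y) belongs to the polygon iff its centre is inside (even-odd
# crossing rule) or exactly on an edge. Returns list(mask, offset).
rasterize_polygon <- function(contour) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3) stop("degenerate contour: need >= 3 vertices", call. = FALSE)
  cx <- contour[, 1]; cy <- contour[, 2]
  xs <- ceiling(min(cx) - 1e-9):floor(max(cx) + 1e-9)
  ys <- ceiling(min(cy) - 1e-9):floor(max(cy) + 1e-9)
  if (length(xs) == 0 || length(ys) == 0) {
    stop("degenerate contour: rasterizes to zero pixels", call. = FALSE)
  }
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  n <- length(cx)
  x1 <- cx; y1 <- cy
  x2 <- c(cx[-1], cx[1]); y2 <- c(cy[-1], cy[1])
  crossings <- integer(length(px))
  on_edge <- logical(length(px))
  for (e in seq_len(n)) {
    ex1 <- x1[e]; ey1 <- y1[e]; ex2 <- x2[e]; ey2 <- y2[e]
    # half-open crossing rule
    hit <- (ey1 <= py) != (ey2 <= py)
    if (any(hit)) {
      xi <- ex1 + (py[hit] - ey1) * (ex2 - ex1) / (ey2 - ey1)
      crossings[hit] <- crossings[hit] + (xi > px[hit])
    }
    # point-on-segment
    d2 <- (ex2 - ex1)^2 + (ey2 - ey1)^2
    if (d2 > 0) {
      t <- ((px - ex1) * (ex2 - ex1) + (py - ey1) * (ey2 - ey1)) / d2
      perp <- abs((ex2 - ex1) * (py - ey1) - (ey2 - ey1) * (px - ex1)) / sqrt(d2)
      on_edge <- on_edge | (t >= -1e-9 & t <= 1 + 1e-9 & perp < 1e-9)
    }
  }
  inside <- (crossings %% 2 == 1) | on_edge
  mask <- matrix(FALSE, nrow = length(ys), ncol = length(xs))
  mask[cbind(py[inside] - ys[1] + 1, px[inside] - xs[1] + 1)] <- TRUE
  list(mask = mask, offset = c(xs[1], ys[1]))
}

# --- connected components (8-connectivity) --------------------------------

label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  todo <- which(mask & lab == 0L)
  while (length(todo) > 0) {
    cur <- cur + 1L
    frontier <- todo[1]
    lab[frontier] <- cur
    while (length(frontier) > 0) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nb_r <- c(r - 1L, r - 1L, r - 1L, r, r, r + 1L, r + 1L, r + 1L)
      nb_c <- c(c - 1L, c, c + 1L, c - 1L, c + 1L, c - 1L, c, c + 1L)
      ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
      idx <- unique((nb_c[ok] - 1L) * nr + nb_r[ok])
      idx <- idx[mask[idx] & lab[idx] == 0L]
      lab[idx] <- cur
      frontier <- idx
    }
    todo <- which(mask & lab == 0L)
  }
  lab
}
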