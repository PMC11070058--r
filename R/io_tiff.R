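# Minimal baseline TIFF 6.0 codec for integer label masks. Reads
# uncompressed greyscale 8/16/32-bit unsigned multi-page TIFFs (either byte
# order, multiple strips); writes uncompressed little-endian single-strip
# pages. Deliberately narrow: compressed, tiled, float or RGB TIFFs are
# rejected with a format error. Implemented in-package because no TIFF
# reader is available in the supported dependency set.

nat_sort <- function(paths) {
  base <- basename(paths)
  key <- gsub("(\\d+)", "~\\1~", base)
  parts <- strsplit(key, "~", fixed = TRUE)
  width <- 15
  padded <- vapply(parts, function(p) {
    p <- p[p != ""]
    num <- grepl("^\\d+$", p)
    p[num] <- formatC(p[num], width = width, flag = "0")
    paste(p, collapse = "")
  }, character(1))
  paths[order(padded, base)]
}

#' Read a multi-page TIFF of integer matrices
#'
#' @param path a TIFF file.
#' @return List of integer matrices, one per page.
#' @export
read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) stop("format error: not a TIFF file", call. = FALSE)
  head2 <- rawToChar(raw[1:2])
  endian <- if (head2 == "II") "little" else if (head2 == "MM") "big" else
    stop("format error: not a TIFF file (bad byte-order mark)", call. = FALSE)
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = endian)
  u32 <- function(off) {
    v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4,
                 endian = endian)
    if (v < 0) stop("format error: offset overflow", call. = FALSE)
    v
  }
  if (u16(2) != 42L) stop("format error: bad TIFF magic", call. = FALSE)
  read_values <- function(type, count, off) {
    # off = file offset of the 4-byte value/offset field
    size <- c(`1` = 1L, `3` = 2L, `4` = 4L)[as.character(type)]
    if (is.na(size)) return(NULL)  # type we don't need
    total <- size * count
    src <- if (total <= 4) off else u32(off)
    vapply(seq_len(count), function(k) {
      o <- src + (k - 1) * size
      if (size == 1) as.integer(raw[o + 1])
      else if (size == 2) u16(o)
      else u32(o)
    }, numeric(1))
  }
  pages <- list()
  ifd <- u32(4)
  while (ifd != 0) {
    ntags <- u16(ifd)
    tags <- list()
    for (k in seq_len(ntags)) {
      e <- ifd + 2 + (k - 1) * 12
      tag <- u16(e); type <- u16(e + 2); count <- u32(e + 4)
      tags[[as.character(tag)]] <- read_values(type, count, e + 8)
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop("format error: missing TIFF tag ", tag,
                                   call. = FALSE)
        default
      } else v
    }
    width <- need(256); height <- need(257)
    bits <- need(258, 1)
    if (length(unique(bits)) != 1) stop("format error: mixed bit depths",
                                        call. = FALSE)
    bits <- bits[1]
    if (!bits %in% c(8, 16, 32)) {
      stop("format error: unsupported bit depth ", bits, call. = FALSE)
    }
    if (need(259, 1) != 1) stop("format error: compressed TIFF not supported",
                                call. = FALSE)
    if (need(277, 1) != 1) stop("format error: multi-sample TIFF not supported",
                                call. = FALSE)
    sf <- need(339, 1)
    if (any(sf == 3)) stop("format error: float-typed TIFF", call. = FALSE)
    offs <- need(273)
    cnts <- need(279, (width * height * bits / 8))
    rps <- need(278, height)
    vals <- integer(0)
    for (s in seq_along(offs)) {
      nbytes <- cnts[min(s, length(cnts))]
      chunk <- raw[(offs[s] + 1):(offs[s] + nbytes)]
      v <- if (bits == 8) {
        as.integer(chunk)
      } else {
        readBin(chunk, "integer", n = nbytes / (bits / 8), size = bits / 8,
                signed = bits == 32, endian = endian)
      }
      vals <- c(vals, v)
    }
    if (bits == 16) {
      vals <- ifelse(vals < 0, vals + 65536L, vals)
    }
    if (any(vals < 0)) stop("format error: negative pixel values", call. = FALSE)
    if (length(vals) < width * height) {
      stop("format error: truncated pixel data", call. = FALSE)
    }
    pages[[length(pages) + 1L]] <-
      matrix(vals[seq_len(width * height)], nrow = height, ncol = width,
             byrow = TRUE)
    ifd <- u32(ifd + 2 + ntags * 12)
  }
  pages
}

#' Write integer matrices as a multi-page uncompressed TIFF
#'
#' 8-bit when all values fit, 16-bit otherwise (32-bit as a last resort);
#' little-endian, one strip per page.
#'
#' @param mats list of nonnegative integer matrices of equal shape.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(mats, path) {
  stopifnot(length(mats) > 0)
  maxval <- max(0, vapply(mats, max, numeric(1)))
  bits <- if (maxval < 256) 8L else if (maxval < 65536) 16L else 32L
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  sizes <- vapply(mats, function(m) nrow(m) * ncol(m) * bits / 8, numeric(1))
  data_off <- 8 + c(0, cumsum(sizes))[seq_along(mats)]
  ifd_bytes <- 2 + 9 * 12 + 4
  ifd_off <- 8 + sum(sizes) + (seq_along(mats) - 1) * ifd_bytes
  writeChar("II", con, nchars = 2, eos = NULL)
  w16(42)
  w32(ifd_off[1])
  for (m in mats) {
    v <- as.integer(t(m))
    if (any(v < 0)) stop("format error: negative labels", call. = FALSE)
    if (bits == 8) writeBin(as.raw(v), con)
    else if (bits == 16) {
      v <- ifelse(v > 32767L, v - 65536L, v)
      writeBin(v, con, size = 2, endian = "little")
    } else writeBin(v, con, size = 4, endian = "little")
  }
  for (k in seq_along(mats)) {
    m <- mats[[k]]
    entry <- function(tag, type, count, value) {
      w16(tag); w16(type); w32(count);
      if (type == 3 && count == 1) { w16(value); w16(0) } else w32(value)
    }
    w16(9)
    entry(256, 4, 1, ncol(m))          # ImageWidth
    entry(257, 4, 1, nrow(m))          # ImageLength
    entry(258, 3, 1, bits)             # BitsPerSample
    entry(259, 3, 1, 1)                # Compression: none
    entry(262, 3, 1, 1)                # Photometric: BlackIsZero
    entry(273, 4, 1, data_off[k])      # StripOffsets
    entry(277, 3, 1, 1)                # SamplesPerPixel
    entry(278, 4, 1, nrow(m))          # RowsPerStrip
    entry(279, 4, 1, sizes[k])         # StripByteCounts
    w32(if (k < length(mats)) ifd_off[k + 1] else 0)
  }
  invisible(path)
}

#' Read a label-mask stack into frame segmentations
#'
#' Accepts a multi-page TIFF or a directory of per-frame TIFFs (natural
#' filename sort, logged). Frames are indexed `0..T-1` in stack order.
#'
#' @param path TIFF file or directory of TIFF files.
#' @param intensity_path optional matching intensity stack.
#' @param hu_transform passed to [extract_instances()].
#' @param verbose log the resolved frame order for directories.
#' @return List of [frame_segmentation()].
#' @export
read_label_stack <- function(path, intensity_path = NULL,
                             hu_transform = "log", verbose = FALSE) {
  load_stack <- function(p) {
    if (dir.exists(p)) {
      files <- nat_sort(list.files(p, pattern = "\\.tiff?$",
                                   ignore.case = TRUE, full.names = TRUE))
      if (length(files) == 0) stop("format error: no TIFF files in ", p,
                                   call. = FALSE)
      if (verbose) message("frame order: ",
                           paste(basename(files), collapse = ", "))
      do.call(c, lapply(files, read_tiff_stack))
    } else {
      read_tiff_stack(p)
    }
  }
  masks <- load_stack(path)
  shapes <- unique(lapply(masks, dim))
  if (length(shapes) != 1) stop("format error: inconsistent frame shapes",
                                call. = FALSE)
  intens <- if (!is.null(intensity_path)) load_stack(intensity_path)
  lapply(seq_along(masks), function(k) {
    extract_instances(masks[[k]], frame = k - 1L,
                      intensity_image = if (!is.null(intens)) intens[[k]],
                      hu_transform = hu_transform)
  })
}

#' Render a tracked forest as a label-mask TIFF stack
#'
#' Each cell's pixels carry its tree id (16-bit output); gap-fill nodes are
#' rendered like real nodes. Overlapping renders warn and let the later
#' tree win.
#'
#' @param forest a `track_forest`.
#' @param image_shape `c(height, width)`.
#' @param path output TIFF.
#' @param n_frames number of pages; defaults to `forest$n_frames`.
#' @return `path`, invisibly.
#' @export
write_tracked_masks <- function(forest, image_shape, path,
                                n_frames = forest$n_frames) {
  stopifnot(!is.na(n_frames))
  mats <- lapply(seq_len(n_frames), function(k)
    matrix(0L, image_shape[1], image_shape[2]))
  clash <- FALSE
  for (br in forest$branches) {
    for (nd in br$nodes) {
      f <- nd$cell$frame + 1L
      pts <- mask_pixel_coords(nd$cell$mask, nd$cell$offset)
      keep <- pts[, 1] >= 0 & pts[, 1] < image_shape[2] &
              pts[, 2] >= 0 & pts[, 2] < image_shape[1]
      pts <- pts[keep, , drop = FALSE]
      idx <- cbind(pts[, 2] + 1L, pts[, 1] + 1L)
      if (any(mats[[f]][idx] != 0L)) clash <- TRUE
      mats[[f]][idx] <- br$tree_id
    }
  }
  if (clash) warning("overlapping rendered masks; later tree wins",
                     call. = FALSE)
  write_tiff_stack(mats, path)
}
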