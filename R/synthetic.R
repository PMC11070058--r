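# Seeded synthetic timelapse generator. Emulates what the tracker assumes
# about real movies: slowly moving cells whose masks overlap between
# consecutive frames (Gaussian random-walk steps small relative to the cell
# radius), binary divisions where an M-labelled mother swells and splits
# into two adjacent daughters each ~55% of her area (so the mother is ~1.8x
# each daughter, comfortably above the 1.3x rule), cell-cycle class blocks
# long enough for the smoothing window, and controllable corruption
# (detection dropout, single-frame false positives, label noise). Masks
# within a frame never overlap and every run is bit-identical given the
# seed.

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic timelapse configuration
#'
#' Defaults describe the reference scenario used throughout the test suite:
#' 20 cells, 100 frames, a 512x512 canvas, 2 px/frame Gaussian motion and
#' 12 px mean cell radius (a cell moves a small fraction of its diameter
#' per frame, as in timelapse microscopy sampled every few minutes).
#'
#' @param n_cells number of cells in frame 0.
#' @param n_frames movie length.
#' @param image_shape `c(height, width)` pixels.
#' @param motion_sigma random-walk step s.d., px/frame.
#' @param radius_mean,radius_sd cell radius distribution, px.
#' @param n_divisions number of division events (distinct mothers, frames
#'   spread over the middle of the movie).
#' @param daughter_area_fraction each daughter's area as a fraction of the
#'   (swollen) mother area; 0.55 keeps the mother ~1.8x each daughter.
#' @param with_classes attach cell-cycle phase labels (G1/G2, S, and M
#'   straddling each division: the mother's last 2 frames and each
#'   daughter's first 2 frames).
#' @param seed integer seed; all randomness flows through it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 20L, n_frames = 100L,
                              image_shape = c(512L, 512L),
                              motion_sigma = 2, radius_mean = 12,
                              radius_sd = 1.5, n_divisions = 0L,
                              daughter_area_fraction = 0.55,
                              with_classes = TRUE, seed = 1L) {
  stopifnot(n_cells >= 1, n_frames >= 1, motion_sigma >= 0,
            radius_mean > 2, n_divisions >= 0,
            daughter_area_fraction > 0, daughter_area_fraction < 0.77)
  # feasibility: cells are kept ~70 px apart at spawn
  if (n_cells > (image_shape[1] / 70) * (image_shape[2] / 70) * 1.3) {
    stop("configuration error: too many cells for the canvas", call. = FALSE)
  }
  structure(list(n_cells = as.integer(n_cells),
                 n_frames = as.integer(n_frames),
                 image_shape = as.integer(image_shape),
                 motion_sigma = motion_sigma, radius_mean = radius_mean,
                 radius_sd = radius_sd, n_divisions = as.integer(n_divisions),
                 daughter_area_fraction = daughter_area_fraction,
                 with_classes = with_classes, seed = as.integer(seed)),
            class = "simulation_config")
}

# cell-cycle phase of a lineage at relative time d (G1/G2 and S blocks)
phase_cycle <- function(d) {
  ifelse((d %% 60) < 35, "G1/G2", "S")
}

rasterize_ellipse <- function(cx, cy, a, b, theta, image_shape) {
  ext <- max(a, b) + 1
  xs <- max(0, floor(cx - ext)):min(image_shape[2] - 1, ceiling(cx + ext))
  ys <- max(0, floor(cy - ext)):min(image_shape[1] - 1, ceiling(cy + ext))
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  dx <- px - cx; dy <- py - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  mask <- matrix(FALSE, length(ys), length(xs))
  mask[cbind(py[inside] - ys[1] + 1, px[inside] - xs[1] + 1)] <- TRUE
  list(mask = mask, offset = c(xs[1], ys[1]))
}

#' Simulate a ground-truthed synthetic timelapse
#'
#' @param config a [simulation_config()].
#' @return List with `frames` (list of [frame_segmentation()]), `truth`
#'   (the ground-truth `track_forest`) and `divisions` (list of
#'   `(frame, mother_branch, daughters)` events). Instance ids are stable
#'   per lineage segment across frames.
#' @export
simulate_timelapse <- function(config = simulation_config()) {
  with_seed(config$seed, {
    H <- config$image_shape[1]; W <- config$image_shape[2]
    margin <- 2.2 * config$radius_mean
    sep_spawn <- 70
    n <- config$n_cells
    # spawn positions
    pos <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      for (try in 1:2000) {
        p <- c(stats::runif(1, margin, W - margin),
               stats::runif(1, margin, H - margin))
        if (i == 1 || all(sqrt(rowSums((pos[seq_len(i - 1), , drop = FALSE] -
              matrix(p, i - 1, 2, byrow = TRUE))^2)) >= sep_spawn)) {
          pos[i, ] <- p
          break
        }
      }
      if (is.na(pos[i, 1])) {
        stop("configuration error: could not place all cells", call. = FALSE)
      }
    }
    # per-cell static shape parameters
    cells <- data.frame(
      id = seq_len(n), parent = NA_integer_,
      birth = 0L, death = config$n_frames,  # death = division frame (exclusive)
      r = pmin(pmax(stats::rnorm(n, config$radius_mean, config$radius_sd),
                    config$radius_mean * 0.66), config$radius_mean * 1.33),
      ecc = stats::runif(n, 1.02, 1.2),
      theta = stats::runif(n, 0, pi),
      omega = stats::rnorm(n, 0, 0.03),
      phase_offset = sample.int(60L, n, replace = TRUE) - 1L,
      divides = FALSE, div_frame = NA_integer_)
    cells$x <- pos[, 1]; cells$y <- pos[, 2]
    # division schedule
    K <- config$n_divisions
    if (K > 0) {
      if (config$n_frames < 30) {
        stop("configuration error: divisions need >= 30 frames", call. = FALSE)
      }
      movers <- sample.int(n, K)
      dfr <- round(seq(0.3 * config$n_frames, 0.7 * config$n_frames,
                       length.out = K))
      cells$divides[movers] <- TRUE
      cells$div_frame[movers] <- as.integer(dfr)
      cells$death[movers] <- as.integer(dfr)
    }
    next_id <- n + 1L
    swell <- sqrt(1.5)  # linear swell of an M-phase mother (area x1.5)

    # trajectory simulation
    state <- cells  # live table; rows removed at death, daughters appended
    traj <- list()  # per frame: data.frame of live cells
    events <- list()
    for (t in seq_len(config$n_frames) - 1L) {
      # divisions occurring at this frame
      due <- which(!is.na(state$div_frame) & state$div_frame == t)
      for (i in sort(due, decreasing = TRUE)) {
        m <- state[i, ]
        ang <- stats::runif(1, 0, 2 * pi)
        rd <- m$r * swell * sqrt(config$daughter_area_fraction)
        off <- rd * 1.3 + 1.5
        d <- m[c(1, 1), ]
        d$id <- c(next_id, next_id + 1L)
        d$parent <- m$id
        d$birth <- t
        d$death <- config$n_frames
        d$r <- rd
        d$divides <- FALSE
        d$div_frame <- NA_integer_
        d$x <- pmin(pmax(m$x + c(1, -1) * off * cos(ang), margin), W - margin)
        d$y <- pmin(pmax(m$y + c(1, -1) * off * sin(ang), margin), H - margin)
        d$theta <- stats::runif(2, 0, pi)
        d$phase_offset <- 0L
        events[[length(events) + 1L]] <- list(frame = t, mother = m$id,
                                              daughters = d$id)
        state <- rbind(state[-i, ], d)
        next_id <- next_id + 2L
      }
      # random-walk step with collision avoidance (skip frame 0)
      if (t > 0) {
        for (i in seq_len(nrow(state))) {
          if (state$birth[i] == t) next  # daughters placed this frame
          for (try in 1:8) {
            nx <- state$x[i] + stats::rnorm(1, 0, config$motion_sigma)
            ny <- state$y[i] + stats::rnorm(1, 0, config$motion_sigma)
            nx <- min(max(nx, margin), W - margin)
            ny <- min(max(ny, margin), H - margin)
            others <- setdiff(seq_len(nrow(state)), i)
            sibling <- !is.na(state$parent[i]) &
              !is.na(state$parent[others]) &
              state$parent[others] == state$parent[i]
            lim <- 1.6 * (state$r[i] + state$r[others]) + 6
            lim[sibling] <- 1.25 * (state$r[i] + state$r[others][sibling]) + 2
            if (length(others) == 0 ||
                all(sqrt((state$x[others] - nx)^2 +
                         (state$y[others] - ny)^2) >= lim)) {
              state$x[i] <- nx; state$y[i] <- ny
              break
            }
          }
          state$theta[i] <- state$theta[i] + state$omega[i]
        }
      }
      traj[[t + 1L]] <- state
    }

    # rasterization + class labels + truth forest
    forest <- new_forest()
    branch_of <- list()  # lineage id -> branch id
    frames <- vector("list", config$n_frames)
    for (t in seq_len(config$n_frames) - 1L) {
      st <- traj[[t + 1L]]
      st <- st[order(st$id), , drop = FALSE]
      insts <- list()
      for (i in seq_len(nrow(st))) {
        ci <- st[i, ]
        r_eff <- ci$r
        is_m <- FALSE
        if (ci$divides && t >= ci$div_frame - 2L) {  # mother swells, M phase
          r_eff <- ci$r * swell
          is_m <- TRUE
        }
        if (!is.na(ci$parent) && t - ci$birth < 2L) is_m <- TRUE
        cls <- NULL
        if (config$with_classes) {
          cls <- if (is_m) "M" else if (ci$divides) {
            phase_cycle(ci$div_frame - 3L - t)
          } else if (!is.na(ci$parent)) {
            phase_cycle(t - ci$birth - 2L)
          } else {
            phase_cycle(t + ci$phase_offset)
          }
        }
        wob <- 1 + 0.02 * sin(0.7 * t + ci$id)
        ras <- rasterize_ellipse(ci$x, ci$y, r_eff * ci$ecc * wob,
                                 r_eff / ci$ecc, ci$theta,
                                 config$image_shape)
        insts[[length(insts) + 1L]] <- instance_from_mask(
          ras$mask, ras$offset, frame = t, instance_id = ci$id,
          class_label = cls)
      }
      frames[[t + 1L]] <- frame_segmentation(t, insts, config$image_shape)
      # grow the truth forest
      ev_now <- Filter(function(e) e$frame == t, events)
      for (e in ev_now) {
        d1 <- Filter(function(x) x$instance_id == e$daughters[1], insts)[[1]]
        d2 <- Filter(function(x) x$instance_id == e$daughters[2], insts)[[1]]
        forest <- open_division(forest, branch_of[[as.character(e$mother)]],
                                d1, d2, t)
        branch_of[[as.character(e$daughters[1])]] <- forest$last_daughter_ids[1]
        branch_of[[as.character(e$daughters[2])]] <- forest$last_daughter_ids[2]
      }
      born <- vapply(events, function(e) e$frame == t, logical(1))
      newborn <- if (any(born)) unlist(lapply(events[born], `[[`, "daughters"))
                 else integer(0)
      for (inst in insts) {
        key <- as.character(inst$instance_id)
        if (inst$instance_id %in% newborn && t > 0) next  # added above
        if (is.null(branch_of[[key]]) || is.na(branch_of[[key]])) {
          forest <- new_tree(forest, inst)
          branch_of[[key]] <- forest$last_branch_id
        } else {
          forest <- add_node(forest, branch_of[[key]], inst)
        }
      }
    }
    forest$n_frames <- config$n_frames
    truth_div <- forest_divisions(forest)
    list(frames = frames, truth = forest, divisions = truth_div)
  })
}

#' Corrupt a movie with detection dropout and false-positive blobs
#'
#' Each instance is deleted independently with probability `p`; per frame,
#' `Poisson(q)` spurious small single-frame blobs are added at positions
#' clear of real cells (and of other blobs in nearby frames, so blobs never
#' link to anything). `fp_count` injects an exact total number of blobs
#' instead of a rate. The ground truth is untouched.
#'
#' @param frames list of [frame_segmentation()].
#' @param p per-instance dropout probability.
#' @param q expected false-positive blobs per frame.
#' @param seed RNG seed.
#' @param fp_count exact number of blobs to inject (overrides `q`).
#' @param max_gap optional cap on consecutive dropped frames per instance
#'   id (deletions that would exceed it are skipped).
#' @return List with `frames`, `n_dropped`, `n_fp`.
#' @export
corrupt_dropout_fp <- function(frames, p = 0, q = 0, seed = 1L,
                               fp_count = NULL, max_gap = NULL) {
  stopifnot(p >= 0, p <= 1, q >= 0)
  with_seed(seed, {
    shape <- frames[[1]]$image_shape
    H <- shape[1]; W <- shape[2]
    miss_run <- new.env(parent = emptyenv())
    n_dropped <- 0L
    out <- frames
    if (p > 0) {
      for (k in seq_along(out)) {
        fs <- out[[k]]
        keep <- logical(length(fs$instances))
        for (j in seq_along(fs$instances)) {
          id <- as.character(fs$instances[[j]]$instance_id)
          run <- if (is.null(miss_run[[id]])) 0L else miss_run[[id]]
          drop <- stats::runif(1) < p
          if (drop && !is.null(max_gap) && run + 1L > max_gap) drop <- FALSE
          keep[j] <- !drop
          miss_run[[id]] <- if (drop) run + 1L else 0L
        }
        n_dropped <- n_dropped + sum(!keep)
        out[[k]] <- frame_segmentation(fs$frame, fs$instances[keep], shape)
      }
    }
    # false positives
    n_per_frame <- integer(length(out))
    if (!is.null(fp_count)) {
      stopifnot(fp_count <= length(out))
      hit <- sample.int(length(out), fp_count)
      n_per_frame[hit] <- 1L
    } else if (q > 0) {
      n_per_frame <- stats::rpois(length(out), q)
    }
    blobs <- NULL  # (frame, x, y) of placed blobs
    n_fp <- 0L
    for (k in seq_along(out)) {
      nk <- n_per_frame[k]
      if (nk == 0) next
      fs <- out[[k]]
      cent <- t(vapply(fs$instances, function(ci) ci$centroid, numeric(2)))
      for (b in seq_len(nk)) {
        for (try in 1:500) {
          bx <- stats::runif(1, 20, W - 20)
          by <- stats::runif(1, 20, H - 20)
          ok <- (nrow(cent) == 0 ||
                 all(sqrt((cent[, 1] - bx)^2 + (cent[, 2] - by)^2) >= 40))
          if (ok && !is.null(blobs)) {
            near <- abs(blobs[, 1] - (k - 1)) <= 6
            ok <- all(sqrt((blobs[near, 2] - bx)^2 +
                           (blobs[near, 3] - by)^2) >= 100)
          }
          if (ok) break
        }
        r <- stats::runif(1, 3, 5)
        ras <- rasterize_ellipse(bx, by, r, r * 0.9, 0, shape)
        n_fp <- n_fp + 1L
        blob <- instance_from_mask(ras$mask, ras$offset, frame = fs$frame,
                                   instance_id = 10000L + n_fp)
        fs$instances[[length(fs$instances) + 1L]] <- blob
        blobs <- rbind(blobs, c(k - 1, bx, by))
      }
      out[[k]] <- frame_segmentation(fs$frame, fs$instances, shape)
    }
    list(frames = out, n_dropped = n_dropped, n_fp = n_fp)
  })
}

#' Corrupt class labels with i.i.d. noise
#'
#' Each label is independently replaced, with probability `r`, by a
#' different class drawn uniformly from the observed vocabulary (or by
#' `confusion` weights).
#'
#' @param frames list of [frame_segmentation()].
#' @param r flip probability in `[0, 1]`.
#' @param seed RNG seed.
#' @param confusion optional named list: for each source class, a named
#'   weight vector over target classes.
#' @return List with `frames` and `n_flipped`.
#' @export
corrupt_classes <- function(frames, r, seed = 1L, confusion = NULL) {
  stopifnot(r >= 0, r <= 1)
  vocab <- sort(unique(unlist(lapply(frames, function(fs)
    lapply(fs$instances, function(ci) ci$class_label)))))
  if (length(vocab) < 2) {
    stop("need at least two observed classes to add label noise", call. = FALSE)
  }
  with_seed(seed, {
    n_flipped <- 0L
    out <- frames
    for (k in seq_along(out)) {
      fs <- out[[k]]
      for (j in seq_along(fs$instances)) {
        cls <- fs$instances[[j]]$class_label
        if (is.null(cls)) next
        if (stats::runif(1) < r) {
          others <- setdiff(vocab, cls)
          new_cls <- if (!is.null(confusion) && !is.null(confusion[[cls]])) {
            w <- confusion[[cls]][others]
            w[is.na(w)] <- 0
            sample(others, 1, prob = w)
          } else sample(others, 1)
          fs$instances[[j]]$class_label <- new_cls
          n_flipped <- n_flipped + 1L
        }
      }
      out[[k]] <- fs
    }
    list(frames = out, n_flipped = n_flipped)
  })
}
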