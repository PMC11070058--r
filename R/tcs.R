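# Class smoothing along lineage branches. A classifier's per-frame labels
# flicker stochastically; a real phase transition persists. The smoothing
# rule adopts the branch's first label as the running default, and at each
# node whose label deviates it looks ahead up to `window` nodes: if the
# deviating label strictly exceeds `threshold` of that lookahead, the
# default switches there; otherwise the deviating node is rewritten to the
# default. The search never crosses a division: each branch is smoothed
# independently and daughters start fresh from their own first label.

#' Smooth one branch's class label sequence
#'
#' @param classes character vector of raw labels along one branch, frame
#'   order. `NA` labels never trigger a switch and are rewritten to the
#'   running default.
#' @param window forward lookahead in nodes (default 9); shrinks to the
#'   nodes remaining near the branch end.
#' @param threshold fraction of the lookahead that must carry the deviating
#'   label, strictly exceeded, for the switch to be adopted (default 0.60:
#'   6 of 9 switches, 5 of 9 does not).
#' @param min_tail with fewer than this many nodes remaining after the
#'   trigger, no switch is allowed (default 3; a decision on 1-2 samples is
#'   not trusted).
#' @return Character vector of smoothed labels, same length.
#' @export
smooth_branch <- function(classes, window = 9L, threshold = 0.60,
                          min_tail = 3L) {
  n <- length(classes)
  if (n == 0) return(character(0))
  out <- classes
  default <- classes[1]
  for (i in seq_len(n)[-1]) {
    x <- classes[i]
    if (is.na(x)) {
      out[i] <- default
      next
    }
    if (is.na(default)) {  # branch started unlabelled: adopt first label
      default <- x
      next
    }
    if (x == default) {
      out[i] <- default
      next
    }
    remaining <- n - i
    k <- min(window, remaining)
    switch_ok <- FALSE
    if (remaining >= min_tail && k > 0) {
      cnt <- sum(classes[(i + 1):(i + k)] == x, na.rm = TRUE)
      switch_ok <- (cnt / k) > threshold
    }
    if (switch_ok) {
      default <- x
      out[i] <- x
    } else {
      out[i] <- default
    }
  }
  out
}

#' Apply class smoothing to every branch of a forest
#'
#' Writes `smoothed_class` on every node; `raw_class` is untouched.
#' Gap-fill nodes carry the copied raw class of their source node and
#' participate in the smoothing windows. A forest without any class labels
#' is returned unchanged with a warning.
#'
#' @param forest a refined `track_forest`.
#' @param config a [tracker_config()] (supplies `tcs_window` and
#'   `tcs_threshold`).
#' @param thresholds optional named per-class threshold map overriding
#'   `tcs_threshold` for switches *into* the named class.
#' @return The forest with `smoothed_class` populated.
#' @export
apply_tcs <- function(forest, config = tracker_config(), thresholds = NULL) {
  any_class <- any(vapply(forest$branches, function(b)
    any(!is.na(vapply(b$nodes, function(nd) nd$raw_class, character(1)))),
    logical(1)))
  if (!any_class) {
    warning("no class labels in forest; class smoothing is a no-op",
            call. = FALSE)
    return(forest)
  }
  for (key in names(forest$branches)) {
    br <- forest$branches[[key]]
    raw <- vapply(br$nodes, function(nd) nd$raw_class, character(1))
    sm <- if (is.null(thresholds)) {
      smooth_branch(raw, config$tcs_window, config$tcs_threshold)
    } else {
      smooth_branch_perclass(raw, config$tcs_window, config$tcs_threshold,
                             thresholds)
    }
    for (k in seq_along(br$nodes)) br$nodes[[k]]$smoothed_class <- sm[k]
    forest$branches[[key]] <- br
  }
  forest
}

# variant with a per-class threshold map for the switch-into class
smooth_branch_perclass <- function(classes, window, threshold, thresholds,
                                   min_tail = 3L) {
  n <- length(classes)
  if (n == 0) return(character(0))
  out <- classes
  default <- classes[1]
  for (i in seq_len(n)[-1]) {
    x <- classes[i]
    if (is.na(x)) { out[i] <- default; next }
    if (is.na(default)) { default <- x; next }
    if (x == default) { out[i] <- default; next }
    thr <- if (!is.null(thresholds[[x]])) thresholds[[x]] else threshold
    remaining <- n - i
    k <- min(window, remaining)
    ok <- FALSE
    if (remaining >= min_tail && k > 0) {
      cnt <- sum(classes[(i + 1):(i + k)] == x, na.rm = TRUE)
      ok <- (cnt / k) > thr
    }
    if (ok) { default <- x; out[i] <- x } else out[i] <- default
  }
  out
}
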