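#' Inverse-distance similarity of two cell centroids
#'
#' `1 / (1e-5 + d)` where `d` is the Euclidean centroid distance, so the
#' value is strictly decreasing in distance and capped at `1e5` for
#' coincident centroids.
#'
#' @param ci,cj [cell_instance()] objects.
#' @return Positive real, at most `1e5`.
#' @export
dis <- function(ci, cj) {
  d <- sqrt(sum((ci$centroid - cj$centroid)^2))
  1 / (1e-5 + d)
}

#' Hu-moment shape distance
#'
#' `sum_n |1/m_n(i) - 1/m_n(j)|` over the 7 Hu invariants; 0 for congruent
#' shapes (translation, rotation, uniform scale). Terms where either
#' invariant is exactly 0 are skipped (a reciprocal would be undefined) with
#' a message.
#'
#' @param ci,cj [cell_instance()] objects carrying 7 (transformed) Hu
#'   invariants.
#' @return Nonnegative real; this is a *dissimilarity* (0 = identical).
#' @export
sps <- function(ci, cj) {
  mi <- ci$hu; mj <- cj$hu
  ok <- mi != 0 & mj != 0
  if (!all(ok)) {
    message("sps: skipping ", sum(!ok), " zero Hu moment term(s)")
  }
  sum(abs(1 / mi[ok] - 1 / mj[ok]))
}

#' Area-ratio similarity
#'
#' `min(areas) / max(areas)`; 1 iff the areas are equal.
#'
#' @param ci,cj [cell_instance()] objects with positive areas.
#' @return Value in `(0, 1]`.
#' @export
sas <- function(ci, cj) {
  if (!(ci$area > 0) || !(cj$area > 0)) {
    stop("degenerate contour: zero area", call. = FALSE)
  }
  min(ci$area, cj$area) / max(ci$area, cj$area)
}

#' Intensity similarity term
#'
#' Sum of the smaller-over-larger ratio of intensity means and of intensity
#' variances; each ratio lies in `(0, 1]` so the value is at most 2 and
#' equals 2 for identical statistics. Returns 0 when either instance lacks
#' intensity data, so the term vanishes cleanly from the similarity index.
#'
#' @param ci,cj [cell_instance()] objects.
#' @return Nonnegative real.
#' @export
delta_intensity <- function(ci, cj) {
  if (is.null(ci$intensity_mean) || is.null(cj$intensity_mean)) return(0)
  ratio <- function(a, b) {
    if (a == b) return(1)  # covers the 0/0 case
    min(a, b) / max(a, b)
  }
  ratio(ci$intensity_mean, cj$intensity_mean) +
    ratio(ci$intensity_var, cj$intensity_var)
}

#' Five-component similarity index between two cell instances
#'
#' `total = w1*IoU + w2*Dis + w3*Sps + w4*Sas + w5*Delta`, the default
#' weights of all `+1` reproducing the plain sum of the five components.
#' Note that `Sps` is a dissimilarity (0 = identical shapes); the unweighted
#' sum is kept as the default, and a negative `Sps` weight can be configured
#' instead. No normalization of component scales is applied, so the
#' inverse-distance term dominates at short range.
#'
#' @param ci,cj [cell_instance()] objects.
#' @param weights numeric length-5 vector `(iou, dis, sps, sas, delta)`.
#' @return Object of class `similarity_breakdown` with fields `iou`, `dis`,
#'   `sps`, `sas`, `delta` and `total`.
#' @export
similarity_index <- function(ci, cj, weights = c(1, 1, 1, 1, 1)) {
  stopifnot(length(weights) == 5, is.numeric(weights))
  comp <- c(iou = mask_iou(ci, cj), dis = dis(ci, cj),
            sps = sps(ci, cj), sas = sas(ci, cj),
            delta = delta_intensity(ci, cj))
  structure(c(as.list(comp), list(total = sum(weights * comp))),
            class = "similarity_breakdown")
}

#' @export
print.similarity_breakdown <- function(x, ...) {
  cat(sprintf(
    "similarity: total=%.6g (iou=%.4g dis=%.4g sps=%.4g sas=%.4g delta=%.4g)\n",
    x$total, x$iou, x$dis, x$sps, x$sas, x$delta))
  invisible(x)
}
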