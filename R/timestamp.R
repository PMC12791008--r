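## Timestamping static samples onto a morphological timeline, with a
## chi-squared-curvature uncertainty.

#' Timestamp a static sample onto a timeline
#'
#' Places a fixed (snapshot) sample on a consensus timeline by minimizing the
#' chi-squared mismatch between the sample's morphological feature and the
#' timeline's feature at each frame, then reports a 1-sigma uncertainty from
#' the curvature of chi-squared: `sigma_t^2 = 2 / (d2 chi2 / dt2)` at the
#' minimum, with the curvature read off a parabola fitted around the minimum.
#'
#' The feature can be any numeric descriptor on a fixed layout, e.g. a
#' rasterized stripe-band image; residuals are standardized by `noise_sd`
#' (estimated from the best-fit residuals when not supplied), so chi-squared
#' has its conventional scale and the curvature formula yields calibrated
#' intervals.
#'
#' @param sample_feature numeric vector (or `field_frame`) for the sample.
#' @param timeline_features matrix with one row per timeline frame (or list of
#'   vectors / `field_frame`s) of the same feature.
#' @param times frame times of the timeline (min); default `0:(nframes-1)`.
#' @param window half-width of the parabola fit in frames (default 5).
#' @param noise_sd feature noise s.d.; `NULL` estimates it as
#'   `sqrt(min RSS / length(feature))`.
#' @param n_members number of live members backing the timeline; fewer than 3
#'   is an error (a robust timeline needs at least three recordings).
#' @return object of class `timestamp`: `t0` (min, parabola vertex), `sigma_t`
#'   (min), `chi2_curve` (per-frame chi-squared), `times`, `frame`.
#' @export
timestamp_fixed <- function(sample_feature, timeline_features, times = NULL,
                            window = 5L, noise_sd = NULL, n_members = NULL) {
  feat <- function(x) if (inherits(x, "field_frame")) as.numeric(x$values)
                      else as.numeric(x)
  s <- feat(sample_feature)
  if (is.list(timeline_features))
    timeline_features <- do.call(rbind, lapply(timeline_features, feat))
  tf <- as.matrix(timeline_features)
  nt <- nrow(tf)
  if (ncol(tf) != length(s))
    stop_morph("invalid_feature", "feature lengths differ")
  if (!is.null(n_members) && n_members < 3L)
    stop_morph("insufficient_members",
               "timestamping requires a minimum of three live samples")
  times <- times %||% (seq_len(nt) - 1)
  rss <- colSums((t(tf) - s)^2, na.rm = TRUE)
  k <- which.min(rss)
  if (is.null(noise_sd)) {
    nfeat <- sum(!is.na(s))
    noise_sd <- sqrt(max(rss[k], .Machine$double.eps) / nfeat)
  }
  chi2 <- rss / noise_sd^2
  timestamp_from_chi2(chi2, times, window)
}

#' Timestamp from a precomputed chi-squared curve
#'
#' Lower-level entry point of [timestamp_fixed()]: given chi-squared sampled
#' per timeline frame, locates the minimum, fits a parabola on `+/- window`
#' frames and converts its curvature into the 1-sigma timestamp uncertainty
#' `sigma_t = sqrt(2 / chi2'')`.
#'
#' @param chi2 numeric chi-squared per frame.
#' @param times frame times (min); default `0:(n-1)`.
#' @param window parabola half-width in frames.
#' @return a `timestamp` object.
#' @export
timestamp_from_chi2 <- function(chi2, times = NULL, window = 5L) {
  nt <- length(chi2)
  times <- times %||% (seq_len(nt) - 1)
  k <- which.min(chi2)
  if (k == 1L || k == nt)
    warn_morph("boundary_timestamp",
               "chi-squared minimum lies on the timeline boundary")
  lo <- max(1L, k - window); hi <- min(nt, k + window)
  idx <- lo:hi
  ## restrict the fit to the quadratic core of chi-squared (delta chi2 <= 9,
  ## the 3-sigma region): far from the minimum the mismatch saturates as the
  ## patterns decorrelate and a parabola through the tails would bias both
  ## the vertex and the curvature
  core <- idx[chi2[idx] <= chi2[k] + 9]
  if (length(core) < 3L) {
    near <- idx[order(abs(idx - k))]
    core <- sort(near[seq_len(min(3L, length(near)))])
  }
  tt <- times[core]; cc <- chi2[core]
  if (length(tt) < 3L)
    stop_morph("uncertainty_undefined", "too few frames for the parabola fit")
  fit <- stats::lm(cc ~ tt + I(tt^2))
  a <- unname(stats::coef(fit)[3])
  if (!is.finite(a) || a <= 0)
    stop_morph("uncertainty_undefined", "non-convex parabola fit")
  b <- unname(stats::coef(fit)[2])
  vertex <- -b / (2 * a)
  t0 <- min(max(vertex, min(tt)), max(tt))
  sigma_t <- sqrt(2 / (2 * a))      # sigma^2 = 2 * (d2chi2/dt2)^-1, d2/dt2 = 2a
  structure(list(t0 = t0, sigma_t = sigma_t, chi2_curve = chi2,
                 times = times, frame = k),
            class = "timestamp")
}

#' @export
print.timestamp <- function(x, ...) {
  cat(sprintf("<timestamp> t0 = %.3g +/- %.3g min (1-sigma)\n",
              x$t0, x$sigma_t))
  invisible(x)
}
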