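## Rigid (shift-only) time alignment from landmark events.

#' Landmark time from an autocorrelation matrix transition
#'
#' Rigid alignment shifts each timeline so that a landmark event is
#' simultaneous. The landmark used for early-embryo flow is the sharp sign
#' change of the posterior vorticity pattern at the onset of axis extension,
#' detected on the square vorticity autocorrelation matrix `M` as
#' `t0 = argmax_x sum_y dM(x, y)/dx`: the column where the correlation
#' structure changes fastest.
#'
#' @param m_self a square [similarity_matrix()] (self-correlation).
#' @param tol relative tolerance for declaring the maximum ambiguous.
#' @return object of class `landmark_time` with fields `t0` (min), `frame`
#'   (1-based index of the first frame after the transition) and `method`.
#' @export
rigid_offset <- function(m_self, tol = 1e-9) {
  v <- m_self$values
  if (nrow(v) != ncol(v))
    stop_morph("invalid_matrix", "autocorrelation matrix must be square")
  n <- nrow(v)
  ## column-wise derivative profile along x (columns), summed over y (rows):
  ## d(x) = sum_y M(x, y) - M(x-1, y), for x = 2..n
  d <- colSums(v[, -1, drop = FALSE] - v[, -n, drop = FALSE], na.rm = TRUE)
  if (length(d) == 0L || diff(range(d)) <= tol * max(1, max(abs(d))))
    stop_morph("ambiguous_landmark", "derivative profile is flat")
  best <- which.max(d)
  scale <- max(1, abs(d[best]))
  if (sum(d >= d[best] - tol * scale) > 1L)
    stop_morph("ambiguous_landmark", "landmark maximum is not unique")
  frame <- best + 1L           # d[k] compares columns k and k+1
  new_landmark_time(m_self$times_a[frame], frame, "vorticity_flip")
}

new_landmark_time <- function(t0, frame, method) {
  structure(list(t0 = t0, frame = frame, method = method),
            class = "landmark_time")
}

#' Flow onset from maximum acceleration of the speed curve
#'
#' The onset of axis extension is the timepoint of maximum acceleration,
#' i.e. the maximum forward difference of the (optionally smoothed) r.m.s.
#' speed curve; it defines `t = 0` for rigid alignment across conditions.
#' Exact ties return the earliest frame with a warning.
#'
#' @param sc a [speed_curve()] with at least 5 frames.
#' @param smooth_window odd moving-average window in frames (1 = none).
#' @param tol absolute tie tolerance on the difference values.
#' @return a `landmark_time` with `method = "max_acceleration"`.
#' @export
onset_from_acceleration <- function(sc, smooth_window = 1L, tol = 1e-12) {
  s <- sc$speeds
  if (length(s) < 5L)
    stop_morph("invalid_curve", "need at least 5 frames for onset detection")
  if (smooth_window > 1L) {
    k <- rep(1 / smooth_window, smooth_window)
    sm <- stats::filter(s, k, sides = 2)
    s <- ifelse(is.na(sm), s, as.numeric(sm))
  }
  d <- diff(s)
  best <- which.max(d)
  ties <- which(d >= d[best] - tol)
  if (length(ties) > 1L) {
    best <- min(ties)
    warn_morph("onset_tie", sprintf(
      "%d tied acceleration maxima; returning earliest frame %d",
      length(ties), best))
  }
  new_landmark_time(sc$times[best], best, "max_acceleration")
}

#' @export
print.landmark_time <- function(x, ...) {
  cat(sprintf("<landmark_time> t0 = %.3g min (frame %d, %s)\n",
              x$t0, x$frame, x$method))
  invisible(x)
}
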