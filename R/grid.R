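#' Grid specification for cartographic chart fields
#'
#' Describes the rectangular lattice on which scalar images and tangent
#' velocity fields live. `x1` is the longitudinal coordinate along the embryo
#' axis (truncated near the poles where projections distort), `x2` the
#' circumferential coordinate around the dorsoventral axis, which is periodic
#' on a cylindrical chart.
#'
#' @param n1,n2 integer node counts along `x1` (columns of the chart) and `x2`.
#' @param spacing1,spacing2 physical node spacing in micrometres.
#' @param periodic2 logical; is `x2` periodic (cylindrical chart)?
#' @param truncation_fraction fraction of the `x1` range removed at *each* end
#'   before analysis (default 0.08, i.e. ~8 percent per end).
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n1, n2, spacing1 = 1, spacing2 = 1,
                      periodic2 = TRUE, truncation_fraction = 0.08) {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 < 4L || n2 < 4L)
    stop_morph("invalid_grid", "grid must be at least 4x4")
  if (spacing1 <= 0 || spacing2 <= 0)
    stop_morph("invalid_grid", "grid spacings must be positive")
  if (truncation_fraction < 0 || truncation_fraction >= 0.5)
    stop_morph("invalid_grid", "truncation_fraction must lie in [0, 0.5)")
  structure(
    list(n1 = n1, n2 = n2, spacing1 = spacing1, spacing2 = spacing2,
         periodic2 = isTRUE(periodic2),
         truncation_fraction = truncation_fraction),
    class = "grid_spec")
}

grid_same <- function(a, b) {
  a$n1 == b$n1 && a$n2 == b$n2 &&
    isTRUE(all.equal(a$spacing1, b$spacing1)) &&
    isTRUE(all.equal(a$spacing2, b$spacing2)) &&
    a$periodic2 == b$periodic2
}

## Physical x1/x2 coordinates of grid nodes (0-based origin).
grid_x1 <- function(g) (seq_len(g$n1) - 1) * g$spacing1
grid_x2 <- function(g) (seq_len(g$n2) - 1) * g$spacing2

#' Scalar field on a grid at one timepoint
#'
#' @param values numeric matrix, `n1 x n2` (rows index `x1`, columns `x2`).
#'   `NA` entries mark missing nodes.
#' @param grid a [grid_spec()].
#' @param time frame time in minutes on the owning timeline.
#' @return object of class `field_frame`.
#' @export
field_frame <- function(values, grid, time = 0) {
  values <- as.matrix(values)
  if (nrow(values) != grid$n1 || ncol(values) != grid$n2)
    stop_morph("invalid_grid", sprintf(
      "values are %dx%d but grid is %dx%d", nrow(values), ncol(values),
      grid$n1, grid$n2))
  if (any(is.infinite(values)))
    stop_morph("invalid_values", "field values must be finite or NA")
  structure(list(values = values, grid = grid, time = time),
            class = "field_frame")
}

#' Time-ordered sequence of scalar field frames
#'
#' @param frames list of [field_frame()] on a shared grid with strictly
#'   increasing, uniformly spaced times.
#' @param dt frame interval in minutes; inferred from times when `NULL`.
#' @return object of class `field_sequence`.
#' @export
field_sequence <- function(frames, dt = NULL) {
  if (length(frames) == 0L) stop_morph("invalid_sequence", "empty sequence")
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1L) {
    steps <- diff(times)
    if (any(steps <= 0)) stop_morph("invalid_sequence",
                                    "frame times must be strictly increasing")
    if (max(steps) - min(steps) > 1e-9 * max(steps))
      stop_morph("invalid_sequence", "frame interval must be uniform")
    dt <- dt %||% steps[1]
  } else dt <- dt %||% 1
  g <- frames[[1]]$grid
  for (f in frames) if (!grid_same(f$grid, g))
    stop_morph("invalid_sequence", "all frames must share one grid")
  structure(list(frames = frames, dt = dt, times = times, grid = g),
            class = "field_sequence")
}

#' Tangent velocity field on a grid at one timepoint
#'
#' @param v1,v2 numeric matrices (`n1 x n2`) of velocity components in
#'   micrometres per minute along `x1` and `x2`.
#' @param grid a [grid_spec()].
#' @param time frame time (min).
#' @param valid optional logical matrix; `FALSE` nodes are excluded from all
#'   statistics (PIV dropouts, truncated poles).
#' @return object of class `velocity_frame`.
#' @export
velocity_frame <- function(v1, v2, grid, time = 0, valid = NULL) {
  v1 <- as.matrix(v1); v2 <- as.matrix(v2)
  if (!all(dim(v1) == c(grid$n1, grid$n2)) ||
      !all(dim(v2) == c(grid$n1, grid$n2)))
    stop_morph("invalid_grid", "velocity component dimensions must match grid")
  if (is.null(valid)) valid <- !(is.na(v1) | is.na(v2))
  valid <- as.matrix(valid) & !(is.na(v1) | is.na(v2))
  structure(list(v1 = v1, v2 = v2, grid = grid, time = time, valid = valid),
            class = "velocity_frame")
}

#' Time-ordered sequence of velocity frames
#'
#' @param frames list of [velocity_frame()]; shared grid, uniform times.
#' @param dt frame interval (min); inferred when `NULL`.
#' @return object of class `velocity_sequence`.
#' @export
velocity_sequence <- function(frames, dt = NULL) {
  if (length(frames) == 0L) stop_morph("invalid_sequence", "empty sequence")
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1L) {
    steps <- diff(times)
    if (any(steps <= 0)) stop_morph("invalid_sequence",
                                    "frame times must be strictly increasing")
    if (max(steps) - min(steps) > 1e-9 * max(abs(steps)))
      stop_morph("invalid_sequence", "frame interval must be uniform")
    dt <- dt %||% steps[1]
  } else dt <- dt %||% 1
  g <- frames[[1]]$grid
  for (f in frames) if (!grid_same(f$grid, g))
    stop_morph("invalid_sequence", "all frames must share one grid")
  structure(list(frames = frames, dt = dt, times = times, grid = g),
            class = "velocity_sequence")
}

#' Landmark polyline in chart coordinates
#'
#' An ordered curve such as the anterior boundary of a pair-rule stripe,
#' used as a morphological clock hand.
#'
#' @param points two-column matrix of `(x1, x2)` positions in micrometres.
#' @param closed2 logical; does the curve wrap around the periodic `x2` axis?
#' @return object of class `stripe_curve`.
#' @export
stripe_curve <- function(points, closed2 = FALSE) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 3L)
    stop_morph("invalid_curve", "curve needs >= 3 (x1, x2) points")
  d <- rowSums(abs(diff(points)))
  if (any(d == 0))
    stop_morph("invalid_curve", "consecutive curve points must be distinct")
  structure(list(points = points, closed2 = isTRUE(closed2)),
            class = "stripe_curve")
}

#' Root-mean-square surface speed trace
#'
#' @param times frame times (min).
#' @param speeds r.m.s. speeds (micrometres per minute), one per frame.
#' @return object of class `speed_curve`.
#' @export
speed_curve <- function(times, speeds) {
  if (length(times) != length(speeds))
    stop_morph("invalid_curve", "times and speeds must have equal length")
  if (any(speeds < 0, na.rm = TRUE))
    stop_morph("invalid_curve", "speeds must be nonnegative")
  structure(list(times = as.numeric(times), speeds = as.numeric(speeds)),
            class = "speed_curve")
}

#' Apply chart grid conventions (pole truncation) to a sequence
#'
#' Removes `ceiling(truncation_fraction * n1)` columns of the chart at each
#' `x1` end, mirroring the practice of discarding the distorted pole regions
#' before any statistics. The periodic `x2` axis is untouched; downstream
#' finite differences and block matching wrap in `x2` by index arithmetic.
#'
#' @param seq a [field_sequence()] or [velocity_sequence()].
#' @param spec a [grid_spec()] carrying `truncation_fraction`; defaults to the
#'   sequence's own grid.
#' @return a sequence of the same class on the truncated grid.
#' @export
apply_grid_conventions <- function(seq, spec = NULL) {
  spec <- spec %||% seq$grid
  g <- seq$grid
  k <- as.integer(ceiling(spec$truncation_fraction * g$n1))
  if (k == 0L) return(seq)
  keep <- seq.int(k + 1L, g$n1 - k)
  if (length(keep) < 1L)
    stop_morph("invalid_grid", "truncation removes the whole x1 range")
  ng <- g
  ng$n1 <- length(keep)
  ng$truncation_fraction <- 0
  ng <- structure(ng, class = "grid_spec")
  if (ng$n1 < 4L) {
    ## keep the object usable for statistics even when tiny; the constructor
    ## minimum applies to fresh grids, not truncation leftovers
    if (ng$n1 < 1L) stop_morph("invalid_grid", "truncation removes everything")
  }
  sub_frame <- function(f) {
    if (inherits(f, "field_frame")) {
      structure(list(values = f$values[keep, , drop = FALSE], grid = ng,
                     time = f$time), class = "field_frame")
    } else {
      structure(list(v1 = f$v1[keep, , drop = FALSE],
                     v2 = f$v2[keep, , drop = FALSE], grid = ng,
                     time = f$time,
                     valid = f$valid[keep, , drop = FALSE]),
                class = class(f))
    }
  }
  out <- seq
  out$frames <- lapply(seq$frames, sub_frame)
  out$grid <- ng
  out
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d nodes, spacing %.3g x %.3g um%s\n",
              x$n1, x$n2, x$spacing1, x$spacing2,
              if (x$periodic2) ", periodic x2" else ""))
  invisible(x)
}

#' @export
print.field_sequence <- function(x, ...) {
  cat(sprintf("<field_sequence> %d frames, dt = %.3g min, grid %d x %d\n",
              length(x$frames), x$dt, x$grid$n1, x$grid$n2))
  invisible(x)
}

#' @export
print.velocity_sequence <- function(x, ...) {
  cat(sprintf("<velocity_sequence> %d frames, dt = %.3g min, grid %d x %d\n",
              length(x$frames), x$dt, x$grid$n1, x$grid$n2))
  invisible(x)
}
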