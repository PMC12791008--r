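## Frame-to-frame similarity measures and similarity matrices.
##
## All measures return a scalar in [-1, 1]; a similarity matrix collects the
## measure over all frame pairs of two timelines and is the substrate of the
## monotone shortest-path alignment.

#' Pearson correlation of two scalar images
#'
#' Classical Pearson coefficient over unmasked nodes,
#' `r = sum((A - mean(A)) (B - mean(B))) / sqrt(sum((A - mean(A))^2) sum((B - mean(B))^2))`,
#' robust to differing mean intensity levels between images.
#'
#' @param a,b [field_frame()] objects on the same grid.
#' @return scalar in `[-1, 1]`.
#' @export
pearson_image <- function(a, b) {
  if (!grid_same(a$grid, b$grid))
    stop_morph("grid_mismatch", "frames must share a grid")
  ok <- is.finite(a$values) & is.finite(b$values)
  x <- a$values[ok]; y <- b$values[ok]
  if (length(x) < 2L)
    stop_morph("undefined_correlation", "fewer than 2 paired nodes")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_morph("undefined_correlation", "constant image has no correlation")
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

#' Vorticity correlation between velocity fields
#'
#' Pearson correlation of the two vorticity patterns. Because vorticity is
#' linear in the field and Pearson is amplitude-invariant, the measure depends
#' only on the normalized spatial structure of the flow: `rho(c u, w) = rho(u, w)`
#' for `c > 0`, and reversing the rotation sense flips the sign.
#'
#' @param u,w [velocity_frame()] objects on the same grid.
#' @return scalar in `[-1, 1]`.
#' @export
corr_vorticity <- function(u, w) {
  pearson_image(vorticity(u), vorticity(w))
}

#' Vector-angle correlation between velocity fields
#'
#' Unweighted mean of `cos(theta)` between paired vectors over nodes where both
#' speeds exceed `floor`; slow nodes carry no reliable direction and are
#' excluded.
#'
#' @param u,w [velocity_frame()] objects on the same grid.
#' @param floor speed floor in micrometres per minute (default 0.1).
#' @return scalar in `[-1, 1]`.
#' @export
corr_angle <- function(u, w, floor = 0.1) {
  if (!grid_same(u$grid, w$grid))
    stop_morph("grid_mismatch", "frames must share a grid")
  ok <- u$valid & w$valid
  su <- sqrt(u$v1^2 + u$v2^2)
  sw <- sqrt(w$v1^2 + w$v2^2)
  ok <- ok & !is.na(su) & !is.na(sw) & su > floor & sw > floor
  if (!any(ok))
    stop_morph("undefined_correlation", "no node exceeds the speed floor")
  cosv <- (u$v1 * w$v1 + u$v2 * w$v2)[ok] / (su * sw)[ok]
  mean(cosv)
}

#' Similarity of two landmark curves
#'
#' Pearson correlation of the two Gaussian band rasterizations on a common
#' grid; this is the stripe-morphology comparison that underlies timeline
#' alignment of stripe-marker recordings.
#'
#' @param c1,c2 [stripe_curve()] objects in the same chart.
#' @param spec a [grid_spec()] for rasterization.
#' @param bandwidth band s.d. in micrometres.
#' @return scalar in `[-1, 1]`.
#' @export
curve_similarity <- function(c1, c2, spec, bandwidth) {
  pearson_image(rasterize_curve(c1, spec, bandwidth),
                rasterize_curve(c2, spec, bandwidth))
}

#' Build a similarity matrix between two timelines
#'
#' Entry `(i, j)` holds `measure(frame_a_i, frame_b_j)`. Pairs for which the
#' measure is undefined (e.g. a constant frame) are stored as `NA`, never as a
#' silent zero.
#'
#' @param seq_a,seq_b sequences of matching type ([field_sequence()],
#'   [velocity_sequence()], or lists of [stripe_curve()] with a `times`
#'   attribute).
#' @param measure `"pearson"`, `"vorticity"`, `"angle"`, `"curve"` or a
#'   function of two frames.
#' @param ... measure parameters (`floor`, `spec`, `bandwidth`).
#' @return object of class `similarity_matrix` with fields `values`,
#'   `times_a`, `times_b`, `measure_id`.
#' @export
similarity_matrix <- function(seq_a, seq_b, measure = "pearson", ...) {
  fa <- seq_frames(seq_a); fb <- seq_frames(seq_b)
  if (length(fa) == 0L || length(fb) == 0L)
    stop_morph("invalid_sequence", "sequences must be nonempty")
  fn <- measure_fn(measure, ...)
  vals <- matrix(NA_real_, length(fa), length(fb))
  for (i in seq_along(fa)) for (j in seq_along(fb)) {
    vals[i, j] <- tryCatch(fn(fa[[i]], fb[[j]]),
                           undefined_correlation = function(e) NA_real_)
  }
  new_similarity_matrix(vals, seq_times(seq_a), seq_times(seq_b),
                        if (is.character(measure)) measure else "custom")
}

new_similarity_matrix <- function(values, times_a, times_b, measure_id) {
  structure(list(values = values, times_a = times_a, times_b = times_b,
                 measure_id = measure_id),
            class = "similarity_matrix")
}

seq_frames <- function(s) {
  if (inherits(s, c("field_sequence", "velocity_sequence"))) s$frames
  else if (is.list(s)) s
  else stop_morph("invalid_sequence", "unsupported sequence type")
}

seq_times <- function(s) {
  if (!is.null(s$times)) s$times
  else attr(s, "times") %||% (seq_along(seq_frames(s)) - 1)
}

measure_fn <- function(measure, ...) {
  if (is.function(measure)) return(function(a, b) measure(a, b, ...))
  dots <- list(...)
  switch(measure,
    pearson = function(a, b) pearson_image(a, b),
    vorticity = function(a, b) corr_vorticity(a, b),
    angle = function(a, b) corr_angle(a, b, floor = dots$floor %||% 0.1),
    curve = function(a, b) curve_similarity(a, b, spec = dots$spec,
                                            bandwidth = dots$bandwidth),
    stop_morph("invalid_measure", sprintf("unknown measure '%s'", measure)))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d, measure '%s', %d missing\n",
              nrow(x$values), ncol(x$values), x$measure_id,
              sum(is.na(x$values))))
  invisible(x)
}
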