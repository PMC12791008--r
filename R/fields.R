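## Flow-field scalar observables: vorticity and r.m.s. speed.

## Central difference of matrix `m` along rows (x1), one-sided at the ends.
diff_x1 <- function(m, h) {
  n <- nrow(m)
  out <- m
  out[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (2 * h)
  out[1, ] <- (m[2, ] - m[1, ]) / h
  out[n, ] <- (m[n, ] - m[n - 1, ]) / h
  out
}

## Central difference along columns (x2), wrapping when periodic.
diff_x2 <- function(m, h, periodic) {
  n <- ncol(m)
  out <- m
  if (periodic) {
    ip <- wrap_index(seq_len(n) + 1L, n)
    im <- wrap_index(seq_len(n) - 1L, n)
    out <- (m[, ip, drop = FALSE] - m[, im, drop = FALSE]) / (2 * h)
  } else {
    out[, 2:(n - 1)] <- (m[, 3:n] - m[, 1:(n - 2)]) / (2 * h)
    out[, 1] <- (m[, 2] - m[, 1]) / h
    out[, n] <- (m[, n] - m[, n - 1]) / h
  }
  out
}

#' Vorticity of a tangent velocity field
#'
#' Computes the scalar curl `omega = d(v2)/d(x1) - d(v1)/d(x2)` by central
#' differences (one-sided at the `x1` edges, index-wrapped in periodic `x2`).
#' The spatial pattern of vorticity is a magnitude-invariant fingerprint of
#' the flow; its posterior sign flip marks the ventral-furrow-to-extension
#' transition used for rigid time alignment.
#'
#' @param frame a [velocity_frame()].
#' @return a [field_frame()] of vorticity in 1/min; nodes whose finite
#'   difference touches a masked node are `NA`.
#' @export
vorticity <- function(frame) {
  g <- frame$grid
  v1 <- frame$v1; v2 <- frame$v2
  v1[!frame$valid] <- NA_real_
  v2[!frame$valid] <- NA_real_
  om <- diff_x1(v2, g$spacing1) - diff_x2(v1, g$spacing2, g$periodic2)
  field_frame(om, g, frame$time)
}

#' Root-mean-square surface speed per frame
#'
#' For each frame, `sqrt(mean(v1^2 + v2^2))` over unmasked nodes. The r.m.s.
#' speed trace is the kinematic summary used for acceleration-based onset
#' detection and for temperature rescaling.
#'
#' @param seq a [velocity_sequence()] (grid conventions applied).
#' @return a [speed_curve()].
#' @export
rms_speed <- function(seq) {
  speeds <- vapply(seq$frames, function(f) {
    sq <- (f$v1^2 + f$v2^2)[f$valid]
    sq <- sq[!is.na(sq)]
    if (length(sq) == 0L)
      stop_morph("all_masked", "no unmasked nodes in frame")
    sqrt(mean(sq))
  }, numeric(1))
  speed_curve(seq$times, speeds)
}
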