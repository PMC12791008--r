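## Pathline integration through a time-dependent gridded velocity field,
## and displacement fields derived from it.

## Bilinear interpolation of component matrices at physical positions,
## wrapping in periodic x2 and clamping in x1. pos: n x 2 matrix (um).
interp_velocity <- function(frame, pos) {
  g <- frame$grid
  f1 <- pos[, 1] / g$spacing1
  f2 <- pos[, 2] / g$spacing2
  i0 <- floor(f1); a1 <- f1 - i0
  j0 <- floor(f2); a2 <- f2 - j0
  i0 <- pmin(pmax(i0, 0), g$n1 - 2)
  a1 <- pmin(pmax(f1 - i0, 0), 1)
  if (g$periodic2) {
    j0w <- wrap_index(as.integer(j0) + 1L, g$n2)
    j1w <- wrap_index(as.integer(j0) + 2L, g$n2)
  } else {
    j0 <- pmin(pmax(j0, 0), g$n2 - 2)
    a2 <- pmin(pmax(f2 - j0, 0), 1)
    j0w <- as.integer(j0) + 1L
    j1w <- j0w + 1L
  }
  i0w <- as.integer(i0) + 1L
  i1w <- i0w + 1L
  bil <- function(m) {
    m[cbind(i0w, j0w)] * (1 - a1) * (1 - a2) +
      m[cbind(i1w, j0w)] * a1 * (1 - a2) +
      m[cbind(i0w, j1w)] * (1 - a1) * a2 +
      m[cbind(i1w, j1w)] * a1 * a2
  }
  v1 <- frame$v1; v2 <- frame$v2
  v1[!frame$valid] <- NA_real_; v2[!frame$valid] <- NA_real_
  cbind(bil(v1), bil(v2))
}

## Velocity at arbitrary (t, pos): linear interpolation between frames.
velocity_at <- function(seq, t, pos) {
  times <- seq$times
  if (t <= times[1]) return(interp_velocity(seq$frames[[1]], pos))
  n <- length(times)
  if (t >= times[n]) return(interp_velocity(seq$frames[[n]], pos))
  k <- findInterval(t, times)
  w <- (t - times[k]) / (times[k + 1] - times[k])
  (1 - w) * interp_velocity(seq$frames[[k]], pos) +
    w * interp_velocity(seq$frames[[k + 1]], pos)
}

#' Integrate pathlines through a velocity sequence
#'
#' Fourth-order Runge-Kutta integration of material trajectories with
#' bilinear spatial and linear temporal interpolation of the gridded field.
#' Positions wrap in periodic `x2`; a seed whose trajectory leaves the `x1`
#' domain (the truncated pole region, where the field is unreliable) is frozen
#' at its last position and flagged.
#'
#' @param seq a [velocity_sequence()].
#' @param t_start,t_end integration span (min) within the sequence span.
#' @param dt_int integration step (min, default 0.2; several substeps per
#'   frame interval smooth the trajectories).
#' @param seeds optional `n x 2` matrix of start positions (um); default all
#'   unmasked grid nodes at the first integrated frame.
#' @return object of class `pathline_set`: `seeds`, `positions` (array
#'   `n_seed x n_step+1 x 2`), `t_start`, `t_end`, `dt_int`, `escaped`.
#' @export
integrate_pathlines <- function(seq, t_start, t_end, dt_int = 0.2,
                                seeds = NULL) {
  if (t_end <= t_start)
    stop_morph("invalid_span", "t_end must exceed t_start")
  g <- seq$grid
  if (is.null(seeds)) {
    k <- max(1L, findInterval(t_start, seq$times))
    ok <- which(seq$frames[[k]]$valid, arr.ind = TRUE)
    seeds <- cbind((ok[, 1] - 1) * g$spacing1, (ok[, 2] - 1) * g$spacing2)
  }
  seeds <- as.matrix(seeds)
  nseed <- nrow(seeds)
  nstep <- as.integer(round((t_end - t_start) / dt_int))
  if (nstep < 1L) stop_morph("invalid_span", "span shorter than dt_int")
  x1max <- (g$n1 - 1) * g$spacing1
  period2 <- g$n2 * g$spacing2
  pos <- seeds
  escaped <- rep(FALSE, nseed)
  positions <- array(NA_real_, c(nseed, nstep + 1L, 2L))
  positions[, 1L, ] <- pos
  wrap2 <- function(p) {
    if (g$periodic2) p[, 2] <- p[, 2] %% period2
    p
  }
  for (s in seq_len(nstep)) {
    t <- t_start + (s - 1L) * dt_int
    act <- !escaped
    if (any(act)) {
      p <- pos[act, , drop = FALSE]
      k1 <- velocity_at(seq, t, wrap2(p))
      k2 <- velocity_at(seq, t + dt_int / 2, wrap2(p + dt_int / 2 * k1))
      k3 <- velocity_at(seq, t + dt_int / 2, wrap2(p + dt_int / 2 * k2))
      k4 <- velocity_at(seq, t + dt_int, wrap2(p + dt_int * k3))
      step <- dt_int / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      newp <- p + step
      bad <- is.na(step[, 1]) | is.na(step[, 2]) |
        newp[, 1] < 0 | newp[, 1] > x1max
      newp[bad, ] <- p[bad, , drop = FALSE]
      ## stored positions stay unwrapped so displacements are well defined;
      ## wrapping happens only when sampling the field
      pos[act, ] <- newp
      esc <- rep(FALSE, nseed); esc[act] <- bad
      escaped <- escaped | esc
    }
    positions[, s + 1L, ] <- pos
  }
  structure(list(seeds = seeds, positions = positions, t_start = t_start,
                 t_end = t_end, dt_int = dt_int, escaped = escaped),
            class = "pathline_set")
}

#' Net displacement per pathline
#'
#' Euclidean norm of the straight-line displacement between each seed's start
#' and end position, `Delta(t1) = sqrt((x1-x0)^2 + (y1-y0)^2)`; this is the
#' total-deformation observable compared across temperature conditions.
#' Escaped seeds are masked (`NA`).
#'
#' @param p a `pathline_set`.
#' @return object of class `displacement_field`: `delta` (um, `NA` for
#'   escaped seeds), `seeds`.
#' @export
displacement_field <- function(p) {
  n <- dim(p$positions)[2]
  d1 <- p$positions[, n, 1] - p$positions[, 1, 1]
  d2 <- p$positions[, n, 2] - p$positions[, 1, 2]
  delta <- sqrt(d1^2 + d2^2)
  delta[p$escaped] <- NA_real_
  structure(list(delta = delta, seeds = p$seeds),
            class = "displacement_field")
}
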