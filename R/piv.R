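## Minimal particle image velocimetry: normalized cross-correlation block
## matching with subpixel parabolic peak refinement. This is plumbing so the
## pipeline runs end-to-end from images; production analyses would substitute
## a dedicated PIV tool.

ncc <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  den <- sqrt(sum(xc^2) * sum(yc^2))
  if (den == 0) return(NA_real_)
  sum(xc * yc) / den
}

#' Estimate a velocity field from two consecutive images
#'
#' Divides the first image into square windows (edge `window` grid units,
#' conventionally 2-3 percent of the chart range), finds for each the integer
#' shift within `+/- search` maximizing normalized cross-correlation against
#' the second image, refines the peak by a 3-point parabolic fit per axis, and
#' divides by the frame interval. Windows wrap around periodic `x2`; windows
#' with zero variance are masked.
#'
#' @param a,b [field_frame()] objects on the same grid; `b` later than `a`.
#' @param window window edge length in grid units (>= 8).
#' @param search maximum shift searched, grid units.
#' @return a [velocity_frame()] on the coarser window-centre grid
#'   (spacing = `window` times the image spacing).
#' @export
piv_estimate <- function(a, b, window = 8L, search = 4L) {
  if (!grid_same(a$grid, b$grid))
    stop_morph("grid_mismatch", "frames must share a grid")
  if (window < 8L)
    stop_morph("invalid_window", "PIV window must be at least 8 grid units")
  g <- a$grid
  dt <- b$time - a$time
  if (dt <= 0) stop_morph("invalid_sequence", "frame b must be later than a")
  nw1 <- g$n1 %/% window
  nw2 <- g$n2 %/% window
  if (nw1 < 1L || nw2 < 1L)
    stop_morph("invalid_window", "window larger than image")
  v1 <- matrix(NA_real_, nw1, nw2)
  v2 <- matrix(NA_real_, nw1, nw2)
  A <- a$values; B <- b$values
  for (wi in seq_len(nw1)) for (wj in seq_len(nw2)) {
    i0 <- (wi - 1L) * window
    j0 <- (wj - 1L) * window
    rows <- i0 + seq_len(window)
    cols <- j0 + seq_len(window)
    tmpl <- A[rows, cols]
    if (anyNA(tmpl) || stats::sd(tmpl) == 0) next
    shifts1 <- -search:search
    shifts2 <- -search:search
    cmat <- matrix(NA_real_, length(shifts1), length(shifts2))
    for (si in seq_along(shifts1)) {
      r2 <- rows + shifts1[si]
      if (min(r2) < 1L || max(r2) > g$n1) next
      for (sj in seq_along(shifts2)) {
        c2 <- cols + shifts2[sj]
        c2 <- if (g$periodic2) wrap_index(c2, g$n2) else c2
        if (min(c2) < 1L || max(c2) > g$n2) next
        patch <- B[r2, c2]
        if (anyNA(patch)) next
        cmat[si, sj] <- ncc(tmpl, patch)
      }
    }
    if (all(is.na(cmat))) next
    pk <- which(cmat == max(cmat, na.rm = TRUE), arr.ind = TRUE)[1, ]
    ## a perfect integer match needs no subpixel refinement (the 3-point fit
    ## would only import asymmetry of the correlation falloff)
    exact <- cmat[pk[1], pk[2]] > 1 - 1e-12
    d1 <- shifts1[pk[1]] + if (exact) 0 else subpixel_offset(cmat, pk, 1L)
    d2 <- shifts2[pk[2]] + if (exact) 0 else subpixel_offset(cmat, pk, 2L)
    v1[wi, wj] <- d1 * g$spacing1 / dt
    v2[wi, wj] <- d2 * g$spacing2 / dt
  }
  gout <- grid_spec(max(nw1, 4L), max(nw2, 4L),
                    g$spacing1 * window, g$spacing2 * window,
                    periodic2 = g$periodic2, truncation_fraction = 0)
  ## pad with masked rows/cols if the window grid is tiny
  pad <- function(mm) {
    out <- matrix(NA_real_, gout$n1, gout$n2)
    out[seq_len(nw1), seq_len(nw2)] <- mm
    out
  }
  velocity_frame(pad(v1), pad(v2), gout, time = a$time)
}

## 3-point parabolic interpolation of a correlation peak along one axis.
subpixel_offset <- function(cmat, pk, axis) {
  i <- pk[1]; j <- pk[2]
  get <- function(di, dj) {
    ii <- i + di; jj <- j + dj
    if (ii < 1L || ii > nrow(cmat) || jj < 1L || jj > ncol(cmat))
      return(NA_real_)
    cmat[ii, jj]
  }
  if (axis == 1L) { cm <- get(-1L, 0L); cp <- get(1L, 0L) }
  else { cm <- get(0L, -1L); cp <- get(0L, 1L) }
  c0 <- cmat[i, j]
  if (is.na(cm) || is.na(cp)) return(0)
  den <- cm - 2 * c0 + cp
  if (den >= 0) return(0)   # not a peak
  off <- 0.5 * (cm - cp) / den
  if (abs(off) > 1) 0 else off
}
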