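## Stripe-boundary extraction and curve rasterization.
##
## Pair-rule stripes act as a morphological clock: the boundary of a chosen
## stripe is extracted as a polyline, and polylines are compared by Pearson
## correlation of their Gaussian band rasterizations.

## Separable Gaussian smoothing; reflect at x1 edges, wrap in periodic x2.
gauss_smooth <- function(m, sd_units, periodic2) {
  if (sd_units <= 0) return(m)
  r <- max(1L, ceiling(3 * sd_units))
  k <- stats::dnorm(seq(-r, r), sd = sd_units)
  k <- k / sum(k)
  conv1 <- function(v) { # reflect padding
    n <- length(v)
    idx <- c(rev(seq_len(min(r, n))), seq_len(n), n + 1 - rev(seq_len(min(r, n))))
    pad <- v[pmin(pmax(idx, 1L), n)]
    stats::filter(pad, k, sides = 2)[(r + 1):(r + n)]
  }
  convw <- function(v) { # wrap padding
    n <- length(v)
    pad <- v[wrap_index(seq.int(1L - r, n + r), n)]
    stats::filter(pad, k, sides = 2)[(r + 1):(r + n)]
  }
  m <- apply(m, 2, conv1)              # along x1 (rows)
  t(apply(m, 1, if (periodic2) convw else conv1)) # along x2 (columns)
}

## Otsu threshold on a 256-bin histogram.
otsu_threshold <- function(v) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- hist(v, breaks = seq(rng[1], rng[2], length.out = 257L), plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

## 4-connected component labelling with optional x2 wrap; returns label matrix.
label_components <- function(mask, periodic2) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  lab <- matrix(0L, n1, n2)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      i <- ((p - 1L) %% n1) + 1L
      j <- ((p - 1L) %/% n1) + 1L
      nb_i <- c(i - 1L, i + 1L, i, i)
      nb_j <- c(j, j, j - 1L, j + 1L)
      if (periodic2) nb_j <- wrap_index(nb_j, n2)
      ok <- nb_i >= 1L & nb_i <= n1 & nb_j >= 1L & nb_j <= n2
      for (q in which(ok)) {
        pq <- (nb_j[q] - 1L) * n1 + nb_i[q]
        if (mask[pq] && lab[pq] == 0L) {
          lab[pq] <- cur
          queue <- c(queue, pq)
        }
      }
    }
  }
  lab
}

#' Extract a stripe boundary from a scalar image
#'
#' Recovers the anterior (low `x1`) or posterior (high `x1`) edge of the
#' dominant bright stripe in a chart image: Gaussian smoothing (s.d. one grid
#' unit by default), Otsu threshold, largest connected component, then a
#' per-`x2`-row subpixel edge by linear interpolation of the smoothed profile
#' across the threshold.
#'
#' @param frame a [field_frame()] containing one dominant bright stripe.
#' @param side `"anterior"` (default) or `"posterior"`.
#' @param smooth_sd smoothing s.d. in grid units (default 1).
#' @return a [stripe_curve()] ordered in `x2`, coordinates in micrometres.
#' @export
extract_stripe_boundary <- function(frame, side = c("anterior", "posterior"),
                                    smooth_sd = 1) {
  side <- match.arg(side)
  g <- frame$grid
  img <- frame$values
  img[is.na(img)] <- min(img, na.rm = TRUE)
  sm <- gauss_smooth(img, smooth_sd, g$periodic2)
  thr <- otsu_threshold(sm)
  mask <- sm > thr
  if (!any(mask) || all(mask))
    stop_morph("no_stripe", "no above-threshold stripe component found")
  lab <- label_components(mask, g$periodic2)
  sizes <- tabulate(lab[lab > 0L])
  if (length(sizes) == 0L)
    stop_morph("no_stripe", "no above-threshold stripe component found")
  comp <- lab == which.max(sizes)
  x1 <- grid_x1(g)
  pts <- matrix(NA_real_, g$n2, 2L)
  for (j in seq_len(g$n2)) {
    rows <- which(comp[, j])
    if (length(rows) == 0L) next
    i <- if (side == "anterior") min(rows) else max(rows)
    step <- if (side == "anterior") -1L else 1L
    i2 <- i + step
    e <- x1[i]
    if (i2 >= 1L && i2 <= g$n1 && is.finite(sm[i2, j]) && sm[i2, j] != sm[i, j]) {
      frac <- (sm[i, j] - thr) / (sm[i, j] - sm[i2, j])
      frac <- min(max(frac, 0), 1)
      e <- x1[i] + step * frac * g$spacing1
    }
    pts[j, ] <- c(e, (j - 1) * g$spacing2)
  }
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 3L)
    stop_morph("no_stripe", "stripe component spans fewer than 3 x2 rows")
  stripe_curve(pts, closed2 = g$periodic2 && nrow(pts) == g$n2)
}

## Minimum distance from grid nodes to a polyline, honouring x2 periodicity.
curve_distance_field <- function(curve, spec) {
  x1 <- grid_x1(spec); x2 <- grid_x2(spec)
  P1 <- matrix(x1, spec$n1, spec$n2)
  P2 <- matrix(x2, spec$n1, spec$n2, byrow = TRUE)
  pts <- curve$points
  segs <- cbind(pts[-nrow(pts), , drop = FALSE], pts[-1, , drop = FALSE])
  if (curve$closed2 && nrow(pts) >= 3L)
    segs <- rbind(segs, c(pts[nrow(pts), ], pts[1, ]))
  period <- spec$n2 * spec$spacing2
  shifts <- if (spec$periodic2) c(-period, 0, period) else 0
  d2 <- matrix(Inf, spec$n1, spec$n2)
  for (s in seq_len(nrow(segs))) {
    a1 <- segs[s, 1]; a2 <- segs[s, 2]; b1 <- segs[s, 3]; b2 <- segs[s, 4]
    for (sh in shifts) {
      u1 <- b1 - a1; u2 <- b2 - a2
      w2s <- a2 + sh
      len2 <- u1 * u1 + u2 * u2
      t <- ((P1 - a1) * u1 + (P2 - w2s) * u2) / max(len2, .Machine$double.eps)
      t <- pmin(pmax(t, 0), 1)
      q1 <- a1 + t * u1; q2 <- w2s + t * u2
      d2 <- pmin(d2, (P1 - q1)^2 + (P2 - q2)^2)
    }
  }
  sqrt(d2)
}

#' Rasterize a curve into a Gaussian band image
#'
#' Produces an image whose value at each node is
#' `exp(-d^2 / (2 * bandwidth^2))` with `d` the distance to the curve, so the
#' band peaks at 1 on the curve and decays with s.d. `bandwidth`. Band images
#' make polylines comparable by the same Pearson measure used for images.
#'
#' @param curve a [stripe_curve()].
#' @param spec target [grid_spec()].
#' @param bandwidth Gaussian s.d. in micrometres (> 0).
#' @param time time attached to the output frame (min).
#' @return a [field_frame()].
#' @export
rasterize_curve <- function(curve, spec, bandwidth, time = 0) {
  if (!is_scalar_number(bandwidth) || bandwidth <= 0)
    stop_morph("invalid_bandwidth", "bandwidth must be a positive number")
  d <- curve_distance_field(curve, spec)
  field_frame(exp(-d^2 / (2 * bandwidth^2)), spec, time)
}
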