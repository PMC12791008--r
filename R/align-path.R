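## Monotone time warping: endpoint selection and weighted shortest path
## through a similarity matrix ("fast marching" on the frame lattice).

#' Select correspondence-curve endpoints on a similarity matrix
#'
#' The correspondence curve starts on the top or left edge of the matrix and
#' ends on the bottom or right edge; each endpoint is placed at the cell of
#' maximal similarity on its edge. Ties are broken toward the top-left corner
#' for the start (smallest row+col, then smallest row) and toward the
#' bottom-right for the end.
#'
#' @param m a [similarity_matrix()].
#' @return list with integer `start = c(row, col)` and `end = c(row, col)`
#'   (1-based).
#' @export
select_endpoints <- function(m) {
  v <- m$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 2L || nc < 2L)
    stop_morph("invalid_matrix", "similarity matrix must be at least 2x2")
  edge_cells <- function(rows, cols) {
    cells <- unique(rbind(
      cbind(rows, rep(seq_len(nc), each = length(rows))),
      cbind(rep(seq_len(nr), each = length(cols)), cols)))
    cells
  }
  pick <- function(cells, toward_end) {
    vals <- v[cells]
    if (all(is.na(vals)))
      stop_morph("degenerate_overlap", "all edge similarities missing")
    best <- max(vals, na.rm = TRUE)
    cand <- cells[!is.na(vals) & vals >= best - 1e-12, , drop = FALSE]
    key <- cand[, 1] + cand[, 2]
    if (toward_end) {
      cand <- cand[key == max(key), , drop = FALSE]
      cand[which.max(cand[, 1]), ]
    } else {
      cand <- cand[key == min(key), , drop = FALSE]
      cand[which.min(cand[, 1]), ]
    }
  }
  start <- pick(edge_cells(1L, 1L), FALSE)
  end <- pick(edge_cells(nr, nc), TRUE)
  if (start[1] > end[1] || start[2] > end[2] ||
      (start[1] == end[1] && start[2] == end[2]))
    stop_morph("degenerate_overlap",
               "start point is not strictly up-left of end point")
  list(start = unname(start), end = unname(end))
}

## Similarity -> positive path weight. eps keeps weights finite when the
## minimum similarity is traversed; constant matrices get unit weights.
similarity_weights <- function(v) {
  if (all(is.na(v))) stop_morph("no_path", "similarity matrix is all missing")
  rng <- range(v, na.rm = TRUE)
  if (diff(rng) == 0) {
    w <- matrix(1, nrow(v), ncol(v))
    w[is.na(v)] <- 1
    return(w)
  }
  ## missing entries are interpolated only here, inside the search
  vf <- fill_missing(v)
  eps <- 0.05 * diff(rng)
  1 / (vf - rng[1] + eps)
}

## Iterative neighbour-mean fill of NA entries (search-internal only).
fill_missing <- function(v) {
  if (!anyNA(v)) return(v)
  nr <- nrow(v); nc <- ncol(v)
  for (iter in seq_len(nr + nc)) {
    na <- which(is.na(v), arr.ind = TRUE)
    if (nrow(na) == 0L) break
    filled <- v
    for (k in seq_len(nrow(na))) {
      i <- na[k, 1]; j <- na[k, 2]
      nb <- c(if (i > 1) v[i - 1, j], if (i < nr) v[i + 1, j],
              if (j > 1) v[i, j - 1], if (j < nc) v[i, j + 1])
      nb <- nb[!is.na(nb)]
      if (length(nb)) filled[i, j] <- mean(nb)
    }
    v <- filled
  }
  v[is.na(v)] <- mean(v, na.rm = TRUE)
  v
}

#' Monotone weighted shortest path through a similarity matrix
#'
#' Finds the minimum-cost lattice path from `start` to `end` moving only down,
#' right or diagonally down-right, where the cost of a step is its Euclidean
#' length times the mean of the two endpoint weights and the weight of a cell
#' is `1 / (rho - rho_min + eps)` with `eps = 0.05 * (rho_max - rho_min)`.
#' The path hugs the ridge of maximal similarity while remaining order
#' preserving, and reduces to a discrete straight line on a constant matrix.
#' Diagonal moves win cost ties (bias toward unit rate ratio).
#'
#' @param m a [similarity_matrix()].
#' @param start,end 1-based `c(row, col)` endpoints; default from
#'   [select_endpoints()].
#' @return object of class `correspondence_curve`: `t_a` (strictly increasing),
#'   `t_b` (nondecreasing), the lattice `path`, total `cost` and
#'   `mean_similarity` along the path.
#' @export
monotone_shortest_path <- function(m, start = NULL, end = NULL) {
  if (is.null(start) || is.null(end)) {
    ep <- select_endpoints(m)
    start <- start %||% ep$start
    end <- end %||% ep$end
  }
  v <- m$values
  w <- similarity_weights(v)
  r0 <- start[1]; c0 <- start[2]; r1 <- end[1]; c1 <- end[2]
  if (r1 < r0 || c1 < c0)
    stop_morph("degenerate_overlap", "end must be down-right of start")
  nr <- r1 - r0 + 1L; nc <- c1 - c0 + 1L
  ws <- w[r0:r1, c0:c1, drop = FALSE]
  if (any(!is.finite(ws)))
    stop_morph("no_path", "non-finite path weights")
  dist <- matrix(Inf, nr, nc)
  dist[1, 1] <- 0
  s2 <- sqrt(2)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (i == 1L && j == 1L) next
    best <- Inf
    if (i > 1L && j > 1L)
      best <- min(best, dist[i - 1, j - 1] +
                    s2 * (ws[i - 1, j - 1] + ws[i, j]) / 2)
    if (i > 1L)
      best <- min(best, dist[i - 1, j] + (ws[i - 1, j] + ws[i, j]) / 2)
    if (j > 1L)
      best <- min(best, dist[i, j - 1] + (ws[i, j - 1] + ws[i, j]) / 2)
    dist[i, j] <- best
  }
  ## backtrack; among cost-tied predecessors prefer the one closest to the
  ## straight start-end chord (a constant matrix then yields the discrete
  ## straight line), with the diagonal breaking any residual tie
  chord_dev <- function(i, j) {
    a1 <- nr - 1; a2 <- nc - 1
    abs(a2 * (i - 1) - a1 * (j - 1)) / max(sqrt(a1^2 + a2^2), 1)
  }
  path <- matrix(0L, nr + nc, 2L)
  i <- nr; j <- nc; k <- 0L
  while (TRUE) {
    k <- k + 1L
    path[k, ] <- c(i + r0 - 1L, j + c0 - 1L)
    if (i == 1L && j == 1L) break
    cand <- list()
    if (i > 1L && j > 1L)
      cand[[length(cand) + 1L]] <- c(i - 1L, j - 1L,
        dist[i - 1, j - 1] + s2 * (ws[i - 1, j - 1] + ws[i, j]) / 2)
    if (i > 1L)
      cand[[length(cand) + 1L]] <- c(i - 1L, j,
        dist[i - 1, j] + (ws[i - 1, j] + ws[i, j]) / 2)
    if (j > 1L)
      cand[[length(cand) + 1L]] <- c(i, j - 1L,
        dist[i, j - 1] + (ws[i, j - 1] + ws[i, j]) / 2)
    costs <- vapply(cand, `[`, numeric(1), 3)
    tied <- which(costs <= min(costs) + 1e-12 * (1 + abs(min(costs))))
    pick <- tied[which.min(vapply(tied, function(q)
      chord_dev(cand[[q]][1], cand[[q]][2]), numeric(1)))]
    i <- as.integer(cand[[pick]][1]); j <- as.integer(cand[[pick]][2])
  }
  path <- path[k:1, , drop = FALSE]
  sim_path <- v[path]
  ## collapse to a function t_A -> t_B: one sample per visited row
  ta_idx <- sort(unique(path[, 1]))
  tb <- vapply(ta_idx, function(r) mean(m$times_b[path[path[, 1] == r, 2]]),
               numeric(1))
  new_correspondence_curve(m$times_a[ta_idx], tb,
                           path = path, cost = dist[nr, nc],
                           mean_similarity = mean(sim_path, na.rm = TRUE))
}

new_correspondence_curve <- function(t_a, t_b, path = NULL, cost = NA_real_,
                                     mean_similarity = NA_real_) {
  if (any(diff(t_a) <= 0))
    stop_morph("invalid_curve", "t_a must be strictly increasing")
  if (any(diff(t_b) < -1e-9))
    stop_morph("invalid_curve", "t_b must be nondecreasing")
  structure(list(t_a = t_a, t_b = t_b, path = path, cost = cost,
                 mean_similarity = mean_similarity),
            class = "correspondence_curve")
}

#' Evaluate or invert a correspondence curve
#'
#' `warp_time` maps times on axis A to axis B by linear interpolation between
#' curve samples (clamped at the ends); `unwarp_time` is the inverse where the
#' curve is strictly increasing.
#'
#' @param curve a `correspondence_curve`.
#' @param t times to map (min).
#' @return mapped times (min).
#' @export
warp_time <- function(curve, t) interp_clamped(curve$t_a, curve$t_b, t)

#' @rdname warp_time
#' @export
unwarp_time <- function(curve, t) {
  keep <- c(TRUE, diff(curve$t_b) > 0)
  interp_clamped(curve$t_b[keep], curve$t_a[keep], t)
}

#' @export
print.correspondence_curve <- function(x, ...) {
  cat(sprintf(
    "<correspondence_curve> %d samples, t_a in [%.3g, %.3g] min, mean similarity %.3f\n",
    length(x$t_a), min(x$t_a), max(x$t_a), x$mean_similarity))
  invisible(x)
}
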