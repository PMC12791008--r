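## Flow autocorrelation, stationary-module segmentation, and time/ensemble
## averaging of velocity fields.

#' Autocorrelation matrix of a velocity sequence
#'
#' Square symmetric matrix `M(t_i, t_j) = rho(v(t_i), v(t_j))` under the
#' chosen similarity measure. Blocks of high correlation along the diagonal
#' are the stationary flow modules: periods during which the normalized
#' spatial flow pattern barely changes while tissue keeps moving.
#'
#' @param seq a [velocity_sequence()] with at least 2 frames.
#' @param measure `"vorticity"` (default), `"angle"`, or a function.
#' @param ... measure parameters.
#' @return a symmetric [similarity_matrix()] with unit diagonal.
#' @export
autocorr_matrix <- function(seq, measure = "vorticity", ...) {
  fr <- seq$frames
  n <- length(fr)
  if (n < 2L) stop_morph("invalid_sequence", "need at least 2 frames")
  fn <- measure_fn(measure, ...)
  v <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    val <- tryCatch(fn(fr[[i]], fr[[j]]),
                    undefined_correlation = function(e) NA_real_)
    v[i, j] <- val
    v[j, i] <- val
  }
  new_similarity_matrix(v, seq$times, seq$times,
                        if (is.character(measure)) measure else "custom")
}

#' Segment a timeline into stationary flow modules
#'
#' Dynamic-programming partition of the diagonal of a square autocorrelation
#' matrix into disjoint blocks maximizing
#' `sum((block mean correlation - threshold) * block_area)` over blocks of at
#' least `min_len` frames. Frames between blocks stay unassigned (e.g. the
#' decorrelated transition between extension and retraction). The default
#' threshold 0.6 sits at the `exp(-1/2) ~ 0.61` decorrelation level used for
#' pattern decorrelation, keeping the two notions consistent.
#'
#' @param m a square symmetric [similarity_matrix()].
#' @param threshold minimum within-module mean correlation (default 0.6).
#' @param min_len minimum module length in frames (default 3).
#' @return object of class `module_segmentation`: data frame `modules` with
#'   `t_start`, `t_end`, `mean_corr`, `label`, frame index columns, and the
#'   `threshold` used.
#' @export
segment_modules <- function(m, threshold = 0.6, min_len = 3L) {
  v <- m$values
  n <- nrow(v)
  if (n != ncol(v)) stop_morph("invalid_matrix", "matrix must be square")
  v0 <- v
  v0[is.na(v0)] <- 0
  ## 2D prefix sums for O(1) block means
  P <- rbind(0, cbind(0, t(apply(apply(v0, 2, cumsum), 1, cumsum))))
  cnt <- matrix(1, n, n); cnt[is.na(v)] <- 0
  Pc <- rbind(0, cbind(0, t(apply(apply(cnt, 2, cumsum), 1, cumsum))))
  block_stat <- function(i, j) {
    s <- P[j + 1, j + 1] - P[i, j + 1] - P[j + 1, i] + P[i, i]
    k <- Pc[j + 1, j + 1] - Pc[i, j + 1] - Pc[j + 1, i] + Pc[i, i]
    if (k == 0) return(c(NA_real_, 0))
    c(s / k, (j - i + 1)^2)
  }
  ## frames whose self-correlation is undefined (e.g. zero-flow gaps under
  ## the vorticity measure) cannot belong to any module
  ok_frame <- !is.na(diag(v))
  best <- numeric(n + 1L)        # best[j+1] = optimum over frames 1..j
  choice <- vector("list", n + 1L)
  for (j in seq_len(n)) {
    best[j + 1L] <- best[j]
    choice[[j + 1L]] <- NULL
    if (j >= min_len && ok_frame[j]) {
      for (i in seq_len(j - min_len + 1L)) {
        if (!all(ok_frame[i:j])) next
        bs <- block_stat(i, j)
        if (is.na(bs[1]) || bs[1] <= threshold) next
        sc <- best[i] + (bs[1] - threshold) * bs[2]
        if (sc > best[j + 1L] + 1e-12) {
          best[j + 1L] <- sc
          choice[[j + 1L]] <- c(i, j, bs[1])
        }
      }
    }
  }
  ## backtrack
  blocks <- list()
  j <- n
  while (j >= 1L) {
    ch <- choice[[j + 1L]]
    if (is.null(ch)) { j <- j - 1L; next }
    blocks[[length(blocks) + 1L]] <- ch
    j <- ch[1] - 1L
  }
  blocks <- rev(blocks)
  modules <- if (length(blocks)) {
    data.frame(
      frame_start = vapply(blocks, `[`, numeric(1), 1),
      frame_end = vapply(blocks, `[`, numeric(1), 2),
      t_start = m$times_a[vapply(blocks, `[`, numeric(1), 1)],
      t_end = m$times_a[vapply(blocks, `[`, numeric(1), 2)],
      mean_corr = vapply(blocks, `[`, numeric(1), 3),
      label = paste0("module_", seq_along(blocks)))
  } else {
    data.frame(frame_start = numeric(0), frame_end = numeric(0),
               t_start = numeric(0), t_end = numeric(0),
               mean_corr = numeric(0), label = character(0))
  }
  structure(list(modules = modules, threshold = threshold,
                 min_len = min_len),
            class = "module_segmentation")
}

#' Time-averaged flow over a window
#'
#' Arithmetic mean of the velocity components over frames with times in
#' `[t_start, t_end]`; a node is valid when valid in every averaged frame.
#'
#' @param seq a [velocity_sequence()].
#' @param t_start,t_end averaging window (min).
#' @return a [velocity_frame()] stamped at the window midpoint.
#' @export
time_average_flow <- function(seq, t_start, t_end) {
  sel <- which(seq$times >= t_start & seq$times <= t_end)
  if (length(sel) == 0L)
    stop_morph("invalid_span", "no frames inside the averaging window")
  g <- seq$grid
  v1 <- Reduce(`+`, lapply(seq$frames[sel], `[[`, "v1")) / length(sel)
  v2 <- Reduce(`+`, lapply(seq$frames[sel], `[[`, "v2")) / length(sel)
  valid <- Reduce(`&`, lapply(seq$frames[sel], `[[`, "valid"))
  velocity_frame(v1, v2, g, time = (t_start + t_end) / 2, valid = valid)
}

#' Ensemble-averaged flow across aligned members
#'
#' Frame-by-frame arithmetic mean across members that were rigidly aligned
#' beforehand (alignment by shift only, to distort the data as little as
#' possible). All members must share grid and frame times.
#'
#' @param seqs list of at least 2 aligned [velocity_sequence()] members.
#' @return a [velocity_sequence()].
#' @export
ensemble_average_flow <- function(seqs) {
  if (length(seqs) < 2L)
    stop_morph("invalid_ensemble", "ensemble averaging needs >= 2 members")
  nt <- length(seqs[[1]]$frames)
  for (s in seqs) {
    if (length(s$frames) != nt || !grid_same(s$grid, seqs[[1]]$grid))
      stop_morph("invalid_ensemble", "members must share grid and length")
  }
  frames <- lapply(seq_len(nt), function(k) {
    v1 <- Reduce(`+`, lapply(seqs, function(s) s$frames[[k]]$v1)) / length(seqs)
    v2 <- Reduce(`+`, lapply(seqs, function(s) s$frames[[k]]$v2)) / length(seqs)
    valid <- Reduce(`&`, lapply(seqs, function(s) s$frames[[k]]$valid))
    velocity_frame(v1, v2, seqs[[1]]$grid,
                   time = seqs[[1]]$times[k], valid = valid)
  })
  velocity_sequence(frames, dt = seqs[[1]]$dt)
}

#' Per-frame correlation of a member to the ensemble mean
#'
#' Correlation trace of one member's frames against the ensemble-averaged
#' flow at matching times, under the chosen measure; quantifies how
#' stereotyped each member's flow is.
#'
#' @param member a [velocity_sequence()].
#' @param ensemble_mean an aligned [velocity_sequence()] (same times).
#' @param measure,... similarity measure (default `"vorticity"`).
#' @return object of class `correlation_trace` with `times` and `values`.
#' @export
corr_to_ensemble <- function(member, ensemble_mean, measure = "vorticity",
                             ...) {
  nt <- length(member$frames)
  if (length(ensemble_mean$frames) != nt)
    stop_morph("invalid_ensemble", "sequences must have equal length")
  fn <- measure_fn(measure, ...)
  vals <- vapply(seq_len(nt), function(k) {
    tryCatch(fn(member$frames[[k]], ensemble_mean$frames[[k]]),
             undefined_correlation = function(e) NA_real_)
  }, numeric(1))
  structure(list(times = member$times, values = vals),
            class = "correlation_trace")
}

#' @export
print.module_segmentation <- function(x, ...) {
  cat(sprintf("<module_segmentation> %d modules (threshold %.2f)\n",
              nrow(x$modules), x$threshold))
  if (nrow(x$modules)) print(x$modules, row.names = FALSE)
  invisible(x)
}
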