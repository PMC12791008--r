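## Shared in-code fixtures. All randomness is seeded per call site.

## Small non-periodic grid for analytic flow tests.
grid_small <- function(n1 = 16, n2 = 16, sp = 1, periodic2 = FALSE)
  grid_spec(n1, n2, sp, sp, periodic2 = periodic2, truncation_fraction = 0)

## Velocity frame from component functions of physical (x1, x2).
vel_from_fn <- function(g, f1, f2, time = 0) {
  X1 <- matrix((seq_len(g$n1) - 1) * g$spacing1, g$n1, g$n2)
  X2 <- matrix((seq_len(g$n2) - 1) * g$spacing2, g$n1, g$n2, byrow = TRUE)
  velocity_frame(f1(X1, X2), f2(X1, X2), g, time = time)
}

## Constant-in-time velocity sequence from one frame.
vel_seq_const <- function(frame, n_frames, dt = 1) {
  velocity_sequence(lapply(seq_len(n_frames) - 1L, function(k) {
    velocity_frame(frame$v1, frame$v2, frame$grid, time = k * dt,
                   valid = frame$valid)
  }), dt = dt)
}

## Smooth seeded random field frame (for oracle comparisons).
random_field <- function(g, seed, smooth = 2) {
  set.seed(seed)
  m <- matrix(stats::rnorm(g$n1 * g$n2), g$n1, g$n2)
  k <- stats::dnorm(seq(-3 * smooth, 3 * smooth), sd = smooth)
  k <- k / sum(k)
  m <- apply(m, 2, function(v) stats::filter(c(rev(v), v, rev(v)), k,
                                             sides = 2)[g$n1 + seq_len(g$n1)])
  m <- t(apply(m, 1, function(v) stats::filter(c(rev(v), v, rev(v)), k,
                                               sides = 2)[g$n2 + seq_len(g$n2)]))
  field_frame(m, g)
}

random_velocity <- function(g, seed, smooth = 2) {
  a <- random_field(g, seed, smooth)
  b <- random_field(g, seed + 5000L, smooth)
  velocity_frame(a$values, b$values, g)
}

## Brute-force enumeration of all monotone lattice paths (oracle for the
## shortest-path search). Returns the minimum cost.
brute_force_path_cost <- function(values, start, end) {
  w <- morphaline:::similarity_weights(values)
  best <- Inf
  s2 <- sqrt(2)
  recurse <- function(i, j, cost) {
    if (cost >= best) return()
    if (i == end[1] && j == end[2]) { best <<- min(best, cost); return() }
    if (i < end[1] && j < end[2])
      recurse(i + 1L, j + 1L, cost + s2 * (w[i, j] + w[i + 1, j + 1]) / 2)
    if (i < end[1])
      recurse(i + 1L, j, cost + (w[i, j] + w[i + 1, j]) / 2)
    if (j < end[2])
      recurse(i, j + 1L, cost + (w[i, j] + w[i, j + 1]) / 2)
  }
  recurse(start[1], start[2], 0)
  best
}

## Similarity matrix wrapper around a plain values matrix.
simmat <- function(values, times_a = NULL, times_b = NULL) {
  morphaline:::new_similarity_matrix(
    values,
    times_a %||% (seq_len(nrow(values)) - 1),
    times_b %||% (seq_len(ncol(values)) - 1),
    "test")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
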