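test_that("icp_register recovers exact rigid transforms", {
  tube <- make_tube_mesh(c(10, 9, 8, 9, 10, 11, 10, 9, 8, 7), 80,
                         n_z = 10, n_theta = 12)
  p <- tube$vertices
  ## break the tube's discrete rotational symmetry: registration unique
  th <- atan2(p[, 2], p[, 1])
  p <- p * (1 + 0.15 * cos(th))
  tf_true <- random_rigid_transform(max_angle = 25, max_shift = 8, seed = 3)
  q <- apply_transform(tf_true, p)
  res <- icp_register(p, q)
  expect_lt(res$residual, 1e-8)
  expect_equal(res$transform$rotation, tf_true$rotation, tolerance = 1e-6)
  expect_equal(res$transform$translation, tf_true$translation,
               tolerance = 1e-6)

  ## identity
  res_id <- icp_register(p, p)
  expect_lt(res_id$residual, 1e-10)
  expect_equal(res_id$transform$rotation, diag(3), tolerance = 1e-6)

  ## degenerate input
  flat <- cbind(runif(10), runif(10), 0)
  expect_error(icp_register(flat, p), class = "degenerate_points")
})

test_that("icp composed with its recovered transform is the identity", {
  p <- make_icosphere(10, 2)$vertices
  p <- p + outer(sin(p[, 1]), c(0.3, 0.1, 0.2))  # break symmetry
  for (s in 1:3) {
    tf <- random_rigid_transform(max_angle = 28, max_shift = 5, seed = 10 + s)
    q <- apply_transform(tf, p)
    rec <- icp_register(p, q)$transform
    back <- apply_transform(rec, p)
    expect_lt(max(abs(back - q)), 1e-6)
  }
})

test_that("icp residual tracks the noise floor", {
  tube <- make_tube_mesh(10 + sin(seq(0, 3, length.out = 12)), 90,
                         n_z = 12, n_theta = 12)
  p <- tube$vertices
  sigma <- 0.05
  ratio <- numeric(10)
  for (s in 1:10) {
    tf <- random_rigid_transform(max_angle = 15, max_shift = 3,
                                 seed = 40 + s)
    set.seed(140 + s)
    q <- apply_transform(tf, p) + matrix(rnorm(length(p), sd = sigma),
                                         nrow(p), 3)
    res <- suppressWarnings(icp_register(p, q, max_iter = 60))
    ## with matched points the residual approaches sigma * sqrt(3); nearest-
    ## neighbour correspondence can only reduce it
    ratio[s] <- res$residual / (sigma * sqrt(3))
  }
  expect_lt(abs(mean(ratio) - 1), 0.2)
})

test_that("mean curvature converges to 1/R on icospheres", {
  ## levels 0-1 are exact by symmetry; convergence is visible from level 2
  errs <- vapply(2:4, function(lev) {
    m <- make_icosphere(10, lev)
    H <- morphaline:::mean_curvature(m)$H
    mean(abs(H - 1 / 10)) * 10
  }, numeric(1))
  expect_lt(errs[2], errs[1] / 2)
  expect_lt(errs[3], errs[2] / 2)
  expect_lt(errs[3], 1e-4)
})

test_that("out_of_plane_deformation matches sphere and cylinder closed forms", {
  ## expanding sphere: d = 2 (1/R) Rdot
  R <- 20; Rdot <- 0.5
  m0 <- make_icosphere(R, 3)
  m1 <- make_icosphere(R + Rdot, 3); m1$time <- 1
  def <- out_of_plane_deformation(m0, m1, dt = 1)
  expect_equal(mean(def$d), 2 * Rdot / R, tolerance = 0.05 * 2 * Rdot / R)
  expect_equal(mean(def$v_n), Rdot, tolerance = 0.01)

  ## inflating cylinder: H = 1/(2R), d = Rdot / R (interior vertices)
  mk_cyl <- function(r) make_tube_mesh(r, 100, n_z = 40, n_theta = 24)
  c0 <- mk_cyl(10); c1 <- mk_cyl(10.5); c1$time <- 1
  defc <- out_of_plane_deformation(c0, c1, dt = 1)
  zi <- which(!defc$boundary & abs(c0$vertices[, 3] - 50) < 30)
  expect_equal(mean(defc$d[zi]), 0.5 / 10, tolerance = 0.05 * 0.5 / 10)

  ## static mesh: zero
  m1s <- m0; m1s$time <- 1
  defs <- out_of_plane_deformation(m0, m1s, dt = 1)
  expect_true(all(abs(defs$d) < 1e-12))
})

test_that("deformation is invariant under a common rigid motion", {
  tube <- make_tube_sequence(n_frames = 2, r0 = 10, n_z = 20, n_theta = 16,
                             constrictions = list(
                               list(z = 50, depth = 3, sd = 10,
                                    t_start = 0, t_end = 1)))
  d0 <- out_of_plane_deformation(tube$frames[[1]], tube$frames[[2]], dt = 1)
  tf <- random_rigid_transform(max_angle = 20, max_shift = 10, seed = 77)
  mv <- function(m) mesh_frame(apply_transform(tf, m$vertices), m$faces,
                               m$time)
  d1 <- out_of_plane_deformation(mv(tube$frames[[1]]), mv(tube$frames[[2]]),
                                 dt = 1)
  expect_lt(max(abs(d1$d - d0$d)), 1e-6)
})

test_that("a deepening constriction shows d most negative at its centre", {
  tube <- make_tube_sequence(n_frames = 3, r0 = 10, length_z = 100,
                             n_z = 30, n_theta = 16,
                             constrictions = list(
                               list(z = 50, depth = 4, sd = 8,
                                    t_start = 0, t_end = 2)))
  def <- out_of_plane_deformation(tube$frames[[1]], tube$frames[[2]], dt = 1)
  interior <- !def$boundary
  zc <- tube$frames[[1]]$vertices[, 3]
  expect_lt(min(def$d[interior]), 0)
  worst <- which.min(ifelse(interior, def$d, Inf))
  expect_lt(abs(zc[worst] - 50), 10)

  ## no constriction, no motion: d ~ 0
  still <- make_tube_sequence(n_frames = 2, r0 = 10, n_z = 20, n_theta = 16)
  d0 <- out_of_plane_deformation(still$frames[[1]], still$frames[[2]], dt = 1)
  expect_true(all(abs(d0$d) < 1e-12))
})

test_that("lagrangian_autocorr sees amplitude-invariant patterns and blocks", {
  tube0 <- make_tube_mesh(rep(10, 20), 100, n_z = 20, n_theta = 12)
  nv <- nrow(tube0$vertices)
  zc <- tube0$vertices[, 3]
  patA <- -exp(-(zc - 50)^2 / 100)          # middle constriction pattern
  patB <- -exp(-(zc - 15)^2 / 100) - exp(-(zc - 85)^2 / 100)
  mkdef <- function(pat, amp, t) structure(
    list(H = rep(0.05, nv), v_n = pat * amp / 0.1, d = pat * amp,
         boundary = rep(FALSE, nv), time = t),
    class = "deformation_frame")
  ## same material pattern, varying amplitude -> all-ones matrix
  defsA <- lapply(1:4, function(k) mkdef(patA, k / 2, k - 1))
  mA <- lagrangian_autocorr(defsA)
  expect_equal(mA$values, matrix(1, 4, 4), tolerance = 1e-12)

  ## two-phase program -> block structure with the direct-Pearson off-block
  defs2 <- c(lapply(1:3, function(k) mkdef(patA, 1, k - 1)),
             lapply(4:6, function(k) mkdef(patB, 1, k - 1)))
  m2 <- lagrangian_autocorr(defs2)
  expect_equal(m2$values[1:3, 1:3], matrix(1, 3, 3), tolerance = 1e-12)
  expect_equal(m2$values[1, 4], stats::cor(patA, patB), tolerance = 1e-12)

  ## noise-only frames: near-zero off-diagonal mean
  set.seed(9)
  defsn <- lapply(1:5, function(k) mkdef(rnorm(nv), 1, k - 1))
  mn <- lagrangian_autocorr(defsn)
  off <- mn$values[upper.tri(mn$values)]
  expect_lt(abs(mean(off)), 2 / sqrt(nv))
})

test_that("shape similarity + monotone path recovers a tube time warp", {
  sched <- list(list(z = 30, depth = 4, sd = 8, t_start = 0, t_end = 4),
                list(z = 60, depth = 5, sd = 7, t_start = 3, t_end = 8),
                list(z = 45, depth = 3, sd = 6, t_start = 6, t_end = 10))
  seq_a <- make_tube_sequence(n_frames = 11, dt = 1, r0 = 10,
                              n_z = 16, n_theta = 10, constrictions = sched)
  ## embryo B: same program recorded at 2x slower clock + rigid motions
  sched_b <- lapply(sched, function(cs) {
    cs$t_start <- cs$t_start * 2; cs$t_end <- cs$t_end * 2; cs
  })
  motions <- lapply(1:21, function(k)
    random_rigid_transform(max_angle = 15, max_shift = 4, seed = 500 + k))
  seq_b <- make_tube_sequence(n_frames = 21, dt = 1, r0 = 10,
                              n_z = 16, n_theta = 10,
                              constrictions = sched_b,
                              rigid_motions = motions)
  m <- shape_similarity_matrix(seq_a, seq_b)
  expect_true(all(is.finite(m$values)))
  cv <- monotone_shortest_path(m)
  err <- abs(cv$t_b - 2 * cv$t_a)
  expect_lte(stats::median(err), 1)

  ## ICP invariance: rigidly transformed copy gives the same matrix
  m_self <- shape_similarity_matrix(seq_a, seq_a)
  expect_true(all(diff(apply(m_self$values, 1, which.max)) >= 0))
})
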