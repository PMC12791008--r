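## Helper: banded similarity matrix whose ridge follows row = col + offset.
banded_matrix <- function(n, m, offset = 0, width = 1) {
  outer(seq_len(n), seq_len(m), function(i, j)
    exp(-((i - j - offset) / width)^2))
}

test_that("select_endpoints finds and orders edge maxima", {
  m <- simmat(banded_matrix(6, 6))
  ep <- select_endpoints(m)
  expect_equal(ep$start, c(1, 1))
  expect_equal(ep$end, c(6, 6))

  ## A starts 3 frames earlier: ridge shifted down
  m2 <- simmat(banded_matrix(9, 6, offset = 3))
  ep2 <- select_endpoints(m2)
  expect_equal(ep2$start, c(4, 1))   # first column, row 4 (0-based row 3)

  ## all-equal 2x2: documented tie-break toward (1,1)/(2,2)
  ep3 <- select_endpoints(simmat(matrix(0.5, 2, 2)))
  expect_equal(ep3$start, c(1, 1))
  expect_equal(ep3$end, c(2, 2))
})

test_that("monotone_shortest_path follows a dominant diagonal", {
  v <- matrix(0.1, 7, 7); diag(v) <- 0.9
  cv <- monotone_shortest_path(simmat(v), c(1, 1), c(7, 7))
  expect_equal(cv$path[, 1], 1:7)
  expect_equal(cv$path[, 2], 1:7)
})

test_that("constant matrix gives a straight path", {
  cv <- monotone_shortest_path(simmat(matrix(0.5, 6, 10)), c(1, 1), c(6, 10))
  ## straight line: t_b as a function of t_a is linear within half a step
  pred <- seq(0, 9, length.out = 6)
  expect_lt(max(abs(cv$t_b - pred)), 0.75)
})

test_that("path cost equals brute-force enumeration (>= 100 seeded 5x5s)", {
  for (s in 1:100) {
    set.seed(s)
    v <- matrix(runif(25, -0.5, 1), 5, 5)
    cv <- monotone_shortest_path(simmat(v), c(1, 1), c(5, 5))
    expect_equal(cv$cost, brute_force_path_cost(v, c(1, 1), c(5, 5)),
                 tolerance = 1e-9)
  }
})

test_that("rigid_offset applies the derivative-sum landmark formula", {
  f <- c(rep(-1, 3), rep(1, 7))
  M <- outer(f, f)
  lt <- rigid_offset(simmat(M))
  expect_equal(lt$frame, 4L)       # first frame after the sign flip
  expect_equal(lt$t0, 3)           # 0-based frame 3 at dt = 1
  expect_error(rigid_offset(simmat(matrix(1, 5, 5))),
               class = "ambiguous_landmark")
})

test_that("onset_from_acceleration finds sigmoid inflection and handles ties", {
  tt <- 0:30
  sc <- speed_curve(tt, 2 / (1 + exp(-(tt - 14.2))))
  lt <- onset_from_acceleration(sc)
  expect_lt(abs(lt$t0 - 14.2), 1.001)

  ramp <- speed_curve(0:9, 0:9)
  expect_warning(lt2 <- onset_from_acceleration(ramp), class = "onset_tie")
  expect_equal(lt2$frame, 1L)
})

test_that("onsets of time-dilated ensembles map as t0' = t0/s", {
  tt1 <- seq(0, 40, by = 1)
  base <- function(t) 3 / (1 + exp(-(t - 20) / 1.5))
  s <- 2
  sc1 <- speed_curve(tt1, base(tt1))
  sc2 <- speed_curve(tt1, s * base(tt1 * s))  # dilated clock
  ## symmetric sigmoids sampled symmetrically tie at the two central frames
  t1 <- suppressWarnings(onset_from_acceleration(sc1)$t0)
  t2 <- suppressWarnings(onset_from_acceleration(sc2)$t0)
  expect_lt(abs(t2 - t1 / s), 1.001)
})

test_that("pure time shifts give unit-slope curves matching rigid offsets", {
  ens <- synth_ensemble(1, n_frames = 30, noise_sd = 0,
                        warps = list(warp_spec(shift = 5)), seed = 7)
  a <- ens$master$images
  b <- ens$members[[1]]$images
  m <- similarity_matrix(a, b, "pearson")
  cv <- monotone_shortest_path(m)
  slope <- diff(range(cv$t_b)) / diff(range(cv$t_a))
  expect_lt(abs(slope - 1), 0.1)
  offsets <- cv$t_b - cv$t_a
  expect_lt(max(abs(offsets - 5)), 1.001)
})

test_that("consensus_timeline: identical members give identity maps", {
  tt <- 0:10
  id_curve <- morphaline:::new_correspondence_curve(tt, tt,
                                                    mean_similarity = 1)
  pairs <- list()
  for (i in c("a", "b", "c")) for (j in c("a", "b", "c")) {
    if (i != j) pairs[[length(pairs) + 1]] <-
        list(from = i, to = j, curve = id_curve)
  }
  ct <- consensus_timeline(pairs)
  for (id in ct$member_ids)
    expect_equal(ct$maps[[id]]$t_b, ct$maps[[id]]$t_a, tolerance = 1e-9)
})

test_that("consensus_timeline recovers known warps up to reparameterization", {
  ## members recorded from one master under known monotone warps g_e
  warps <- list(warp_spec(shift = 0, rate = 1),
                warp_spec(shift = 3, rate = 0.8),
                warp_spec(shift = -2, rate = 1.25))
  ens <- synth_ensemble(3, n_frames = 30, noise_sd = 0.03, warps = warps,
                        seed = 11)
  seqs <- lapply(ens$members, `[[`, "images")
  names(seqs) <- c("e1", "e2", "e3")
  pairs <- pairwise_align(seqs, "pearson")
  ct <- consensus_timeline(pairs)
  ## check pairwise composition: consensus->member_i after member_j->consensus
  ## equals g_i o g_j^-1 on the overlap (here g_e maps master -> member time)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    gi <- warps[[i]]$g; gjinv <- warps[[j]]$g_inv
    mi <- ct$maps[[i]]; mj <- ct$maps[[j]]
    tj <- mj$t_a[mj$t_a > min(mj$t_a) + 3 & mj$t_a < max(mj$t_a) - 3]
    ## member j time -> consensus -> member i time
    ti_est <- unwarp_time(mi, warp_time(mj, tj))
    ti_true <- gi(gjinv(tj))
    keep <- ti_true > min(mi$t_a) + 1 & ti_true < max(mi$t_a) - 1
    expect_lt(stats::median(abs(ti_est[keep] - ti_true[keep])), 1.0)
  }
})

test_that("consensus_timeline rejects disconnected overlap graphs", {
  tt <- 0:5
  cvu <- morphaline:::new_correspondence_curve(tt, tt, mean_similarity = 1)
  pairs <- list(list(from = "a", to = "b", curve = cvu),
                list(from = "b", to = "a", curve = cvu))
  expect_error(consensus_timeline(pairs, ids = c("a", "b", "c")),
               class = "cannot_fuse")
})

test_that("timestamp_from_chi2 matches analytic parabolas", {
  tt <- 0:10
  ts1 <- timestamp_from_chi2((tt - 5)^2, tt)
  expect_equal(ts1$t0, 5)
  expect_equal(ts1$sigma_t, 1)

  ts2 <- timestamp_from_chi2(4 * (tt - 3)^2, tt)
  expect_equal(ts2$t0, 3)
  expect_equal(ts2$sigma_t, sqrt(2 / 8))   # = 0.5 from sigma^2 = 2/chi2''

  expect_warning(timestamp_from_chi2((tt - 0)^2, tt),
                 class = "boundary_timestamp")
  expect_error(suppressWarnings(timestamp_from_chi2(-(tt - 5)^2, tt)),
               class = "uncertainty_undefined")
})

test_that("timestamp_fixed requires three live members and finds the stage", {
  ens <- synth_ensemble(1, n_frames = 25, noise_sd = 0, seed = 5)
  timeline <- ens$master$images
  feats <- lapply(timeline$frames, function(f) as.numeric(f$values))
  fx <- synth_fixed_samples(timeline, times = 12.4, noise_sd = 0.05,
                            seed = 9)
  ts <- timestamp_fixed(fx$frames[[1]], feats, times = timeline$times,
                        n_members = 3)
  expect_lt(abs(ts$t0 - 12.4), 1.5)
  expect_gt(ts$sigma_t, 0)
  expect_error(timestamp_fixed(fx$frames[[1]], feats, n_members = 2),
               class = "insufficient_members")
})
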