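test_that("rescale_collapse is exact on the self-similar family", {
  ## temperature speeds both the amplitude and the clock: v_s(t) = s v1(s t)
  base <- function(t) 3 * exp(-((t - 15) / 6)^2) + 0.5
  fam <- lapply(c(0.6, 1.0, 1.5), function(s) {
    tt <- seq(0, 30 / s, by = 0.25 / s)
    speed_curve(tt, s * base(tt * s))
  })
  out <- rescale_collapse(fam)
  expect_lt(out$residual, 1e-10)

  ident <- rescale_collapse(list(fam[[2]], fam[[2]]))
  expect_equal(ident$residual, 0)
  expect_error(rescale_collapse(list(speed_curve(0:5, rep(0, 6)))),
               class = "invalid_curve")
})

test_that("collapse shrinks the spread of noisy scaled ensembles >= 5x", {
  set.seed(202)
  base <- function(t) 3 * exp(-((t - 15) / 6)^2) + 0.5
  curves <- lapply(c(0.6, 1.0, 1.5), function(s) {
    tt <- seq(0, 30 / s, by = 0.5 / s)
    v <- s * base(tt * s)
    speed_curve(tt, pmax(v * (1 + rnorm(length(v), sd = 0.05)), 0))
  })
  out <- rescale_collapse(curves)
  expect_gte(out$residual_raw / out$residual, 5)
})

test_that("scaled_endpoint implements t1(T) = t1_ref * vmax_ref / vmax_T", {
  expect_equal(scaled_endpoint(30, 2.5, 2.5), 30)
  expect_equal(scaled_endpoint(30, 1.76, 1), 52.8)   # printed speed ratio
  expect_equal(scaled_endpoint(30, 1, 2), 15)
  expect_error(scaled_endpoint(30, 0, 1), class = "invalid_input")
})

test_that("compare_displacements holds its type-I error under the null", {
  n_seeds <- 40
  reps <- 50
  frac <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(300 + r)
    mk <- function() lapply(1:4, function(k) structure(
      list(delta = abs(rnorm(n_seeds, mean = 10, sd = 2)),
           seeds = NULL), class = "displacement_field"))
    frac[r] <- compare_displacements(mk(), mk())$fraction_significant
  }
  expect_lte(mean(frac), 0.05 + 0.02)
})

test_that("compare_displacements flags genuinely shifted seeds", {
  set.seed(301)
  n_seeds <- 40
  shift_idx <- 1:20
  mk <- function(shift = 0) lapply(1:5, function(k) {
    d <- abs(rnorm(n_seeds, mean = 10, sd = 1))
    if (shift > 0) d[shift_idx] <- d[shift_idx] + shift
    structure(list(delta = d, seeds = NULL), class = "displacement_field")
  })
  res <- compare_displacements(mk(0), mk(5))   # 5 in-condition s.d.
  expect_gt(mean(res$significant[shift_idx]), 0.9)

  a <- mk(0)
  expect_equal(compare_displacements(a, a)$fraction_significant, 0)
  expect_error(compare_displacements(a[1:2], a),
               class = "insufficient_replicates")
})

test_that("mitotic_ratio computes per-domain and pairwise ratios", {
  mk <- function(onsets) data.frame(
    domain = rep(names(onsets), each = 2),
    side = rep(c("left", "right"), length(onsets)),
    onset_min = rep(unname(unlist(onsets)), each = 2),
    condition = "x")
  hot <- mk(list(`1` = 10, `2` = 14, `5` = 20, `6` = 26, `11` = 30))
  expect_warning(r1 <- mitotic_ratio(hot, hot), regexp = NA)
  expect_equal(unname(r1$ratios), rep(1, 5))
  expect_equal(r1$sem, 0)   # s.e.m. over domains; identical tables spread 0

  cold <- mk(list(`1` = 30, `2` = 42, `5` = 60, `6` = 78, `11` = 90))
  r3 <- mitotic_ratio(cold, hot, reference = "onset")
  expect_equal(unname(r3$ratios), rep(3, 5))
  r3p <- mitotic_ratio(cold, hot, reference = "pairwise")
  expect_equal(unname(r3p$ratios), rep(3, choose(5, 2)))

  ## invariance to a common shift within one condition (pairwise reference)
  cold_sh <- cold; cold_sh$onset_min <- cold_sh$onset_min + 7
  expect_equal(mitotic_ratio(cold_sh, hot, "pairwise")$ratios, r3p$ratios)

  ## single shared domain: mean defined, s.e.m. flagged
  h1 <- mk(list(`1` = 10)); c1 <- mk(list(`1` = 25))
  expect_warning(rs <- mitotic_ratio(c1, h1), class = "no_sem")
  expect_equal(unname(rs$mean), 2.5)
  expect_true(is.na(rs$sem))
})

test_that("flow_speed_ratio compares clock scalings", {
  sc_cold <- speed_curve(0:10, seq(0, 1, length.out = 11))
  sc_hot <- speed_curve(0:10, seq(0, 1.76, length.out = 11))
  fr <- flow_speed_ratio(sc_cold, sc_hot)
  expect_equal(fr$ratio, 1.76)
})

test_that("decorrelation_timescale_obs fits two-term Gaussians", {
  x <- seq(-20, 20, by = 0.25)
  y2 <- 0.5 * exp(-x^2 / (2 * 2^2)) + 0.5 * exp(-x^2 / (2 * 7.6^2))
  fit <- decorrelation_timescale_obs(x, y2)
  expect_equal(fit$fit_type, "two_term")
  expect_equal(fit$t_obs, 2, tolerance = 0.05)

  y1 <- exp(-x^2 / (2 * 2^2))
  expect_warning(fit1 <- decorrelation_timescale_obs(x, y1),
                 class = "gaussian_fallback")
  expect_equal(fit1$t_obs, 2, tolerance = 0.02)

  expect_error(decorrelation_timescale_obs(x, rep(0.3, length(x))),
               class = "fit_failed")
})

test_that("stripe_width is twice the intensity-weighted s.d.", {
  x <- seq(-30, 30, by = 0.05)
  gauss <- exp(-x^2 / (2 * 4^2))
  expect_equal(stripe_width(x, gauss), 8, tolerance = 1e-3)
  W <- 12
  box <- as.numeric(abs(x) <= W / 2)
  expect_equal(stripe_width(x, box), 2 * W / sqrt(12), tolerance = 1e-2)
  expect_equal(stripe_width(x + 100, box), stripe_width(x, box))
  expect_error(stripe_width(x, x * 0), class = "invalid_input")
})

test_that("decorrelation_timescale_est and threshold match printed values", {
  expect_equal(round(decorrelation_timescale_est(0.34, 19.0, 3.13), 1), 2.1)
  expect_equal(decorrelation_timescale_est(1, 1, 1), 1)
  expect_equal(decorrelation_timescale_est(0.34, 38.0, 3.13),
               2 * decorrelation_timescale_est(0.34, 19.0, 3.13))
  expect_equal(round(decorrelation_threshold(), 2), 0.61)
  expect_error(decorrelation_timescale_est(0.34, -1, 3.13),
               class = "invalid_input")
})

test_that("shift_fraction_c has its closed forms and matches grid search", {
  expect_equal(shift_fraction_c(1, "pearson"), 0)
  expect_equal(shift_fraction_c(exp(-0.5), "pearson"),
               acos(exp(-0.5)) / (2 * pi), tolerance = 1e-10)
  expect_equal(shift_fraction_c(exp(-0.5), "pearson"), 0.1463,
               tolerance = 1e-3)
  expect_equal(shift_fraction_c(exp(-0.5), "uncentered"), 0.2789,
               tolerance = 1e-3)
  expect_error(shift_fraction_c(0.2, "uncentered"),
               class = "unreachable_threshold")

  ## brute-force grid search oracle on actual cos^2 patterns
  xx <- seq(0, 2 * pi, length.out = 4001)[-4001]
  f <- cos(xx)^2
  cgrid <- seq(0, 0.5, by = 1e-4)
  corr_at <- vapply(cgrid, function(c) {
    gshift <- cos(xx - pi * c)^2   # shift by c * wavelength (pi in x)
    stats::cor(f, gshift)
  }, numeric(1))
  thr <- exp(-0.5)
  c_bf <- cgrid[which(corr_at <= thr)[1]]
  expect_equal(shift_fraction_c(thr, "pearson"), c_bf, tolerance = 2e-4)
})
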