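## Ground-truthed synthetic data: piecewise-stationary flows, advected stripe
## patterns, monotone time warps, temperature-scaled ensembles and hidden-time
## fixed samples. Every generator is deterministic given (parameters, seed).

## Run code under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

## Built-in stationary flow patterns on a chart grid. Each returns unit-scale
## v1/v2 matrices; the three stock patterns have mutually distinct vorticity
## structure (convergence has none, the quadrupole has a 2x2 vortex array,
## rotation a single central vortex).
flow_pattern <- function(id, spec, fn = NULL) {
  L1 <- spec$n1 * spec$spacing1
  L2 <- spec$n2 * spec$spacing2
  X1 <- matrix(grid_x1(spec), spec$n1, spec$n2)
  X2 <- matrix(grid_x2(spec), spec$n1, spec$n2, byrow = TRUE)
  switch(id,
    furrow_convergence = list(
      ## circumferential convergence toward x2 = L2/2, modulated along x1 so
      ## the pattern carries a nonzero vorticity fingerprint
      v1 = matrix(0, spec$n1, spec$n2),
      v2 = -sin(2 * pi * (X2 - L2 / 2) / L2) *
        (1 + 0.4 * cos(2 * pi * X1 / L1))),
    extension_quadrupole = {
      ## stream function cos(2 pi x1/L1) cos(2 pi x2/L2): 4-vortex array
      psi_a <- 2 * pi / L1; psi_b <- 2 * pi / L2
      list(v1 = -cos(psi_a * X1) * sin(psi_b * X2) * psi_b / max(psi_a, psi_b),
           v2 = sin(psi_a * X1) * cos(psi_b * X2) * psi_a / max(psi_a, psi_b))
    },
    rotation = {
      c1 <- L1 / 2; c2 <- L2 / 2
      sg <- min(L1, L2) / 4
      env <- exp(-((X1 - c1)^2 + (X2 - c2)^2) / (2 * sg^2))
      list(v1 = -(X2 - c2) / sg * env, v2 = (X1 - c1) / sg * env)
    },
    custom = {
      if (is.null(fn)) stop_morph("invalid_input", "custom pattern needs fn")
      fn(X1, X2)
    },
    stop_morph("invalid_input", sprintf("unknown pattern '%s'", id)))
}

#' Module specification for synthetic flows
#'
#' @param pattern `"furrow_convergence"`, `"extension_quadrupole"`,
#'   `"rotation"` or `"custom"`.
#' @param t_start,t_end active window (min), `t_start < t_end`.
#' @param magnitude peak speed (um/min) or a nonnegative envelope
#'   `function(t)`.
#' @param fn for `"custom"`: `function(X1, X2)` returning `list(v1, v2)`.
#' @return object of class `module_spec`.
#' @export
module_spec <- function(pattern, t_start, t_end, magnitude = 1, fn = NULL) {
  if (t_end <= t_start)
    stop_morph("invalid_input", "module window must have t_start < t_end")
  structure(list(pattern = pattern, t_start = t_start, t_end = t_end,
                 magnitude = magnitude, fn = fn),
            class = "module_spec")
}

#' Generate a piecewise-stationary modular flow
#'
#' The velocity field is a sum over active modules of
#' `envelope_k(t) * P_k(x)`, where each `P_k` is a fixed smooth spatial
#' pattern; outside all module windows the flow is zero plus noise. This
#' emulates the observed organization of gastrulation flows into a few
#' quasi-stationary modules separated by rapid transitions.
#'
#' @param spec a [grid_spec()].
#' @param modules list of [module_spec()]; windows must not overlap.
#' @param n_frames number of frames.
#' @param dt frame interval (min, default 1).
#' @param noise_sd additive velocity noise s.d. (um/min).
#' @param seed RNG seed.
#' @return a [velocity_sequence()] with a `truth` attribute recording the
#'   module boundaries.
#' @export
make_modular_flow <- function(spec, modules, n_frames = 60L, dt = 1,
                              noise_sd = 0, seed = NULL) {
  spans <- lapply(modules, function(m) c(m$t_start, m$t_end))
  if (length(spans) > 1L) {
    o <- order(vapply(spans, `[`, numeric(1), 1))
    spans <- spans[o]
    for (k in seq_len(length(spans) - 1L))
      if (spans[[k]][2] > spans[[k + 1L]][1])
        stop_morph("invalid_input", "module windows overlap")
  }
  pats <- lapply(modules, function(m) flow_pattern(m$pattern, spec, m$fn))
  envs <- lapply(modules, function(m) {
    if (is.function(m$magnitude)) m$magnitude
    else local({ mag <- m$magnitude; function(t) rep(mag, length(t)) })
  })
  with_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(k) {
      t <- (k - 1) * dt
      v1 <- matrix(0, spec$n1, spec$n2)
      v2 <- matrix(0, spec$n1, spec$n2)
      for (m in seq_along(modules)) {
        if (t >= modules[[m]]$t_start && t < modules[[m]]$t_end) {
          a <- envs[[m]](t)
          v1 <- v1 + a * pats[[m]]$v1
          v2 <- v2 + a * pats[[m]]$v2
        }
      }
      if (noise_sd > 0) {
        v1 <- v1 + matrix(stats::rnorm(spec$n1 * spec$n2, sd = noise_sd),
                          spec$n1, spec$n2)
        v2 <- v2 + matrix(stats::rnorm(spec$n1 * spec$n2, sd = noise_sd),
                          spec$n1, spec$n2)
      }
      velocity_frame(v1, v2, spec, time = t)
    })
    out <- velocity_sequence(frames, dt = dt)
    attr(out, "truth") <- list(modules = lapply(modules, function(m)
      list(pattern = m$pattern, t_start = m$t_start, t_end = m$t_end)))
    out
  })
}

## RK4 backtracking of positions from time t1 to t0 (< t1) through `flow`.
backtrack_positions <- function(flow, pos, t1, t0, dt_int = 0.2) {
  g <- flow$grid
  period2 <- g$n2 * g$spacing2
  wrap2 <- function(p) {
    if (g$periodic2) p[, 2] <- p[, 2] %% period2
    p
  }
  x1max <- (g$n1 - 1) * g$spacing1
  t <- t1
  while (t > t0 + 1e-12) {
    h <- min(dt_int, t - t0)
    k1 <- velocity_at(flow, t, wrap2(pos))
    k2 <- velocity_at(flow, t - h / 2, wrap2(pos - h / 2 * k1))
    k3 <- velocity_at(flow, t - h / 2, wrap2(pos - h / 2 * k2))
    k4 <- velocity_at(flow, t - h, wrap2(pos - h * k3))
    step <- h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    step[is.na(step)] <- 0
    pos <- pos - step
    pos[, 1] <- pmin(pmax(pos[, 1], 0), x1max)   # clamp at x1 edges
    t <- t - h
  }
  wrap2(pos)
}

## Bilinear sampling of a scalar matrix at physical positions.
sample_scalar <- function(frame, pos) {
  g <- frame$grid
  vf <- velocity_frame(frame$values, frame$values, g)
  interp_velocity(vf, pos)[, 1]
}

#' Advect a scalar pattern through a flow
#'
#' Semi-Lagrangian advection: each output frame samples the initial pattern
#' at the RK4-backtracked source position of every node (bilinear
#' interpolation, `x2` wrapped, clamped at the `x1` edges). Mimics how
#' stripe patterns are carried along by tissue flow.
#'
#' @param init a [field_frame()] at the flow's first time.
#' @param flow a [velocity_sequence()].
#' @param dt_int backtracking integration step (min).
#' @return a [field_sequence()] at the flow's frame times.
#' @export
advect_scalar <- function(init, flow, dt_int = 0.2) {
  g <- flow$grid
  X1 <- matrix(grid_x1(g), g$n1, g$n2)
  X2 <- matrix(grid_x2(g), g$n1, g$n2, byrow = TRUE)
  nodes <- cbind(as.numeric(X1), as.numeric(X2))
  t0 <- flow$times[1]
  frames <- lapply(seq_along(flow$times), function(k) {
    t <- flow$times[k]
    if (t <= t0) return(field_frame(init$values, g, t))
    src <- backtrack_positions(flow, nodes, t, t0, dt_int)
    vals <- matrix(sample_scalar(init, src), g$n1, g$n2)
    field_frame(vals, g, t)
  })
  field_sequence(frames, dt = flow$dt)
}

#' Monotone time-warp specification
#'
#' `g(t) = shift + rate * t + amp * sin(2 pi t / period)` maps true
#' (reference) time to recorded time; `g' > 0` is enforced at construction
#' (`rate > 2 pi amp / period`). Stands in for embryo-to-embryo variation in
#' morphogenetic rate.
#'
#' @param shift time offset (min).
#' @param rate linear rate factor (> 0); rate 0.5 means the recording runs at
#'   half the reference rate (a recorded minute covers two reference minutes).
#' @param amp amplitude of the smooth periodic perturbation (min).
#' @param period perturbation period (min).
#' @return object of class `warp_spec` with members `g` and `g_inv`.
#' @export
warp_spec <- function(shift = 0, rate = 1, amp = 0, period = 60) {
  if (rate <= 0) stop_morph("invalid_warp", "rate must be positive")
  if (amp < 0) stop_morph("invalid_warp", "amp must be nonnegative")
  if (amp > 0 && rate <= 2 * pi * amp / period)
    stop_morph("invalid_warp", "perturbation would destroy monotonicity")
  g <- function(t) shift + rate * t + amp * sin(2 * pi * t / period)
  g_inv <- function(tau) {
    vapply(tau, function(y) {
      lo <- (y - shift - amp) / rate - 1
      hi <- (y - shift + amp) / rate + 1
      stats::uniroot(function(t) g(t) - y, c(lo, hi), tol = 1e-10)$root
    }, numeric(1))
  }
  structure(list(shift = shift, rate = rate, amp = amp, period = period,
                 g = g, g_inv = g_inv),
            class = "warp_spec")
}

#' Apply a time warp to a sequence
#'
#' Produces the recording a warped embryo would have yielded: output frames
#' sit at uniform recorded times spanning `g([t_first, t_last])` and frame
#' values are resampled at `g_inv(recorded time)` by linear interpolation in
#' time. For velocity sequences the components are additionally divided by
#' `g'` (chain rule: a slowed recording also shows slower flow).
#'
#' @param seq a [field_sequence()] or [velocity_sequence()].
#' @param warp a [warp_spec()].
#' @param noise_sd additive noise s.d. on the resampled values.
#' @param seed RNG seed for the noise.
#' @return a sequence of the same class.
#' @export
apply_time_warp <- function(seq, warp, noise_sd = 0, seed = NULL) {
  dt <- seq$dt
  tau <- seq(warp$g(seq$times[1]), warp$g(seq$times[length(seq$times)]),
             by = dt)
  tt <- warp$g_inv(tau)
  eps <- 1e-6
  gprime <- (warp$g(tt + eps) - warp$g(tt - eps)) / (2 * eps)
  is_vel <- inherits(seq, "velocity_sequence")
  blend <- function(get) {
    lapply(seq_along(tau), function(k) {
      t <- tt[k]
      i <- findInterval(t, seq$times, all.inside = TRUE)
      w <- (t - seq$times[i]) / (seq$times[i + 1] - seq$times[i])
      w <- min(max(w, 0), 1)
      (1 - w) * get(i) + w * get(i + 1L)
    })
  }
  with_seed(seed, {
    g <- seq$grid
    noise <- function() if (noise_sd > 0)
      matrix(stats::rnorm(g$n1 * g$n2, sd = noise_sd), g$n1, g$n2) else 0
    frames <- if (is_vel) {
      v1s <- blend(function(i) seq$frames[[i]]$v1)
      v2s <- blend(function(i) seq$frames[[i]]$v2)
      lapply(seq_along(tau), function(k) {
        velocity_frame(v1s[[k]] / gprime[k] + noise(),
                       v2s[[k]] / gprime[k] + noise(),
                       g, time = tau[k])
      })
    } else {
      vs <- blend(function(i) seq$frames[[i]]$values)
      lapply(seq_along(tau), function(k) {
        field_frame(vs[[k]] + noise(), g, time = tau[k])
      })
    }
    out <- if (is_vel) velocity_sequence(frames, dt = dt)
           else field_sequence(frames, dt = dt)
    attr(out, "truth") <- list(warp = warp)
    out
  })
}

#' Synthetic ensemble of warped, scaled, noised recordings
#'
#' Builds a master stripe-image sequence (a smooth stripe pattern advected by
#' a modular flow), then realizes `n` members by applying per-member monotone
#' warps, speed scales and additive noise. The hidden truth (warps, scales)
#' is returned for assertions.
#'
#' @param n number of members (>= 3 for consensus/timestamping fixtures).
#' @param spec a [grid_spec()] (default 48 x 64 for test-scale speed).
#' @param n_frames master frame count (default 40).
#' @param dt frame interval (min).
#' @param warps list of [warp_spec()] per member (default identity).
#' @param speed_scales numeric per member; scale `s` compresses time by `s`
#'   and multiplies speeds by `s` (the temperature proxy).
#' @param noise_sd additive image noise s.d. as a fraction of the pattern
#'   amplitude (default 0.05).
#' @param seed RNG seed.
#' @return list with `members` (each `list(images, flow)`), `master`
#'   (`list(images, flow)`) and `truth`.
#' @export
synth_ensemble <- function(n, spec = grid_spec(48, 64, 5, 5),
                           n_frames = 40L, dt = 1,
                           warps = NULL, speed_scales = rep(1, n),
                           noise_sd = 0.05, seed = 1L) {
  if (n < 1L) stop_morph("invalid_input", "need at least one member")
  warps <- warps %||% replicate(n, warp_spec(), simplify = FALSE)
  T_total <- (n_frames - 1L) * dt
  modules <- list(
    module_spec("furrow_convergence", 0, 0.3 * T_total, magnitude = 2),
    module_spec("extension_quadrupole", 0.35 * T_total, 0.75 * T_total,
                magnitude = function(t)
                  3 * exp(-((t - 0.55 * T_total) / (0.12 * T_total))^2)),
    module_spec("rotation", 0.8 * T_total, T_total + dt, magnitude = 1.5))
  flow <- make_modular_flow(spec, modules, n_frames, dt, noise_sd = 0,
                            seed = seed)
  L1 <- spec$n1 * spec$spacing1
  X1 <- matrix(grid_x1(spec), spec$n1, spec$n2)
  pattern <- field_frame(cos(2 * pi * 4 * X1 / L1)^2, spec, time = 0)
  images <- advect_scalar(pattern, flow)
  amp <- stats::sd(images$frames[[1]]$values)
  members <- lapply(seq_len(n), function(e) {
    s <- speed_scales[e]
    w0 <- warps[[e]]
    ## member clock runs at rate s relative to the master: recorded time
    ## tau = g(t) / s, speeds multiplied by s
    we <- warp_spec(shift = w0$shift, rate = w0$rate / s,
                    amp = w0$amp / s, period = w0$period)
    img <- apply_time_warp(images, we, noise_sd = noise_sd * amp,
                           seed = seed + 1000L * e)
    flw <- apply_time_warp(flow, we, noise_sd = 0, seed = NULL)
    list(images = img, flow = flw)
  })
  list(members = members, master = list(images = images, flow = flow),
       truth = list(warps = warps, speed_scales = speed_scales,
                    modules = attr(flow, "truth")$modules))
}

#' Fixed samples drawn at hidden times from a sequence
#'
#' Interpolates the sequence at hidden times and adds i.i.d. Gaussian noise,
#' emulating static (fixed/stained) samples whose true stage is unknown.
#'
#' @param seq a [field_sequence()].
#' @param times hidden true times (min) inside the sequence span.
#' @param noise_sd additive noise s.d.
#' @param seed RNG seed.
#' @return list with `frames` (list of [field_frame()], times stripped) and
#'   `truth_times`.
#' @export
synth_fixed_samples <- function(seq, times, noise_sd = 0, seed = 1L) {
  g <- seq$grid
  with_seed(seed, {
    frames <- lapply(times, function(t) {
      i <- findInterval(t, seq$times, all.inside = TRUE)
      w <- (t - seq$times[i]) / (seq$times[i + 1] - seq$times[i])
      w <- min(max(w, 0), 1)
      vals <- (1 - w) * seq$frames[[i]]$values + w * seq$frames[[i + 1]]$values
      if (noise_sd > 0)
        vals <- vals + matrix(stats::rnorm(length(vals), sd = noise_sd),
                              nrow(vals), ncol(vals))
      field_frame(vals, g, time = 0)   # time deliberately uninformative
    })
    list(frames = frames, truth_times = times)
  })
}

#' Synthetic stripe image with a known analytic edge
#'
#' A bright stripe whose anterior (low `x1`) boundary follows `edge(x2)` and
#' whose width is `width`; intensity has smooth (error-function-like) flanks
#' so subpixel edge recovery is well posed.
#'
#' @param spec a [grid_spec()].
#' @param edge function of `x2` (um) returning the anterior edge `x1` (um).
#' @param width stripe width (um).
#' @param softness flank softness (um, default one grid unit).
#' @param noise_sd additive noise s.d.
#' @param seed RNG seed.
#' @return a [field_frame()].
#' @export
make_stripe_image <- function(spec, edge, width, softness = NULL,
                              noise_sd = 0, seed = NULL) {
  softness <- softness %||% spec$spacing1
  X1 <- matrix(grid_x1(spec), spec$n1, spec$n2)
  E <- matrix(edge(grid_x2(spec)), spec$n1, spec$n2, byrow = TRUE)
  sigm <- function(z) 1 / (1 + exp(-z / (softness / 4)))
  vals <- sigm(X1 - E) * sigm(E + width - X1)
  with_seed(seed, {
    if (noise_sd > 0)
      vals <- vals + matrix(stats::rnorm(length(vals), sd = noise_sd),
                            nrow(vals), ncol(vals))
    field_frame(vals, spec, time = 0)
  })
}
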