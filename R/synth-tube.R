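## Synthetic constricting-tube mesh sequences: a gut-like tube whose radius
## develops Gaussian constrictions on a schedule, with optional per-frame
## rigid motion and full recorded truth.

#' Generate a constricting-tube mesh sequence
#'
#' A tube of rest radius `r0` along `z` develops Gaussian constrictions that
#' deepen linearly over their schedule windows, mimicking the sequential
#' constrictions that divide a tubular organ into chambers. Vertex indexing
#' is consistent across frames (material correspondence); optional per-frame
#' rigid motions are recorded as truth.
#'
#' @param n_frames number of frames.
#' @param dt frame interval (min).
#' @param r0 rest radius (um).
#' @param length_z tube length (um).
#' @param n_z,n_theta mesh resolution.
#' @param constrictions list of `list(z, depth, sd, t_start, t_end)`: centre
#'   (um), final depth (um), Gaussian s.d. (um) and deepening window (min).
#' @param rigid_motions optional list of [rigid_transform()] per frame.
#' @param seed RNG seed (reserved for future noise; generation is
#'   deterministic).
#' @return a [mesh_sequence()] with a `truth` attribute
#'   (`constrictions`, `rigid_motions`, `radius` function of `(z, t)`).
#' @export
make_tube_sequence <- function(n_frames = 10L, dt = 1, r0 = 10,
                               length_z = 100, n_z = 30L, n_theta = 24L,
                               constrictions = list(), rigid_motions = NULL,
                               seed = NULL) {
  radius_at <- function(z, t) {
    r <- rep(r0, length(z))
    for (cs in constrictions) {
      frac <- min(max((t - cs$t_start) / (cs$t_end - cs$t_start), 0), 1)
      r <- r - frac * cs$depth * exp(-(z - cs$z)^2 / (2 * cs$sd^2))
    }
    r
  }
  z <- seq(0, length_z, length.out = n_z)
  for (k in seq_len(n_frames)) {
    if (any(radius_at(z, (k - 1) * dt) <= 0))
      stop_morph("invalid_input",
                 "constriction schedule drives the radius nonpositive")
  }
  frames <- lapply(seq_len(n_frames), function(k) {
    t <- (k - 1) * dt
    m <- make_tube_mesh(radius_at(z, t), length_z, n_z, n_theta)
    if (!is.null(rigid_motions)) {
      tf <- rigid_motions[[k]]
      m <- mesh_frame(apply_transform(tf, m$vertices), m$faces, time = t)
    } else m$time <- t
    m
  })
  out <- mesh_sequence(frames, dt = dt)
  attr(out, "truth") <- list(constrictions = constrictions,
                             rigid_motions = rigid_motions,
                             radius = radius_at)
  out
}

#' Random small rigid transform
#'
#' Uniform random rotation up to `max_angle` (degrees, about a random axis)
#' and uniform translation up to `max_shift` per component; handy for ICP
#' fixtures.
#'
#' @param max_angle maximum rotation angle in degrees.
#' @param max_shift maximum per-component translation (um).
#' @param seed RNG seed.
#' @return a [rigid_transform()].
#' @export
random_rigid_transform <- function(max_angle = 20, max_shift = 5,
                                   seed = NULL) {
  with_seed(seed, {
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    th <- stats::runif(1, 0, max_angle * pi / 180)
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    rigid_transform(R, stats::runif(3, -max_shift, max_shift))
  })
}
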