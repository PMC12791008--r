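## Stripe-pattern decorrelation timescales: the observed timescale from a
## two-term Gaussian fit of the autocorrelation-vs-lag curve, and the
## kinematic estimate c * w / v from stripe width and tissue speed.

#' Decorrelation threshold
#'
#' At one standard deviation a Gaussian falls to `exp(-1/2) = 1/sqrt(e)`,
#' about 0.61 of its peak; two patterns are called decorrelated when their
#' correlation drops below this level.
#'
#' @return `exp(-0.5)`.
#' @export
decorrelation_threshold <- function() exp(-0.5)

#' Observed decorrelation timescale from a correlation-vs-lag curve
#'
#' Least-squares fit of a two-term Gaussian
#' `a1 exp(-(x - mu)^2 / (2 s1^2)) + a2 exp(-(x - mu)^2 / (2 s2^2))` with a
#' shared centre; the smaller fitted s.d. is the observed decorrelation
#' timescale `t_obs`. When the fit fails or degenerates (s.d. ratio below
#' 1.2) a single Gaussian is fitted instead, with a warning.
#'
#' @param lag lag axis (min).
#' @param corr correlation values (single dominant peak).
#' @param conf confidence level for the interval (default 0.95).
#' @return list with `t_obs`, `ci` (from the fit covariance), `sigmas`,
#'   `fit_type` (`"two_term"` or `"single"`).
#' @export
decorrelation_timescale_obs <- function(lag, corr, conf = 0.95) {
  if (length(lag) != length(corr) || length(lag) < 5L)
    stop_morph("invalid_curve", "need matched lag/corr vectors, length >= 5")
  if (diff(range(corr)) < 1e-10)
    stop_morph("fit_failed", "flat curve cannot be fitted")
  mu0 <- lag[which.max(corr)]
  amp0 <- max(corr) - min(corr)
  span <- diff(range(lag))
  d <- data.frame(x = lag, y = corr)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  two <- tryCatch(
    stats::nls(y ~ a1 * exp(-(x - mu)^2 / (2 * s1^2)) +
                 a2 * exp(-(x - mu)^2 / (2 * s2^2)),
               data = d,
               start = list(a1 = amp0 / 2, a2 = amp0 / 2, mu = mu0,
                            s1 = span / 20, s2 = span / 4),
               lower = c(a1 = 0, a2 = 0, mu = min(lag),
                         s1 = 1e-6, s2 = 1e-6),
               upper = c(a1 = 2 * amp0, a2 = 2 * amp0, mu = max(lag),
                         s1 = 2 * span, s2 = 2 * span),
               algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(two)) {
    cf <- stats::coef(two)
    sab <- abs(cf[c("s1", "s2")])
    s <- sort(unname(sab))
    amps <- abs(cf[c("a1", "a2")])
    ## degenerate: nearly equal sigmas, or one component carries (almost)
    ## no amplitude -- a single Gaussian in disguise
    if (s[2] / s[1] >= 1.2 && min(amps) / sum(amps) >= 0.05) {
      which_s <- names(sab)[which.min(sab)]
      se <- tryCatch(summary(two)$coefficients[which_s, "Std. Error"],
                     error = function(e) NA_real_)
      return(list(t_obs = unname(s[1]),
                  ci = unname(s[1] + c(-1, 1) * z * se),
                  sigmas = unname(s), fit_type = "two_term"))
    }
  }
  warn_morph("gaussian_fallback",
             "two-term fit failed or degenerated; using a single Gaussian")
  one <- tryCatch(
    stats::nls(y ~ a1 * exp(-(x - mu)^2 / (2 * s1^2)),
               data = d,
               start = list(a1 = amp0, mu = mu0, s1 = span / 6),
               lower = c(a1 = 0, mu = min(lag), s1 = 1e-6),
               upper = c(a1 = 2 * amp0, mu = max(lag), s1 = 2 * span),
               algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(one))
    stop_morph("fit_failed", "Gaussian fit did not converge")
  cf <- stats::coef(one)
  se <- tryCatch(summary(one)$coefficients["s1", "Std. Error"],
                 error = function(e) NA_real_)
  list(t_obs = unname(abs(cf["s1"])),
       ci = unname(abs(cf["s1"]) + c(-1, 1) * z * se),
       sigmas = unname(abs(cf["s1"])), fit_type = "single")
}

#' Stripe width from an intensity profile
#'
#' Width is defined as twice the intensity-weighted standard deviation of
#' position along the profile.
#'
#' @param position positions along the profile (um).
#' @param intensity nonnegative intensities with positive total mass.
#' @return width in micrometres.
#' @export
stripe_width <- function(position, intensity) {
  if (any(intensity < 0)) stop_morph("invalid_input", "negative intensity")
  m <- sum(intensity)
  if (m <= 0) stop_morph("invalid_input", "zero total intensity")
  mu <- sum(position * intensity) / m
  2 * sqrt(sum(intensity * (position - mu)^2) / m)
}

#' Kinematic estimate of the decorrelation timescale
#'
#' `t_est = c * w_est / v_est`: the time for tissue moving at speed `v_est`
#' to shift a stripe of width `w_est` by the decorrelating fraction `c` of
#' its wavelength.
#'
#' @param c dimensionless shift fraction (default 0.34).
#' @param w_est stripe width (um).
#' @param v_est tissue speed (um/min).
#' @return `t_est` in minutes.
#' @export
decorrelation_timescale_est <- function(c = 0.34, w_est, v_est) {
  if (c <= 0 || w_est <= 0 || v_est <= 0)
    stop_morph("invalid_input", "all inputs must be positive")
  c * w_est / v_est
}

#' Shift fraction at which a cos^2 stripe pattern decorrelates
#'
#' For the heuristic stripe profile `f(x) = cos^2(x)` (wavelength `lambda`),
#' finds the smallest shift fraction `c = dx / lambda` at which the chosen
#' correlation of the pattern with its shifted copy equals `threshold`.
#' Pearson correlation has the closed form `corr = cos(2 pi c)`; the
#' uncentered overlap satisfies `(2 + cos(2 pi c)) / 3`. Neither candidate
#' reproduces the conventional `c ~ 0.34`, whose exact construction is not
#' fully specified, so `c` remains a user input elsewhere.
#'
#' @param threshold target correlation in (-1, 1).
#' @param measure `"pearson"` or `"uncentered"`.
#' @return shift fraction `c` in `[0, 0.5]`.
#' @export
shift_fraction_c <- function(threshold, measure = c("pearson", "uncentered")) {
  measure <- match.arg(measure)
  if (threshold >= 1) {
    if (threshold == 1) return(0)
    stop_morph("unreachable_threshold", "threshold above 1 is unreachable")
  }
  if (measure == "pearson") {
    if (threshold <= -1)
      stop_morph("unreachable_threshold", "Pearson threshold must be > -1")
    return(acos(threshold) / (2 * pi))
  }
  ## uncentered overlap ranges over [1/3, 1]
  if (threshold < 1 / 3)
    stop_morph("unreachable_threshold",
               "uncentered overlap of cos^2 never drops below 1/3")
  stats::uniroot(function(c) (2 + cos(2 * pi * c)) / 3 - threshold,
                 c(0, 0.5), tol = 1e-10)$root
}
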