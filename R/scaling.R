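## Temperature rescaling of kinematics, displacement comparisons across
## conditions, and mitotic-clock ratios.

#' Rescale speed curves by their maxima and test collapse
#'
#' Developmental kinematics at different temperatures collapse onto one
#' master curve under the parameter-free rescaling `v -> v / max(v)` and
#' `t -> t * max(v)` (rescaled speed is dimensionless; rescaled time has
#' distance units). Curves must already be rigidly aligned to their own onset
#' (`t = 0` at maximum acceleration). The collapse residual is the r.m.s.
#' difference between rescaled curves on their common support.
#'
#' @param curves list of [speed_curve()] objects, onset-aligned.
#' @param n_grid evaluation points for the residual (default 200).
#' @return list with `rescaled` (list of speed curves), `vmax` per curve,
#'   `residual` (post-collapse r.m.s. spread) and `residual_raw` (same
#'   statistic before rescaling).
#' @export
rescale_collapse <- function(curves, n_grid = 200L) {
  vmax <- vapply(curves, function(sc) max(sc$speeds), numeric(1))
  if (any(vmax <= 0))
    stop_morph("invalid_curve", "every curve needs a positive maximum speed")
  rescaled <- Map(function(sc, vm) {
    speed_curve(sc$times * vm, sc$speeds / vm)
  }, curves, vmax)
  spread <- function(cs) {
    lo <- max(vapply(cs, function(sc) min(sc$times), numeric(1)))
    hi <- min(vapply(cs, function(sc) max(sc$times), numeric(1)))
    if (hi <= lo) return(NA_real_)
    tt <- seq(lo, hi, length.out = n_grid)
    vals <- vapply(cs, function(sc) interp_clamped(sc$times, sc$speeds, tt),
                   numeric(n_grid))
    sqrt(mean(apply(vals, 1, stats::var) * 2))   # r.m.s. pairwise difference
  }
  list(rescaled = rescaled, vmax = vmax,
       residual = spread(rescaled), residual_raw = spread(curves))
}

#' Temperature-rescaled integration endpoint
#'
#' `t1(T) = t1_ref * vmax_ref / vmax_T`: cold embryos (smaller peak speed)
#' are integrated for proportionally longer, hot ones for shorter, so that
#' total deformation is compared at matched rescaled time.
#'
#' @param t1_ref reference endpoint (min, e.g. at 22 degrees C).
#' @param vmax_ref,vmax_T peak r.m.s. speeds of reference and target
#'   condition (um/min, positive).
#' @return rescaled endpoint in minutes.
#' @export
scaled_endpoint <- function(t1_ref, vmax_ref, vmax_T) {
  if (t1_ref <= 0 || vmax_ref <= 0 || vmax_T <= 0)
    stop_morph("invalid_input", "all inputs must be positive")
  t1_ref * vmax_ref / vmax_T
}

#' Compare displacement fields between two conditions
#'
#' Tests, seed by seed, whether the between-condition difference in mean
#' displacement exceeds the in-condition variance: Welch two-sample t-test
#' per seed, Benjamini-Hochberg correction across seeds, and the fraction of
#' seeds significant at FDR `alpha` as summary. A fraction near `alpha` is
#' what a fully rescaling-explained difference looks like.
#'
#' @param fields_a,fields_b lists (>= 3 each) of `displacement_field`
#'   replicates on a common seed grid.
#' @param alpha FDR level (default 0.05).
#' @return list with `p` (raw p per seed), `p_adj`, `significant` (logical),
#'   `fraction_significant`, `n_seeds`.
#' @export
compare_displacements <- function(fields_a, fields_b, alpha = 0.05) {
  if (length(fields_a) < 3L || length(fields_b) < 3L)
    stop_morph("insufficient_replicates",
               "need at least 3 replicates per condition")
  A <- vapply(fields_a, `[[`, numeric(length(fields_a[[1]]$delta)), "delta")
  B <- vapply(fields_b, `[[`, numeric(length(fields_b[[1]]$delta)), "delta")
  if (nrow(A) != nrow(B))
    stop_morph("invalid_input", "replicates must share the seed grid")
  p <- vapply(seq_len(nrow(A)), function(i) {
    a <- A[i, ]; b <- B[i, ]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 3L || length(b) < 3L) return(NA_real_)
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
  }, numeric(1))
  usable <- !is.na(p)
  p_adj <- rep(NA_real_, length(p))
  p_adj[usable] <- stats::p.adjust(p[usable], method = "BH")
  sig <- !is.na(p_adj) & p_adj < alpha
  list(p = p, p_adj = p_adj, significant = sig,
       fraction_significant = mean(sig[usable]), n_seeds = sum(usable))
}

#' Read a mitotic event table
#'
#' @param path CSV with columns `domain,side,onset_min,condition`.
#' @return data frame of class `mitotic_event_table`.
#' @export
read_mitotic_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("domain", "side", "onset_min", "condition")
  if (!all(need %in% names(d)))
    stop_morph("invalid_input", "mitotic table needs domain,side,onset_min,condition")
  if (any(!is.finite(d$onset_min)))
    stop_morph("invalid_input", "onset times must be finite")
  class(d) <- c("mitotic_event_table", class(d))
  d
}

#' Ratio of mitotic division times between two conditions
#'
#' The mitotic clock's temperature scaling is measured as the ratio of
#' division-time intervals between a cold and a hot condition, in one of two
#' references: `"onset"` uses each domain's first-division time relative to
#' the stated reference (onset times are already reference-relative), and
#' `"pairwise"` uses the lag `delta_t` between the first divisions of every
#' domain pair. The mean and s.e.m. are taken over domains (or pairs).
#'
#' @param cold,hot mitotic event tables (data frames with `domain`,
#'   `onset_min`).
#' @param reference `"onset"` or `"pairwise"`.
#' @return list with `ratios`, `mean`, `sem`, `n`, `reference`.
#' @export
mitotic_ratio <- function(cold, hot, reference = c("onset", "pairwise")) {
  reference <- match.arg(reference)
  first_div <- function(d) {
    doms <- sort(unique(d$domain))
    stats::setNames(vapply(doms, function(g) min(d$onset_min[d$domain == g]),
                           numeric(1)), doms)
  }
  fc <- first_div(cold); fh <- first_div(hot)
  shared <- intersect(names(fc), names(fh))
  skipped <- setdiff(union(names(fc), names(fh)), shared)
  if (length(skipped))
    warn_morph("missing_domain", sprintf(
      "domain(s) %s missing in one condition; skipped",
      paste(skipped, collapse = ", ")))
  if (length(shared) == 0L)
    stop_morph("invalid_input", "no shared mitotic domains")
  if (reference == "onset") {
    ratios <- fc[shared] / fh[shared]
    names(ratios) <- shared
  } else {
    if (length(shared) < 2L)
      stop_morph("invalid_input", "pairwise reference needs >= 2 domains")
    prs <- utils::combn(shared, 2L)
    ratios <- apply(prs, 2, function(pr) {
      dc <- fc[pr[2]] - fc[pr[1]]
      dh <- fh[pr[2]] - fh[pr[1]]
      if (dh == 0) NA_real_ else dc / dh
    })
    names(ratios) <- apply(prs, 2, paste, collapse = "-")
    ratios <- ratios[!is.na(ratios)]
  }
  out <- list(ratios = ratios, mean = mean(ratios), reference = reference,
              n = length(ratios))
  if (length(ratios) < 2L) {
    out$sem <- NA_real_
    warn_morph("no_sem", "fewer than 2 usable ratios; s.e.m. undefined")
  } else {
    out$sem <- stats::sd(ratios) / sqrt(length(ratios))
  }
  out
}

#' Flow-speed ratio between two conditions
#'
#' Companion of [mitotic_ratio()]: the ratio of peak r.m.s. flow speeds
#' `max(v_hot) / max(v_cold)` quantifies how much the tissue-flow clock
#' accelerates with temperature, to be compared (Welch t-test) against the
#' mitotic-clock ratio sample.
#'
#' @param sc_cold,sc_hot [speed_curve()] objects (or lists of them for a
#'   ratio sample over replicate pairs).
#' @param mitotic_ratios optional numeric vector of mitotic ratios; when
#'   given, a Welch t-test between the two ratio samples is returned.
#' @return list with `ratio` (or `ratios`), and `test` when applicable.
#' @export
flow_speed_ratio <- function(sc_cold, sc_hot, mitotic_ratios = NULL) {
  as_list <- function(x) if (inherits(x, "speed_curve")) list(x) else x
  lc <- as_list(sc_cold); lh <- as_list(sc_hot)
  ratios <- as.numeric(outer(
    vapply(lh, function(s) max(s$speeds), numeric(1)),
    vapply(lc, function(s) max(s$speeds), numeric(1)),
    function(h, c) h / c))
  out <- list(ratios = ratios, ratio = mean(ratios))
  if (!is.null(mitotic_ratios) && length(ratios) > 1L &&
      length(mitotic_ratios) > 1L)
    out$test <- stats::t.test(ratios, mitotic_ratios)
  out
}
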