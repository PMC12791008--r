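## Deforming-surface morphodynamics: shape-based timeline correspondence,
## covariant out-of-plane deformation 2 H v_n, and Lagrangian correlations.

#' Shape similarity matrix between two mesh sequences
#'
#' Entry `(i, j)` is `exp(-residual_ij / sigma_ref)`, where `residual_ij` is
#' the post-ICP r.m.s. distance between frame `i` of sequence A and frame `j`
#' of sequence B and `sigma_ref` is the median of all residuals. The result
#' is a monotone similarity in `[0, 1]` that feeds directly into
#' [monotone_shortest_path()] and [timestamp_from_chi2()] exactly like an
#' image-based similarity matrix: the organ's shape itself becomes the clock.
#'
#' @param seq_a,seq_b [mesh_sequence()] objects.
#' @param max_iter,tol ICP settings per pair.
#' @return a [similarity_matrix()].
#' @export
shape_similarity_matrix <- function(seq_a, seq_b, max_iter = 30L,
                                    tol = 1e-8) {
  na <- length(seq_a$frames); nb <- length(seq_b$frames)
  res <- matrix(NA_real_, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    res[i, j] <- tryCatch(
      suppressWarnings(
        icp_register(seq_a$frames[[i]]$vertices,
                     seq_b$frames[[j]]$vertices,
                     max_iter = max_iter, tol = tol)$residual),
      morphaline_error = function(e) NA_real_)
  }
  sigma_ref <- stats::median(res, na.rm = TRUE)
  if (!is.finite(sigma_ref) || sigma_ref <= 0)
    sigma_ref <- max(mean(res, na.rm = TRUE), .Machine$double.eps)
  new_similarity_matrix(exp(-res / sigma_ref), seq_a$times, seq_b$times,
                        "icp_shape")
}

#' Covariant out-of-plane deformation between two mesh frames
#'
#' With material vertex correspondence between consecutive frames, the normal
#' velocity is `v_n = ((x1 - x0) / dt) . n0` (positive outward) and the
#' covariant out-of-plane deformation rate is `d = 2 H v_n` with `H` the
#' discrete cotangent mean curvature of the first frame (positive for a
#' sphere with outward normals). `2 H v_n` is the rate of local area change
#' due to motion along the normal, the natural frame-invariant measure of
#' out-of-plane shape change (an inflating sphere of radius `R` at rate
#' `Rdot` has `d = 2 Rdot / R`).
#'
#' @param m0,m1 [mesh_frame()] objects with identical face lists.
#' @param dt time interval (min); default from frame times.
#' @return object of class `deformation_frame`: per-vertex `H` (1/um),
#'   `v_n` (um/min), `d = 2 H v_n` (1/min), and a `boundary` flag (open-edge
#'   vertices, where the discrete operators are unreliable).
#' @export
out_of_plane_deformation <- function(m0, m1, dt = NULL) {
  if (nrow(m0$vertices) != nrow(m1$vertices) ||
      !identical(dim(m0$faces), dim(m1$faces)))
    stop_morph("invalid_mesh", "frames must share vertex correspondence")
  dt <- dt %||% (m1$time - m0$time)
  if (is.null(dt) || !is.finite(dt) || dt <= 0)
    stop_morph("invalid_span", "dt must be positive")
  mc <- mean_curvature(m0)
  disp <- (m1$vertices - m0$vertices) / dt
  v_n <- rowSums(disp * mc$normals)
  d <- 2 * mc$H * v_n
  structure(list(H = mc$H, v_n = v_n, d = d, boundary = mc$boundary,
                 time = m0$time),
            class = "deformation_frame")
}

#' Deformation frames for a whole mesh sequence
#'
#' @param seq a [mesh_sequence()].
#' @return list of `deformation_frame` (one per consecutive frame pair).
#' @export
deformation_sequence <- function(seq) {
  n <- length(seq$frames)
  if (n < 2L) stop_morph("invalid_sequence", "need at least 2 frames")
  lapply(seq_len(n - 1L), function(k) {
    out_of_plane_deformation(seq$frames[[k]], seq$frames[[k + 1L]],
                             dt = seq$times[k + 1L] - seq$times[k])
  })
}

#' Lagrangian autocorrelation of out-of-plane deformation
#'
#' Because vertices are material points, correlating per-vertex deformation
#' fields across timepoints is a tissue-frame (Lagrangian) correlation:
#' entry `(i, j)` is the Pearson correlation over vertices of `d_i` against
#' `d_j`. Boundary vertices are excluded.
#'
#' @param defs list of `deformation_frame` objects sharing vertex indexing.
#' @return a [similarity_matrix()].
#' @export
lagrangian_autocorr <- function(defs) {
  n <- length(defs)
  if (n < 2L) stop_morph("invalid_sequence", "need at least 2 frames")
  keep <- !Reduce(`|`, lapply(defs, `[[`, "boundary"))
  v <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    x <- defs[[i]]$d[keep]; y <- defs[[j]]$d[keep]
    ok <- is.finite(x) & is.finite(y)
    val <- if (sum(ok) > 2L && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0)
      stats::cor(x[ok], y[ok]) else NA_real_
    v[i, j] <- val; v[j, i] <- val
  }
  times <- vapply(defs, `[[`, numeric(1), "time")
  new_similarity_matrix(v, times, times, "lagrangian_2Hvn")
}
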