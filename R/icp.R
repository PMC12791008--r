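## Iterative closest point rigid registration (Kabsch/SVD inner step).

#' Rigid transform container
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 vector (um).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop_morph("invalid_transform", "rotation must be special orthogonal")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param tf a [rigid_transform()].
#' @param p `n x 3` matrix.
#' @return transformed `n x 3` matrix.
#' @export
apply_transform <- function(tf, p) {
  sweep(as.matrix(p) %*% t(tf$rotation), 2, -tf$translation)
}

## Closed-form least-squares rigid fit of p onto q (matched rows), Kabsch.
kabsch <- function(p, q) {
  cp <- colMeans(p); cq <- colMeans(q)
  H <- crossprod(sweep(p, 2, cp), sweep(q, 2, cq))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cq - as.numeric(R %*% cp)
  rigid_transform(R, t)
}

## Brute-force nearest neighbours of rows of p among rows of q.
nearest_neighbours <- function(p, q) {
  qq <- rowSums(q^2)
  apply(p, 1, function(x) {
    which.min(qq - 2 * as.numeric(q %*% x))
  })
}

#' Iterative closest point registration
#'
#' Registers point set `p` onto `q` by alternating nearest-neighbour
#' correspondence with the closed-form (SVD/Kabsch) rigid fit until the
#' r.m.s. residual change falls below `tol`. Initialization aligns centroids
#' and principal axes (sign-disambiguated by residual), which keeps elongated
#' organ shapes out of the head-to-tail local minimum; convergence is only
#' guaranteed within that basin.
#'
#' @param p,q `n x 3` / `m x 3` matrices (>= 4 non-coplanar points each).
#' @param max_iter iteration cap (default 50).
#' @param tol residual-change tolerance (default 1e-10).
#' @param init `"pca"` (default) or `"centroid"` initialization.
#' @return list with `transform` (a [rigid_transform()] mapping `p` onto
#'   `q`), `residual` (final r.m.s. nearest-neighbour distance),
#'   `iterations`, `converged`.
#' @export
icp_register <- function(p, q, max_iter = 50L, tol = 1e-10,
                         init = c("pca", "centroid")) {
  init <- match.arg(init)
  p <- as.matrix(p); q <- as.matrix(q)
  check_nondegenerate <- function(x, name) {
    if (nrow(x) < 4L)
      stop_morph("degenerate_points", sprintf("%s needs >= 4 points", name))
    sv <- svd(sweep(x, 2, colMeans(x)))$d
    if (sv[3] < 1e-9 * max(sv[1], 1e-300))
      stop_morph("degenerate_points",
                 sprintf("%s points are coplanar or collinear", name))
  }
  check_nondegenerate(p, "p"); check_nondegenerate(q, "q")

  rms_to_q <- function(x) {
    nn <- nearest_neighbours(x, q)
    sqrt(mean(rowSums((x - q[nn, , drop = FALSE])^2)))
  }
  ## initialization candidates: centroid shift, optionally with principal-axes
  ## pre-rotations (PCA axes have sign ambiguity; test the 4 proper options)
  cp <- colMeans(p); cq <- colMeans(q)
  inits <- list(rigid_transform(diag(3), cq - cp))
  if (init == "pca") {
    Ep <- svd(sweep(p, 2, cp))$v
    Eq <- svd(sweep(q, 2, cq))$v
    flips <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
    for (fl in flips) {
      R <- Eq %*% diag(fl) %*% t(Ep)
      if (det(R) < 0) R <- Eq %*% diag(-fl) %*% t(Ep)
      inits[[length(inits) + 1L]] <-
        rigid_transform(R, cq - as.numeric(R %*% cp))
    }
  }
  res0 <- vapply(inits, function(tf) rms_to_q(apply_transform(tf, p)),
                 numeric(1))
  tf <- inits[[which.min(res0)]]

  x <- apply_transform(tf, p)
  prev <- Inf
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    nn <- nearest_neighbours(x, q)
    step <- kabsch(x, q[nn, , drop = FALSE])
    x <- apply_transform(step, x)
    tf <- rigid_transform(step$rotation %*% tf$rotation,
                          as.numeric(step$rotation %*% tf$translation) +
                            step$translation)
    res <- sqrt(mean(rowSums((x - q[nearest_neighbours(x, q), ,
                                    drop = FALSE])^2)))
    done <- abs(prev - res) < tol
    prev <- res
    if (done) { converged <- TRUE; break }
  }
  if (!converged)
    warn_morph("icp_no_convergence",
               sprintf("ICP did not converge in %d iterations", max_iter))
  list(transform = tf, residual = prev, iterations = iterations,
       converged = converged)
}
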