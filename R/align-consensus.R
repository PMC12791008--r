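## All-to-all alignment and consensus timeline construction.

#' Pairwise-align every ordered pair of sequences
#'
#' Convenience wrapper producing the input of [consensus_timeline()]: for each
#' ordered pair of members it builds the similarity matrix and traces the
#' monotone shortest path.
#'
#' @param seqs named list of sequences (one per member).
#' @param measure,... passed to [similarity_matrix()].
#' @return list of `list(from, to, curve)` records.
#' @export
pairwise_align <- function(seqs, measure = "pearson", ...) {
  ids <- names(seqs)
  if (is.null(ids)) stop_morph("invalid_sequence", "seqs must be named")
  pairs <- list()
  for (i in ids) for (j in ids) {
    if (i == j) next
    curve <- tryCatch({
      m <- similarity_matrix(seqs[[i]], seqs[[j]], measure, ...)
      monotone_shortest_path(m)
    }, morphaline_error = function(e) NULL)
    if (!is.null(curve))
      pairs[[length(pairs) + 1L]] <- list(from = i, to = j, curve = curve)
  }
  pairs
}

#' Fuse pairwise correspondences into a consensus timeline
#'
#' Designating one recording as the reference would tie the timeline to its
#' idiosyncrasies. Instead the member with the highest mean pairwise
#' similarity along its correspondence curves (the medoid) seeds the consensus
#' axis, every member is mapped onto it through its pairwise curve, and one
#' refinement pass replaces each consensus time by the average raw member time
#' at that stage, removing the medoid's own warp. Maps are re-fitted
#' monotonically.
#'
#' @param pairs list of `list(from, to, curve)` as from [pairwise_align()].
#' @param ids member identifiers (default: all ids appearing in `pairs`).
#' @return object of class `consensus_timeline`: `member_ids`, `medoid`,
#'   `maps` (per member, a `correspondence_curve` member-time to
#'   consensus-time), `consensus_times`, `dt`.
#' @export
consensus_timeline <- function(pairs, ids = NULL) {
  from <- vapply(pairs, `[[`, character(1), "from")
  to <- vapply(pairs, `[[`, character(1), "to")
  ids <- ids %||% sort(unique(c(from, to)))
  if (length(ids) < 2L)
    stop_morph("cannot_fuse", "need at least two members")
  ## connectivity of the (undirected) overlap graph
  comp <- stats::setNames(seq_along(ids), ids)
  for (k in seq_along(pairs)) {
    a <- comp[[from[k]]]; b <- comp[[to[k]]]
    if (a != b) comp[comp == b] <- a
  }
  if (length(unique(comp)) > 1L)
    stop_morph("cannot_fuse", "overlap graph is disconnected")

  get_curve <- function(i, j) {
    k <- which(from == i & to == j)
    if (length(k)) return(pairs[[k[1]]]$curve)
    k <- which(from == j & to == i)
    if (length(k)) { # invert the reverse curve
      cv <- pairs[[k[1]]]$curve
      keep <- c(TRUE, diff(cv$t_b) > 0)
      return(new_correspondence_curve(cv$t_b[keep], cv$t_a[keep],
                                      mean_similarity = cv$mean_similarity))
    }
    NULL
  }

  mean_sim <- vapply(ids, function(i) {
    s <- vapply(pairs[from == i | to == i], function(p) p$curve$mean_similarity,
                numeric(1))
    if (length(s)) mean(s, na.rm = TRUE) else -Inf
  }, numeric(1))
  medoid <- ids[which.max(mean_sim)]

  ## medoid frame times define the initial consensus axis
  med_times <- NULL
  for (p in pairs) {
    if (p$from == medoid) med_times <- union(med_times, p$curve$t_a)
    if (p$to == medoid) med_times <- union(med_times, p$curve$t_b)
  }
  med_times <- sort(med_times)

  maps0 <- lapply(ids, function(i) {
    if (i == medoid)
      return(new_correspondence_curve(med_times, med_times))
    cv <- get_curve(i, medoid)
    if (is.null(cv))
      stop_morph("cannot_fuse", sprintf("no curve linking %s to medoid", i))
    cv
  })
  names(maps0) <- ids

  ## refinement: consensus time of a stage := mean member raw time there
  h <- vapply(med_times, function(t) {
    mean(vapply(maps0, function(cv) unwarp_time(cv, t), numeric(1)))
  }, numeric(1))
  h <- fit_monotone(med_times, h)
  maps <- lapply(ids, function(i) {
    cv <- maps0[[i]]
    tb <- interp_clamped(med_times, h, cv$t_b)
    tb <- fit_monotone(cv$t_a, tb)
    new_correspondence_curve(cv$t_a, tb,
                             mean_similarity = cv$mean_similarity)
  })
  names(maps) <- ids
  cons_times <- sort(unique(h))
  dt <- if (length(cons_times) > 1L) stats::median(diff(cons_times)) else 1
  structure(list(member_ids = ids, medoid = medoid, maps = maps,
                 consensus_times = cons_times, dt = dt),
            class = "consensus_timeline")
}

#' @export
print.consensus_timeline <- function(x, ...) {
  cat(sprintf("<consensus_timeline> %d members (medoid %s), dt = %.3g min\n",
              length(x$member_ids), x$medoid, x$dt))
  invisible(x)
}
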