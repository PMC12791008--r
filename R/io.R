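## Plain-text interchange formats. Scalar field sequences travel as
## long-format CSV plus a JSON metadata sidecar (no binary containers);
## velocity sequences, curves, similarity matrices and segmentations use the
## CSV/JSON layouts documented on each function.

meta_sidecar_path <- function(path) paste0(path, ".json")

#' Read / write a scalar field sequence as CSV + JSON sidecar
#'
#' CSV columns `frame,x1_idx,x2_idx,value` (0-based indices); the sidecar
#' `<path>.json` holds `{dt_min, start_time_min, spacing1_um, spacing2_um,
#' periodic2}`.
#'
#' @param seq a [field_sequence()] (write only).
#' @param path CSV path.
#' @return `read_field_sequence` returns a [field_sequence()].
#' @export
write_field_sequence <- function(seq, path) {
  g <- seq$grid
  rows <- do.call(rbind, lapply(seq_along(seq$frames), function(k) {
    v <- seq$frames[[k]]$values
    data.frame(frame = k - 1L,
               x1_idx = rep(seq_len(g$n1) - 1L, g$n2),
               x2_idx = rep(seq_len(g$n2) - 1L, each = g$n1),
               value = as.numeric(v))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  jsonlite::write_json(
    list(dt_min = seq$dt, start_time_min = seq$times[1],
         spacing1_um = g$spacing1, spacing2_um = g$spacing2,
         periodic2 = g$periodic2),
    meta_sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field_sequence
#' @export
read_field_sequence <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(meta_sidecar_path(path), simplifyVector = TRUE)
  n1 <- max(d$x1_idx) + 1L; n2 <- max(d$x2_idx) + 1L
  g <- grid_spec(n1, n2, meta$spacing1_um, meta$spacing2_um,
                 periodic2 = isTRUE(meta$periodic2), truncation_fraction = 0)
  frames <- lapply(sort(unique(d$frame)), function(k) {
    sub <- d[d$frame == k, ]
    v <- matrix(NA_real_, n1, n2)
    v[cbind(sub$x1_idx + 1L, sub$x2_idx + 1L)] <- sub$value
    field_frame(v, g, time = meta$start_time_min + k * meta$dt_min)
  })
  field_sequence(frames, dt = meta$dt_min)
}

#' Read / write a velocity sequence as long-format CSV
#'
#' Columns `frame,x1_idx,x2_idx,v1_um_per_min,v2_um_per_min,valid` (0-based
#' indices), with the same JSON sidecar as field sequences.
#'
#' @param seq a [velocity_sequence()] (write only).
#' @param path CSV path.
#' @return `read_velocity_sequence` returns a [velocity_sequence()].
#' @export
write_velocity_sequence <- function(seq, path) {
  g <- seq$grid
  rows <- do.call(rbind, lapply(seq_along(seq$frames), function(k) {
    f <- seq$frames[[k]]
    data.frame(frame = k - 1L,
               x1_idx = rep(seq_len(g$n1) - 1L, g$n2),
               x2_idx = rep(seq_len(g$n2) - 1L, each = g$n1),
               v1_um_per_min = as.numeric(f$v1),
               v2_um_per_min = as.numeric(f$v2),
               valid = as.integer(f$valid))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  jsonlite::write_json(
    list(dt_min = seq$dt, start_time_min = seq$times[1],
         spacing1_um = g$spacing1, spacing2_um = g$spacing2,
         periodic2 = g$periodic2),
    meta_sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_velocity_sequence
#' @export
read_velocity_sequence <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(meta_sidecar_path(path), simplifyVector = TRUE)
  n1 <- max(d$x1_idx) + 1L; n2 <- max(d$x2_idx) + 1L
  g <- grid_spec(n1, n2, meta$spacing1_um, meta$spacing2_um,
                 periodic2 = isTRUE(meta$periodic2), truncation_fraction = 0)
  frames <- lapply(sort(unique(d$frame)), function(k) {
    sub <- d[d$frame == k, ]
    ix <- cbind(sub$x1_idx + 1L, sub$x2_idx + 1L)
    v1 <- matrix(NA_real_, n1, n2); v1[ix] <- sub$v1_um_per_min
    v2 <- matrix(NA_real_, n1, n2); v2[ix] <- sub$v2_um_per_min
    valid <- matrix(FALSE, n1, n2); valid[ix] <- sub$valid > 0
    velocity_frame(v1, v2, g, time = meta$start_time_min + k * meta$dt_min,
                   valid = valid)
  })
  velocity_sequence(frames, dt = meta$dt_min)
}

#' Read / write a stripe curve as CSV
#'
#' Columns `point,x1_um,x2_um`.
#'
#' @param curve a [stripe_curve()] (write only).
#' @param path CSV path.
#' @param closed2 wrap flag used on read.
#' @return `read_stripe_curve` returns a [stripe_curve()].
#' @export
write_stripe_curve <- function(curve, path) {
  utils::write.csv(data.frame(point = seq_len(nrow(curve$points)) - 1L,
                              x1_um = curve$points[, 1],
                              x2_um = curve$points[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stripe_curve
#' @export
read_stripe_curve <- function(path, closed2 = FALSE) {
  d <- utils::read.csv(path)
  stripe_curve(cbind(d$x1_um, d$x2_um)[order(d$point), , drop = FALSE],
               closed2 = closed2)
}

#' Read / write a similarity matrix as CSV + JSON sidecar
#'
#' The CSV stores the matrix with the first row holding B-times and the
#' first column holding A-times; the sidecar records `{measure_id}`.
#'
#' @param m a [similarity_matrix()] (write only).
#' @param path CSV path.
#' @return `read_similarity_matrix` returns a [similarity_matrix()].
#' @export
write_similarity_matrix <- function(m, path) {
  out <- rbind(c(NA, m$times_b), cbind(m$times_a, m$values))
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(measure_id = m$measure_id),
                       meta_sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  d <- as.matrix(utils::read.table(path, sep = ","))
  meta <- jsonlite::read_json(meta_sidecar_path(path), simplifyVector = TRUE)
  new_similarity_matrix(unname(d[-1, -1, drop = FALSE]),
                        unname(d[-1, 1]), unname(d[1, -1]),
                        meta$measure_id %||% "unknown")
}

#' Read / write a correspondence curve as CSV
#'
#' Columns `t_a_min,t_b_min`.
#'
#' @param curve a `correspondence_curve` (write only).
#' @param path CSV path.
#' @return `read_correspondence_curve` returns a `correspondence_curve`.
#' @export
write_correspondence_curve <- function(curve, path) {
  utils::write.csv(data.frame(t_a_min = curve$t_a, t_b_min = curve$t_b),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correspondence_curve
#' @export
read_correspondence_curve <- function(path) {
  d <- utils::read.csv(path)
  new_correspondence_curve(d$t_a_min, d$t_b_min)
}

#' Write a pathline set as CSV
#'
#' Columns `seed,step,t_min,x1_um,x2_um,escaped`.
#'
#' @param p a `pathline_set`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_pathline_set <- function(p, path) {
  ns <- dim(p$positions)[1]; nt <- dim(p$positions)[2]
  rows <- data.frame(
    seed = rep(seq_len(ns) - 1L, each = nt),
    step = rep(seq_len(nt) - 1L, ns),
    t_min = rep(p$t_start + (seq_len(nt) - 1L) * p$dt_int, ns),
    x1_um = as.numeric(t(p$positions[, , 1])),
    x2_um = as.numeric(t(p$positions[, , 2])),
    escaped = rep(as.integer(p$escaped), each = nt))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a module segmentation as JSON
#'
#' @param seg a `module_segmentation`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_module_segmentation <- function(seg, path) {
  jsonlite::write_json(list(threshold = seg$threshold,
                            min_len = seg$min_len,
                            modules = seg$modules),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Write a consensus timeline as JSON
#'
#' Stores member ids, the medoid, and each member's monotone map samples.
#'
#' @param ct a `consensus_timeline`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_consensus_timeline <- function(ct, path) {
  jsonlite::write_json(
    list(member_ids = ct$member_ids, medoid = ct$medoid, dt = ct$dt,
         maps = lapply(ct$maps, function(cv)
           list(t_member = cv$t_a, t_consensus = cv$t_b))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
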