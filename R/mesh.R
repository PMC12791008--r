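## Triangulated surface frames: containers, ASCII PLY I/O, primitive
## generators, vertex normals and discrete mean curvature.

#' Triangulated surface at one timepoint
#'
#' @param vertices `n x 3` matrix of positions (um).
#' @param faces `m x 3` integer matrix of 1-based triangle indices with
#'   consistent outward orientation.
#' @param time frame time (min).
#' @return object of class `mesh_frame`.
#' @export
mesh_frame <- function(vertices, faces, time = 0) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  if (ncol(vertices) != 3L) stop_morph("invalid_mesh", "vertices must be n x 3")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop_morph("invalid_mesh", "face indices out of range")
  structure(list(vertices = vertices, faces = faces, time = time),
            class = "mesh_frame")
}

#' Time-ordered mesh sequence with consistent vertex indexing
#'
#' @param frames list of [mesh_frame()] sharing a face list (material vertex
#'   correspondence across frames).
#' @param dt frame interval (min).
#' @return object of class `mesh_sequence`.
#' @export
mesh_sequence <- function(frames, dt = NULL) {
  if (length(frames) == 0L) stop_morph("invalid_sequence", "empty sequence")
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop_morph("invalid_sequence", "times must be strictly increasing")
  nv <- nrow(frames[[1]]$vertices)
  for (f in frames) if (nrow(f$vertices) != nv)
    stop_morph("invalid_sequence", "vertex counts must match across frames")
  dt <- dt %||% if (length(times) > 1L) times[2] - times[1] else 1
  structure(list(frames = frames, times = times, dt = dt),
            class = "mesh_sequence")
}

#' Read / write a mesh as ASCII PLY
#'
#' Minimal ASCII PLY support (vertex x/y/z and triangular faces), enough to
#' round-trip the package's own surfaces.
#'
#' @param path file path.
#' @param mesh a [mesh_frame()] (write only).
#' @return `read_ply` returns a [mesh_frame()]; `write_ply` returns `path`
#'   invisibly.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || lines[1] != "ply")
    stop_morph("invalid_mesh", "not a PLY file")
  hdr_end <- which(lines == "end_header")[1]
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", hdr, value = TRUE)))
  vl <- lines[hdr_end + seq_len(nv)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  fl <- lines[hdr_end + nv + seq_len(nf)]
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"),
                                 function(x) as.integer(x[2:4]) + 1L))
  mesh_frame(verts, faces)
}

#' @rdname read_ply
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  vl <- apply(v, 1, function(r) paste(format(r, trim = TRUE), collapse = " "))
  fl <- apply(f - 1L, 1, function(r) paste(c(3L, r), collapse = " "))
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}

#' Icosphere and open-tube primitive meshes
#'
#' `make_icosphere` subdivides an icosahedron and projects onto the sphere of
#' radius `r`; `make_tube_mesh` builds an open cylinder along `z` with a
#' per-ring radius profile, consistent vertex ordering (ring-major).
#'
#' @param r radius (um).
#' @param subdiv subdivision level (0 = icosahedron).
#' @return a [mesh_frame()].
#' @export
make_icosphere <- function(r = 1, subdiv = 2L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdiv)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    newf <- matrix(0L, 0L, 3L)
    get_mid <- function(a, b) {
      key <- paste(sort(c(a, b)), collapse = "_")
      id <- edge_mid[[key]]
      if (!is.null(id)) return(id)
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      id <- nrow(v)
      edge_mid[[key]] <- id
      id
    }
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, cc); ca <- get_mid(cc, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                    c(ab, bc, ca))
    }
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * r
  mesh_frame(v, f)
}

#' @rdname make_icosphere
#' @param radius_profile radii per ring (length `n_z`), or a single number.
#' @param length_z tube length (um).
#' @param n_z,n_theta rings along `z` and vertices per ring.
#' @export
make_tube_mesh <- function(radius_profile, length_z = 100, n_z = 30L,
                           n_theta = 24L) {
  rr <- rep_len(radius_profile, n_z)
  if (any(rr <= 0)) stop_morph("invalid_mesh", "tube radius must stay positive")
  z <- seq(0, length_z, length.out = n_z)
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  verts <- do.call(rbind, lapply(seq_len(n_z), function(i) {
    cbind(rr[i] * cos(th), rr[i] * sin(th), z[i])
  }))
  idx <- function(i, j) (i - 1L) * n_theta + wrap_index(j, n_theta)
  faces <- matrix(0L, 0L, 3L)
  for (i in seq_len(n_z - 1L)) {
    j <- seq_len(n_theta)
    ## outward-oriented quads split into triangles
    faces <- rbind(faces,
                   cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j)),
                   cbind(idx(i + 1L, j), idx(i, j + 1L), idx(i + 1L, j + 1L)))
  }
  mesh_frame(verts, faces)
}

## Area-weighted outward vertex normals.
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) # 2*area-weighted
  n <- matrix(0, nrow(v), 3L)
  for (c in 1:3) {
    for (ax in 1:3) {
      acc <- rep(0, nrow(v))
      sums <- rowsum(fn[, ax], f[, c])
      acc[as.integer(rownames(sums))] <- sums
      n[, ax] <- n[, ax] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

## Cotangent-Laplacian mean curvature with Meyer mixed Voronoi areas.
## Returns signed H per vertex: positive where the surface curves away from
## the outward normal (sphere with outward normals has H = 1/R).
mean_curvature <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  nv <- nrow(v)
  Lx <- matrix(0, nv, 3L)
  area <- rep(0, nv)
  cot <- function(a, b) { # cotangent of angle between vectors a and b (rows)
    cosv <- rowSums(a * b)
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    sinv <- sqrt(rowSums(cr^2))
    cosv / pmax(sinv, 1e-300)
  }
  i1 <- f[, 1]; i2 <- f[, 2]; i3 <- f[, 3]
  p1 <- v[i1, , drop = FALSE]; p2 <- v[i2, , drop = FALSE]
  p3 <- v[i3, , drop = FALSE]
  cot1 <- cot(p2 - p1, p3 - p1)   # angle at vertex 1, opposite edge (2,3)
  cot2 <- cot(p1 - p2, p3 - p2)
  cot3 <- cot(p1 - p3, p2 - p3)
  tri_area <- {
    cr <- cbind((p2 - p1)[, 2] * (p3 - p1)[, 3] - (p2 - p1)[, 3] * (p3 - p1)[, 2],
                (p2 - p1)[, 3] * (p3 - p1)[, 1] - (p2 - p1)[, 1] * (p3 - p1)[, 3],
                (p2 - p1)[, 1] * (p3 - p1)[, 2] - (p2 - p1)[, 2] * (p3 - p1)[, 1])
    0.5 * sqrt(rowSums(cr^2))
  }
  add <- function(target, idx, val) {
    s <- rowsum(val, idx)
    target[as.integer(rownames(s))] <- target[as.integer(rownames(s))] + s
    target
  }
  ## cotangent Laplace accumulation: for edge (i,j) opposite angle k,
  ## Lx_i += cot_k * (x_j - x_i)
  for (ax in 1:3) {
    Lx[, ax] <- add(Lx[, ax], i1, cot3 * (v[i2, ax] - v[i1, ax]) +
                                  cot2 * (v[i3, ax] - v[i1, ax]))
    Lx[, ax] <- add(Lx[, ax], i2, cot3 * (v[i1, ax] - v[i2, ax]) +
                                  cot1 * (v[i3, ax] - v[i2, ax]))
    Lx[, ax] <- add(Lx[, ax], i3, cot2 * (v[i1, ax] - v[i3, ax]) +
                                  cot1 * (v[i2, ax] - v[i3, ax]))
  }
  ## Meyer mixed areas: Voronoi for non-obtuse triangles, else T/2 at the
  ## obtuse vertex and T/4 at the others.
  len23sq <- rowSums((p2 - p3)^2)
  len13sq <- rowSums((p1 - p3)^2)
  len12sq <- rowSums((p1 - p2)^2)
  obtuse1 <- cot1 < 0; obtuse2 <- cot2 < 0; obtuse3 <- cot3 < 0
  any_obtuse <- obtuse1 | obtuse2 | obtuse3
  a1 <- ifelse(any_obtuse,
               ifelse(obtuse1, tri_area / 2, tri_area / 4),
               (len12sq * cot3 + len13sq * cot2) / 8)
  a2 <- ifelse(any_obtuse,
               ifelse(obtuse2, tri_area / 2, tri_area / 4),
               (len12sq * cot3 + len23sq * cot1) / 8)
  a3 <- ifelse(any_obtuse,
               ifelse(obtuse3, tri_area / 2, tri_area / 4),
               (len13sq * cot2 + len23sq * cot1) / 8)
  area <- add(area, i1, a1); area <- add(area, i2, a2)
  area <- add(area, i3, a3)
  nrm <- vertex_normals(mesh)
  ## Laplace-Beltrami of position: Delta x = Lx / (2A) = -2 H n_out,
  ## so H = -(Lx . n) / (4A); a sphere with outward normals gets H = 1/R.
  H <- -rowSums(Lx * nrm) / (4 * pmax(area, 1e-300))
  ## boundary vertices (edges with a single adjacent face) are unreliable
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  cnt <- table(key)
  bkeys <- names(cnt)[cnt == 1L]
  boundary <- rep(FALSE, nv)
  if (length(bkeys)) {
    bidx <- unique(as.integer(unlist(strsplit(bkeys, " "))))
    boundary[bidx] <- TRUE
  }
  list(H = H, area = area, normals = nrm, boundary = boundary)
}
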