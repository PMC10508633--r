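#' Triangle mesh in millimetre coordinates
#'
#' Light-weight container for a triangulated crown surface: an `n x 3` numeric
#' vertex matrix (mm) and an `m x 3` integer face matrix of 1-based vertex
#' indices. Degenerate (zero-area) faces are rejected, or silently dropped when
#' `drop_degenerate = TRUE` (the file readers do this so that downstream
#' adjacency is well defined).
#'
#' @param vertices numeric matrix with 3 columns (x, y, z in mm).
#' @param faces integer matrix with 3 columns of vertex indices (1-based).
#' @param drop_degenerate drop zero-area faces instead of erroring.
#' @return An object of class `triangle_mesh` with elements `vertices`, `faces`.
#' @export
triangle_mesh <- function(vertices, faces, drop_degenerate = FALSE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3) stop("vertices must have 3 columns")
  if (nrow(vertices) == 0) stop("mesh has no vertices")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (is.null(faces) || length(faces) == 0) {
    faces <- matrix(integer(0), ncol = 3)
  } else {
    faces <- as.matrix(faces)
    if (ncol(faces) != 3) stop("faces must have 3 columns")
  }
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices)) {
      stop("face indices out of range")
    }
    areas <- face_areas(vertices, faces)
    degen <- areas < 1e-12 | faces[, 1] == faces[, 2] |
      faces[, 2] == faces[, 3] | faces[, 1] == faces[, 3]
    if (any(degen)) {
      if (drop_degenerate) {
        faces <- faces[!degen, , drop = FALSE]
      } else {
        stop(sum(degen), " degenerate (zero-area) face(s)")
      }
    }
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  bb <- bounding_box(x)
  cat(sprintf(
    "<triangle_mesh: %d vertices, %d faces, bbox [%.2f %.2f %.2f]-[%.2f %.2f %.2f] mm>\n",
    nrow(x$vertices), nrow(x$faces),
    bb$min[1], bb$min[2], bb$min[3], bb$max[1], bb$max[2], bb$max[3]
  ))
  invisible(x)
}

face_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  cr <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  0.5 * sqrt(rowSums(cr^2))
}

#' Point cloud in millimetre coordinates
#'
#' @param points numeric matrix with 3 columns (mm).
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points) {
  points <- as.matrix(points)
  if (length(points) == 0) points <- matrix(numeric(0), ncol = 3)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (ncol(points) != 3) stop("points must have 3 columns")
  if (!all(is.finite(points))) stop("point coordinates must be finite")
  structure(list(points = points), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud: %d points>\n", nrow(x$points)))
  invisible(x)
}

#' Axis-aligned bounding box of a mesh or point cloud
#'
#' @param mesh a `triangle_mesh` or `point_cloud`.
#' @return List with `min` and `max` 3-vectors (mm).
#' @export
bounding_box <- function(mesh) {
  pts <- if (inherits(mesh, "point_cloud")) mesh$points else mesh$vertices
  if (nrow(pts) == 0) stop("empty geometry has no bounding box")
  list(min = unname(apply(pts, 2, min)), max = unname(apply(pts, 2, max)))
}

bbox_diagonal <- function(mesh) {
  bb <- bounding_box(mesh)
  sqrt(sum((bb$max - bb$min)^2))
}

#' Vertex adjacency list of a mesh
#'
#' @param mesh a `triangle_mesh`.
#' @return List of length `nrow(vertices)`; element `i` holds the sorted
#'   neighbour indices of vertex `i`. Symmetric by construction.
#' @export
mesh_adjacency <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) stop("mesh has no faces")
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  adj <- split(e[, 2], e[, 1])
  out <- vector("list", nrow(mesh$vertices))
  out[as.integer(names(adj))] <- lapply(adj, function(v) sort(unique(v)))
  for (i in seq_along(out)) if (is.null(out[[i]])) out[[i]] <- integer(0)
  out
}

# unique undirected edges as a 2-column matrix, i < j
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# boundary vertices: endpoints of edges adjacent to exactly one face
boundary_vertices <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1L]
  if (length(bkey) == 0) return(integer(0))
  idx <- do.call(rbind, strsplit(bkey, " "))
  sort(unique(as.integer(idx)))
}
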