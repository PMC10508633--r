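#' Discrete mean-curvature magnitude per vertex
#'
#' Cotangent-Laplacian estimate of the mean-curvature normal: for an interior
#' vertex i, `H_i = || sum_j (cot a_ij + cot b_ij) (v_j - v_i) || / (4 A_i)`
#' where the sum runs over the one-ring, `a_ij`, `b_ij` are the angles opposite
#' edge (i, j) and `A_i` is the barycentric vertex area (one third of the
#' incident face area). Only the magnitude is returned (units 1/mm) — the
#' fissure-line cost uses curvature *differences*, for which the sign is
#' irrelevant and the magnitude is rotation invariant.
#'
#' Boundary vertices (where the one-ring is open and the formula is biased)
#' are assigned the value of their nearest interior vertex.
#'
#' @param mesh a [triangle_mesh] with at least one face.
#' @return Numeric vector, one non-negative value per vertex (1/mm).
#' @export
vertex_curvature <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0) stop("vertex_curvature needs a mesh with faces")
  nv <- nrow(v)

  # accumulate cotangent weights and the Laplacian vector per vertex.
  # Every face contributes, for each of its three corners, the cotangent of
  # that corner angle to the two edges not touching the corner.
  lap <- matrix(0, nv, 3)
  area <- numeric(nv)
  corner <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  fa <- face_areas(v, f)
  for (k in 1:3) {
    area_add <- rowsum(rep(fa / 3, 1), f[, k], reorder = FALSE)
    area[as.integer(rownames(area_add))] <-
      area[as.integer(rownames(area_add))] + area_add
  }
  for (perm in corner) {
    i0 <- f[, perm[1]] # corner hosting the angle
    i1 <- f[, perm[2]]
    i2 <- f[, perm[3]]
    e1 <- v[i1, , drop = FALSE] - v[i0, , drop = FALSE]
    e2 <- v[i2, , drop = FALSE] - v[i0, , drop = FALSE]
    dot <- rowSums(e1 * e2)
    crs <- cbind(
      e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
      e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
      e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    )
    cot <- dot / pmax(sqrt(rowSums(crs^2)), 1e-30)
    # angle at i0 is opposite edge (i1, i2): add cot * (v_other - v_this)
    for (pair in list(c(2, 3), c(3, 2))) {
      a <- f[, perm[pair[1]]]
      b <- f[, perm[pair[2]]]
      contrib <- cot * (v[b, , drop = FALSE] - v[a, , drop = FALSE])
      for (d in 1:3) {
        s <- rowsum(contrib[, d], a, reorder = FALSE)
        lap[as.integer(rownames(s)), d] <- lap[as.integer(rownames(s)), d] + s
      }
    }
  }
  h <- sqrt(rowSums(lap^2)) / (4 * pmax(area, 1e-30))

  bnd <- boundary_vertices(mesh)
  if (length(bnd) > 0) {
    interior <- setdiff(seq_len(nv), bnd)
    if (length(interior) == 0) {
      # fully open patch: keep raw estimates rather than fail
      return(h)
    }
    # nearest interior vertex in Euclidean distance
    for (b in bnd) {
      d2 <- rowSums((v[interior, , drop = FALSE] -
                       matrix(v[b, ], length(interior), 3, byrow = TRUE))^2)
      h[b] <- h[interior[which.min(d2)]]
    }
  }
  h
}
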