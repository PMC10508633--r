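# Geometry fixtures shared across tests: all built in code, no data files.

# regular grid height-field mesh over [0, sx] x [0, sy]
grid_mesh <- function(g = 10, gy = g, sx = 1, sy = 1, z = function(x, y) 0 * x) {
  xs <- seq(0, sx, length.out = g)
  ys <- seq(0, sy, length.out = gy)
  gx <- rep(xs, times = gy)
  gyv <- rep(ys, each = g)
  v <- cbind(gx, gyv, z(gx, gyv))
  i <- rep(seq_len(g - 1), gy - 1)
  j <- rep(seq_len(gy - 1), each = g - 1)
  v00 <- i + (j - 1) * g
  f <- rbind(cbind(v00, v00 + 1, v00 + g + 1), cbind(v00, v00 + g + 1, v00 + g))
  triangle_mesh(v, f)
}

# icosphere by midpoint subdivision (subdiv 4 -> 2562 vertices)
icosphere <- function(subdiv = 3, radius = 1) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid <- new.env(parent = emptyenv())
    getmid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- mid[[key]]
      if (is.null(id)) {
        v <<- rbind(v, (v[i, ] + v[j, ]) / 2)
        id <- nrow(v)
        mid[[key]] <- id
      }
      id
    }
    nf <- vector("list", nrow(f))
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c_ <- f[k, 3]
      ab <- getmid(a, b); bc <- getmid(b, c_); ca <- getmid(c_, a)
      nf[[k]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- do.call(rbind, nf)
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  triangle_mesh(v, f)
}

# open cylinder barrel of given radius
cylinder_mesh <- function(radius = 2, height = 4, nth = 60, nz = 20) {
  th <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  zz <- seq(0, height, length.out = nz)
  v <- cbind(radius * cos(rep(th, nz)), radius * sin(rep(th, nz)),
             rep(zz, each = nth))
  idx <- function(i, j) i + (j - 1) * nth
  f <- vector("list", (nz - 1) * nth)
  k <- 0
  for (j in seq_len(nz - 1)) {
    for (i in seq_len(nth)) {
      i2 <- if (i == nth) 1 else i + 1
      k <- k + 1
      f[[k]] <- rbind(c(idx(i, j), idx(i2, j), idx(i2, j + 1)),
                      c(idx(i, j), idx(i2, j + 1), idx(i, j + 1)))
    }
  }
  triangle_mesh(v, do.call(rbind, f))
}

# small jittered grid mesh (4-12 vertices) for exhaustive path search
random_grid_mesh <- function(seed) {
  set.seed(seed)
  g <- sample(2:3, 1)
  g2 <- sample(2:4, 1)
  xs <- seq(0, 1, length.out = g)
  ys <- seq(0, 1, length.out = g2)
  v <- cbind(rep(xs, g2) + stats::runif(g * g2, -0.05, 0.05),
             rep(ys, each = g) + stats::runif(g * g2, -0.05, 0.05),
             stats::runif(g * g2, 0, 0.4))
  i <- rep(seq_len(g - 1), g2 - 1)
  j <- rep(seq_len(g2 - 1), each = g - 1)
  v00 <- i + (j - 1) * g
  f <- rbind(cbind(v00, v00 + 1, v00 + g + 1), cbind(v00, v00 + g + 1, v00 + g))
  triangle_mesh(v, f)
}

# exhaustive minimum-cost search over all simple paths; accumulates the same
# per-step costs as the package's search, in path order, independent of it
oracle_min_path <- function(mesh, start, goal, weights, curvature) {
  adj <- mesh_adjacency(mesh)
  norms <- occlugen:::fissure_normalizers(mesh, curvature)
  v <- mesh$vertices
  best <- list(cost = Inf, path = NULL)
  rec <- function(path, cost) {
    cur <- path[length(path)]
    if (cur == goal) {
      if (cost < best$cost) best <<- list(cost = cost, path = path)
      return(invisible(NULL))
    }
    prev <- if (length(path) >= 2) path[length(path) - 1] else NA_integer_
    for (nb in adj[[cur]]) {
      if (nb %in% path) next
      c1 <- occlugen:::step_cost_impl(v, curvature, weights, norms,
                                      prev, cur, nb, start, goal)
      rec(c(path, nb), cost + c1)
    }
  }
  rec(start, 0)
  best
}

# tiny in-memory training manifest at a given resolution
make_tiny_dataset <- function(n, seed, res = 32, dir = tempfile("ds")) {
  generate_dataset(n, seed, dir,
                   config = projection_config(resolution = res),
                   grid_resolution = max(res, 32))
}
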