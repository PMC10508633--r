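#' Parametric specification of a synthetic molar-like crown
#'
#' The synthetic occlusal surface is a height field
#' `z(x, y) = dome + sum of cusp Gaussians - groove trench`:
#' a smooth dome carrying `k` Gaussian cusps arranged around the crown centre,
#' cut by a trench of given depth and width that follows the groove skeleton
#' (an ordered 2-D polyline through the saddle regions between cusps — here a
#' closed central-fissure loop). Dimensions are millimetres; a typical molar
#' crown is ~9 mm across with 1-2 mm of occlusal relief.
#'
#' @param n_cusps number of cusps (3-5 for molar-like anatomy).
#' @param cusp_centers `k x 2` matrix of cusp apex positions (mm).
#' @param cusp_heights,cusp_widths cusp amplitudes and Gaussian sigmas (mm).
#' @param groove_skeleton ordered 2-column polyline (mm); closed if first and
#'   last rows coincide.
#' @param groove_depth trench depth at the skeleton (mm).
#' @param groove_width trench half-width (Gaussian sigma, mm).
#' @param dome_height height of the base dome (mm).
#' @param crown_radius half-extent of the square crown footprint (mm).
#' @param grid_resolution vertices per side of the triangulated grid.
#' @param seed integer recorded for provenance.
#' @return An object of class `tooth_spec`.
#' @export
tooth_spec <- function(n_cusps, cusp_centers, cusp_heights, cusp_widths,
                       groove_skeleton, groove_depth = 0.8, groove_width = 0.7,
                       dome_height = 2.0, crown_radius = 4.5,
                       grid_resolution = 128, seed = 0L) {
  if (n_cusps > 0) {
    cusp_centers <- matrix(cusp_centers, ncol = 2)
    stopifnot(nrow(cusp_centers) == n_cusps,
              length(cusp_heights) == n_cusps,
              length(cusp_widths) == n_cusps)
    if (any(cusp_widths <= 0)) stop("cusp widths must be positive")
  } else {
    cusp_centers <- matrix(numeric(0), ncol = 2)
    cusp_heights <- numeric(0)
    cusp_widths <- numeric(0)
  }
  if (!is.null(groove_skeleton)) {
    groove_skeleton <- matrix(groove_skeleton, ncol = 2)
    if (max(abs(groove_skeleton)) > crown_radius) {
      stop("groove skeleton must lie inside the crown footprint")
    }
  }
  if (groove_depth < 0) stop("groove depth must be >= 0")
  if (n_cusps > 0 && any(cusp_heights <= 0)) stop("cusp heights must be positive")
  structure(list(n_cusps = as.integer(n_cusps), cusp_centers = cusp_centers,
                 cusp_heights = cusp_heights, cusp_widths = cusp_widths,
                 groove_skeleton = groove_skeleton,
                 groove_depth = groove_depth, groove_width = groove_width,
                 dome_height = dome_height, crown_radius = crown_radius,
                 grid_resolution = as.integer(grid_resolution),
                 seed = as.integer(seed)),
            class = "tooth_spec")
}

#' Randomized molar-like tooth specification
#'
#' Draws a crown with 3-5 cusps spaced around the crown centre with angular
#' jitter, cusp heights of 1.0-1.8 mm over a 2 mm dome, and a closed central
#' groove loop through the inter-cusp saddles, 0.6-1.0 mm deep. The caller's
#' RNG state is left untouched.
#'
#' @param seed integer seed; the spec is a deterministic function of it.
#' @param grid_resolution vertices per side of the generated mesh grid.
#' @return A [tooth_spec].
#' @export
random_tooth_spec <- function(seed, grid_resolution = 128) {
  with_preserved_seed(seed, {
    k <- sample(3:5, 1)
    r_crown <- stats::runif(1, 4.0, 5.0)
    ang <- sort(2 * pi * (seq_len(k) - 1) / k +
                  stats::runif(k, -0.25, 0.25) + stats::runif(1, 0, 2 * pi / k))
    r_cusp <- stats::runif(k, 0.45, 0.6) * r_crown
    centers <- cbind(r_cusp * cos(ang), r_cusp * sin(ang))
    heights <- stats::runif(k, 1.0, 1.8)
    widths <- stats::runif(k, 1.2, 1.9)
    # closed central-fissure loop through the saddles between adjacent cusps
    sad_ang <- (ang + c(ang[-1], ang[1] + 2 * pi)) / 2
    r_groove <- stats::runif(1, 0.3, 0.4) * r_crown
    skel <- cbind(r_groove * cos(sad_ang), r_groove * sin(sad_ang))
    skel <- rbind(skel, skel[1, , drop = FALSE])
    tooth_spec(
      n_cusps = k, cusp_centers = centers, cusp_heights = heights,
      cusp_widths = widths, groove_skeleton = skel,
      groove_depth = stats::runif(1, 0.6, 1.0),
      groove_width = stats::runif(1, 0.5, 0.9),
      dome_height = 2.0, crown_radius = r_crown,
      grid_resolution = grid_resolution, seed = seed
    )
  })
}

# run expr under a fixed seed, restoring the caller's RNG state afterwards
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# minimum distance from points (n x 2) to a polyline (m x 2)
dist_to_polyline <- function(pts, poly) {
  d2 <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(poly) - 1)) {
    a <- poly[s, ]
    b <- poly[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 < 1e-30) next
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

#' Closed-form height field of a synthetic crown
#'
#' Evaluates the generator's height field at arbitrary planar positions —
#' the same function [generate_tooth_mesh()] samples on its grid, exposed so
#' that projections and extracted curves can be checked against ground truth.
#'
#' @param spec a [tooth_spec].
#' @param x,y planar coordinates (mm), recycled to a common length.
#' @return Heights z in mm.
#' @export
tooth_height_field <- function(spec, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n)
  y <- rep_len(y, n)
  r2 <- x^2 + y^2
  # wide Gaussian dome over the footprint
  z <- spec$dome_height * exp(-r2 / (2 * (0.9 * spec$crown_radius)^2))
  if (spec$n_cusps > 0) {
    for (i in seq_len(spec$n_cusps)) {
      d2 <- (x - spec$cusp_centers[i, 1])^2 + (y - spec$cusp_centers[i, 2])^2
      z <- z + spec$cusp_heights[i] * exp(-d2 / (2 * spec$cusp_widths[i]^2))
    }
  }
  if (!is.null(spec$groove_skeleton) && spec$groove_depth > 0) {
    dg <- dist_to_polyline(cbind(x, y), spec$groove_skeleton)
    z <- z - spec$groove_depth * exp(-dg^2 / (2 * spec$groove_width^2))
  }
  z
}

#' Generate a synthetic molar-like crown mesh
#'
#' Samples the spec's height field on a regular `grid_resolution` square grid
#' over the crown footprint and triangulates it (two triangles per cell).
#' Fully deterministic for a given spec.
#'
#' @param spec a [tooth_spec].
#' @return A [triangle_mesh] with the occlusal surface facing +Z.
#' @export
generate_tooth_mesh <- function(spec) {
  stopifnot(inherits(spec, "tooth_spec"))
  g <- spec$grid_resolution
  if (g < 2) stop("grid resolution must be at least 2")
  r <- spec$crown_radius
  xs <- seq(-r, r, length.out = g)
  ys <- seq(-r, r, length.out = g)
  gx <- rep(xs, times = g)
  gy <- rep(ys, each = g)
  z <- tooth_height_field(spec, gx, gy)
  verts <- cbind(gx, gy, z)
  # grid triangulation: vertex (i, j) at index i + (j-1)*g
  i <- rep(seq_len(g - 1), times = g - 1)
  j <- rep(seq_len(g - 1), each = g - 1)
  v00 <- i + (j - 1) * g
  v10 <- v00 + 1L
  v01 <- v00 + g
  v11 <- v01 + 1L
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  triangle_mesh(verts, faces)
}

#' Generate the opposing (antagonist) surface of a crown
#'
#' Mirrors the crown in z and offsets it so that the minimum vertical gap
#' between the two surfaces equals `clearance` — a geometric stand-in for the
#' jaw-space constraint the opposing tooth imposes. Applying the operation
#' twice recovers the original surface up to a vertical translation.
#'
#' @param mesh a [triangle_mesh] (height-field-like, occlusal side +Z).
#' @param clearance minimum inter-surface gap in mm (>= 0).
#' @return A [triangle_mesh] of the opposing surface.
#' @export
generate_opposing_mesh <- function(mesh, clearance = 0.5) {
  if (clearance < 0) stop("clearance must be >= 0")
  zmax <- max(mesh$vertices[, 3])
  a <- 2 * zmax + clearance
  verts <- mesh$vertices
  verts[, 3] <- a - verts[, 3]
  # flip face orientation so outward normals stay outward after mirroring
  faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  triangle_mesh(verts, faces)
}

#' Paired training triplet (mask, opposing, target)
#'
#' @param x mask [depth_image] of the "missing" tooth (occlusal region
#'   suppressed to 0).
#' @param op [depth_image] of the opposing surface on the same planar raster.
#' @param y target [depth_image]: the projection restricted to the fissure
#'   band, 0 elsewhere.
#' @return An object of class `sample_triplet`.
#' @export
sample_triplet <- function(x, op, y) {
  stopifnot(inherits(x, "depth_image"), inherits(op, "depth_image"),
            inherits(y, "depth_image"))
  if (!all(dim(x) == dim(op)) || !all(dim(x) == dim(y))) {
    stop("triplet images must share one resolution")
  }
  structure(list(x = x, op = op, y = y), class = "sample_triplet")
}

#' Build a (mask, opposing, target) triplet from a crown and its antagonist
#'
#' Projects the crown, suppresses a circular occlusal region centred on the
#' crown footprint centroid to obtain the "missing tooth" mask image, projects
#' the opposing surface on the same planar raster (with its own projection
#' plane), and restricts the crown projection to the groove band — pixels
#' whose centres lie within `spec$groove_width` of the groove skeleton — to
#' obtain the target pit/fissure image.
#'
#' @param mesh crown [triangle_mesh].
#' @param opposing its antagonist, e.g. from [generate_opposing_mesh()].
#' @param config a [projection_config] shared by the three images.
#' @param spec the [tooth_spec] that generated `mesh` (provides the skeleton).
#' @param mask_radius radius (mm) of the suppressed disk; default 55% of the
#'   crown radius.
#' @return A [sample_triplet].
#' @export
build_triplet <- function(mesh, opposing, config = projection_config(),
                          spec, mask_radius = NULL) {
  stopifnot(inherits(spec, "tooth_spec"))
  full <- project_mesh(mesh, config)
  cfg <- attr(full, "config")
  if (is.null(mask_radius)) mask_radius <- 0.55 * spec$crown_radius

  res <- cfg$resolution
  px <- cfg$origin[1] + (seq_len(res) - 1) * cfg$spacing   # column x
  py <- cfg$origin[2] - (seq_len(res) - 1) * cfg$spacing   # row y
  PX <- matrix(px, res, res, byrow = TRUE)
  PY <- matrix(py, res, res)

  cen <- colMeans(mesh$vertices[, 1:2, drop = FALSE])
  xpix <- unclass(full)
  xpix[(PX - cen[1])^2 + (PY - cen[2])^2 <= mask_radius^2] <- 0L
  x_img <- depth_image(xpix, cfg)

  # antagonist on the same planar raster, projection plane above itself
  cfg_op <- cfg
  cfg_op$plane_z <- NULL
  op_img <- project_mesh(opposing, cfg_op)

  ypix <- unclass(full)
  if (is.null(spec$groove_skeleton)) {
    ypix[] <- 0L
  } else {
    dg <- dist_to_polyline(cbind(as.vector(PX), as.vector(PY)),
                           spec$groove_skeleton)
    ypix[matrix(dg, res, res) > spec$groove_width] <- 0L
  }
  y_img <- depth_image(ypix, cfg)
  sample_triplet(x_img, op_img, y_img)
}

#' Generate a synthetic training dataset on disk
#'
#' Draws `n_samples` randomized crowns, builds their (mask, opposing, target)
#' triplets, writes each image as 8-bit PNG with a JSON metadata sidecar, and
#' records a JSON-lines manifest. The first 75% of samples form the training
#' split and the remainder the test split, so 400 samples yield the canonical
#' 300/100 partition. Byte-identical across runs with the same seed.
#'
#' @param n_samples number of triplets (>= 1).
#' @param seed integer master seed; per-sample seeds are derived from it.
#' @param outdir output directory, created if needed.
#' @param config a [projection_config] (its resolution sets the image size).
#' @param grid_resolution mesh grid vertices per side.
#' @param clearance antagonist gap in mm.
#' @return Tibble manifest (id, role, x_path, op_path, y_path, seed),
#'   also written to `manifest.jsonl` in `outdir`.
#' @export
generate_dataset <- function(n_samples, seed, outdir,
                             config = projection_config(),
                             grid_resolution = 128, clearance = 0.5) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  n_train <- round(0.75 * n_samples)
  rows <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    s_i <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    spec <- random_tooth_spec(s_i, grid_resolution = grid_resolution)
    mesh <- generate_tooth_mesh(spec)
    opp <- generate_opposing_mesh(mesh, clearance = clearance)
    tri <- build_triplet(mesh, opp, config, spec)
    id <- sprintf("sample%04d", i)
    paths <- file.path(outdir, paste0(id, c("_x.png", "_op.png", "_y.png")))
    write_depth_image(tri$x, paths[1])
    write_depth_image(tri$op, paths[2])
    write_depth_image(tri$y, paths[3])
    rows[[i]] <- tibble::tibble(
      id = id, role = if (i <= n_train) "train" else "test",
      x_path = paths[1], op_path = paths[2], y_path = paths[3], seed = s_i
    )
  }
  manifest <- do.call(rbind, rows)
  con <- file(file.path(outdir, "manifest.jsonl"), "w")
  for (i in seq_len(nrow(manifest))) {
    writeLines(jsonlite::toJSON(as.list(manifest[i, ]), auto_unbox = TRUE), con)
  }
  close(con)
  manifest
}

#' Read a JSON-lines dataset manifest
#'
#' @param path `manifest.jsonl` path or the directory containing it.
#' @return Tibble with one row per sample.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.jsonl")
  if (!file.exists(path)) stop("no manifest at ", path)
  rows <- lapply(readLines(path, warn = FALSE), function(l) {
    tibble::as_tibble(jsonlite::fromJSON(l))
  })
  do.call(rbind, rows)
}
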