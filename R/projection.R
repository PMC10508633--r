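#' Orthographic depth-projection configuration
#'
#' The occlusal surface is viewed along -Z from a projection plane placed
#' `gamma` mm above the mesh top. Vertical distance `d` from the plane to the
#' surface maps to an 8-bit pixel via `255 - 255 * (d / h)^n`: `h` is the
#' limit-plane distance beyond which pixels are 0, and the enhancement
#' exponent `n` redistributes grey levels (its default 1.4 maximizes the
#' image entropy of molar depth maps).
#'
#' Grid placement (`origin`, `spacing`, `plane_z`) is normally derived from
#' the mesh bounding box — a square grid centred on the box with a 5% margin —
#' but can be fixed explicitly, e.g. to project a tooth and its antagonist on
#' a common raster.
#'
#' @param resolution pixels per image side (default 256).
#' @param h limit-plane distance in mm (default 6.5).
#' @param n enhancement exponent, dimensionless (default 1.4).
#' @param gamma height of the projection plane above the mesh top, mm.
#' @param origin optional `c(x, y)` of the centre of pixel (1, 1)
#'   (top-left: minimum x, maximum y).
#' @param spacing optional pixel size in mm/pixel.
#' @param plane_z optional absolute z of the projection plane, mm.
#' @param margin fractional margin around the bounding box (default 0.05).
#' @return An object of class `projection_config`.
#' @export
projection_config <- function(resolution = 256, h = 6.5, n = 1.4, gamma = 1.0,
                              origin = NULL, spacing = NULL, plane_z = NULL,
                              margin = 0.05) {
  if (h <= 0) stop("h must be positive")
  if (n <= 0) stop("n must be positive")
  if (resolution < 2) stop("resolution must be at least 2")
  if (!is.null(spacing) && spacing <= 0) stop("spacing must be positive")
  structure(list(resolution = as.integer(resolution), h = h, n = n,
                 gamma = gamma, origin = origin, spacing = spacing,
                 plane_z = plane_z, margin = margin),
            class = "projection_config")
}

round_half_up <- function(x) floor(x + 0.5)

#' Map plane-to-surface distance to an 8-bit pixel value
#'
#' `pixel = round(255 - 255 * (d / h)^n)`, clamped to `[0, 255]`; distances
#' beyond the limit plane (`d > h`) give 0. Monotonically non-increasing in
#' `d`.
#'
#' @param d vertical distance(s) from the projection plane, mm; must be >= 0.
#' @param h limit-plane distance, mm.
#' @param n enhancement exponent.
#' @return Integer pixel value(s) in `[0, 255]`.
#' @export
pixel_from_distance <- function(d, h = 6.5, n = 1.4) {
  if (any(d < 0)) stop("distance must be non-negative")
  p <- round_half_up(255 - 255 * (d / h)^n)
  p <- pmin(pmax(p, 0), 255)
  p[d > h] <- 0
  as.integer(p)
}

#' Invert the depth-to-pixel mapping
#'
#' `d = h * (1 - p / 255)^(1 / n)` — the exact inverse of the unrounded pixel
#' mapping, used to turn generated pit/fissure images back into 3-D points.
#'
#' @param p pixel value(s) in `[0, 255]`.
#' @inheritParams pixel_from_distance
#' @return Distance(s) in mm.
#' @export
distance_from_pixel <- function(p, h = 6.5, n = 1.4) {
  if (any(p < 0 | p > 255)) stop("pixel values must lie in [0, 255]")
  h * (1 - p / 255)^(1 / n)
}

#' 8-bit depth image with projection metadata
#'
#' @param pixels integer matrix, values in `[0, 255]`; row 1 is the top of
#'   the image (maximum y).
#' @param config the [projection_config] used, with `origin`, `spacing` and
#'   `plane_z` resolved (required for back-projection).
#' @return An object of class `depth_image` (an integer matrix with a
#'   `config` attribute).
#' @export
depth_image <- function(pixels, config) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  if (any(pixels < 0 | pixels > 255)) stop("pixel values must lie in [0, 255]")
  structure(pixels, config = config, class = c("depth_image", "matrix", "array"))
}

#' @export
print.depth_image <- function(x, ...) {
  cat(sprintf("<depth_image %dx%d, range [%d, %d]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

# resolve grid placement for a given mesh: square raster, 5% margin,
# plane gamma above the top
resolve_grid <- function(mesh, config) {
  bb <- bounding_box(mesh)
  res <- config$resolution
  if (is.null(config$spacing)) {
    extent <- max(bb$max[1] - bb$min[1], bb$max[2] - bb$min[2]) *
      (1 + config$margin)
    spacing <- extent / res
  } else {
    spacing <- config$spacing
    extent <- spacing * res
  }
  if (is.null(config$origin)) {
    cx <- (bb$min[1] + bb$max[1]) / 2
    cy <- (bb$min[2] + bb$max[2]) / 2
    origin <- c(cx - extent / 2 + spacing / 2,   # x of pixel column 1
                cy + extent / 2 - spacing / 2)   # y of pixel row 1 (top)
  } else {
    origin <- config$origin
  }
  plane_z <- config$plane_z %||% (bb$max[3] + config$gamma)
  config$spacing <- spacing
  config$origin <- origin
  config$plane_z <- plane_z
  config
}

#' Project a mesh to a depth image
#'
#' Casts one -Z ray per pixel centre from the projection plane and keeps the
#' nearest surface intersection (the visible occlusal surface). Pixels whose
#' ray misses the mesh, or whose distance exceeds the limit plane `h`, are 0.
#'
#' @param mesh a [triangle_mesh] with its occlusal side facing +Z.
#' @param config a [projection_config].
#' @param raw also attach the unquantized distance matrix (mm, `NA` where the
#'   ray misses) as attribute `"distances"`; used for error analysis.
#' @return A [depth_image] whose `config` attribute has the resolved grid.
#' @export
project_mesh <- function(mesh, config = projection_config(), raw = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0) stop("cannot project a mesh without faces")
  config <- resolve_grid(mesh, config)
  res <- config$resolution
  sp <- config$spacing
  x0 <- config$origin[1]
  y0 <- config$origin[2]
  # z-buffer of surface heights (max z wins = nearest to the plane above)
  zbuf <- matrix(-Inf, res, res)
  v <- mesh$vertices
  f <- mesh$faces
  ax <- v[f[, 1], 1]; ay <- v[f[, 1], 2]; az <- v[f[, 1], 3]
  bx <- v[f[, 2], 1]; by <- v[f[, 2], 2]; bz <- v[f[, 2], 3]
  cx <- v[f[, 3], 1]; cy <- v[f[, 3], 2]; cz <- v[f[, 3], 3]
  # pixel index ranges per face (columns from x, rows from y downwards)
  jmin <- pmax(floor((pmin(ax, bx, cx) - x0) / sp) + 1, 1)
  jmax <- pmin(ceiling((pmax(ax, bx, cx) - x0) / sp) + 1, res)
  imin <- pmax(floor((y0 - pmax(ay, by, cy)) / sp) + 1, 1)
  imax <- pmin(ceiling((y0 - pmin(ay, by, cy)) / sp) + 1, res)
  denom <- (by - cy) * (ax - cx) + (cx - bx) * (ay - cy)
  eps <- 1e-12
  for (t in seq_len(nrow(f))) {
    if (jmin[t] > jmax[t] || imin[t] > imax[t]) next
    dn <- denom[t]
    if (abs(dn) < eps) next  # degenerate in projection
    jj <- jmin[t]:jmax[t]
    ii <- imin[t]:imax[t]
    px <- x0 + (jj - 1) * sp
    py <- y0 - (ii - 1) * sp
    # barycentric coordinates on the pixel-centre lattice patch
    PX <- matrix(px, length(ii), length(jj), byrow = TRUE)
    PY <- matrix(py, length(ii), length(jj))
    l1 <- ((by[t] - cy[t]) * (PX - cx[t]) + (cx[t] - bx[t]) * (PY - cy[t])) / dn
    l2 <- ((cy[t] - ay[t]) * (PX - cx[t]) + (ax[t] - cx[t]) * (PY - cy[t])) / dn
    l3 <- 1 - l1 - l2
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    if (!any(inside)) next
    z <- l1 * az[t] + l2 * bz[t] + l3 * cz[t]
    sub <- zbuf[ii, jj, drop = FALSE]
    upd <- inside & z > sub
    sub[upd] <- z[upd]
    zbuf[ii, jj] <- sub
  }
  d <- config$plane_z - zbuf            # Inf where no hit
  hit <- is.finite(d) & d >= 0 & d <= config$h
  px <- matrix(0L, res, res)
  px[hit] <- pixel_from_distance(d[hit], config$h, config$n)
  img <- depth_image(px, config)
  if (raw) {
    d[!is.finite(d)] <- NA_real_
    attr(img, "distances") <- d
  }
  img
}

#' Back-project a depth image to a 3-D point cloud
#'
#' Inverts the projection: every nonzero pixel becomes one point at its pixel
#' centre `(x, y)` with `z = plane_z - distance_from_pixel(p)`. Zero pixels
#' (background / beyond the limit plane) emit no point.
#'
#' @param img a [depth_image] with resolved grid metadata.
#' @return A [point_cloud].
#' @export
backproject <- function(img) {
  cfg <- attr(img, "config")
  if (is.null(cfg) || is.null(cfg$origin) || is.null(cfg$spacing) ||
      is.null(cfg$plane_z)) {
    stop("depth image lacks projection metadata; cannot back-project")
  }
  idx <- which(img != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0) return(point_cloud(matrix(numeric(0), ncol = 3)))
  x <- cfg$origin[1] + (idx[, 2] - 1) * cfg$spacing
  y <- cfg$origin[2] - (idx[, 1] - 1) * cfg$spacing
  d <- distance_from_pixel(img[idx], cfg$h, cfg$n)
  point_cloud(cbind(x, y, cfg$plane_z - d))
}

#' Shannon entropy of an 8-bit image
#'
#' `E = -sum_i P(i) log2 P(i)` over grey levels 0-255, with `0 log 0 := 0`.
#' Bounded by 0 (constant image) and 8 bits (uniform histogram).
#'
#' @param img integer matrix of values in `[0, 255]`.
#' @return Entropy in bits.
#' @export
image_entropy <- function(img) {
  if (length(img) == 0) stop("empty image has no entropy")
  p <- tabulate(as.integer(img) + 1L, nbins = 256)
  p <- p / sum(p)
  p <- p[p > 0]
  e <- -sum(p * log2(p))
  if (e == 0) e <- 0   # normalize negative zero
  e
}

#' Choose the enhancement exponent by entropy maximization
#'
#' Projects each mesh at every candidate exponent, averages the image entropy
#' across meshes, and returns the candidate with the highest mean entropy
#' (smallest candidate on ties). The full curve is returned for inspection;
#' on molar-like surfaces it rises and then falls with `n`.
#'
#' @param meshes list of [triangle_mesh] objects.
#' @param candidate_ns positive numeric grid of candidate exponents.
#' @param config base [projection_config]; its `n` is overridden per candidate.
#' @return List with `n` (selected exponent) and `curve`
#'   (tibble of `n`, `entropy`).
#' @export
select_enhancement <- function(meshes, candidate_ns = seq(0.2, 3.0, by = 0.2),
                               config = projection_config()) {
  if (length(meshes) == 0) stop("need at least one mesh")
  if (length(candidate_ns) == 0 || any(candidate_ns <= 0)) {
    stop("candidate exponents must be positive")
  }
  mean_e <- vapply(candidate_ns, function(nn) {
    cfg <- config
    cfg$n <- nn
    mean(vapply(meshes, function(m) image_entropy(project_mesh(m, cfg)), 0))
  }, 0)
  best <- which(mean_e == max(mean_e))[1]   # smallest candidate among maxima
  list(n = candidate_ns[best],
       curve = tibble::tibble(n = candidate_ns, entropy = mean_e))
}

#' Write a depth image as 8-bit PNG plus a JSON metadata sidecar
#'
#' @param img a [depth_image].
#' @param path output PNG path; metadata goes to the same path with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_depth_image <- function(img, path) {
  png::writePNG(unclass(img) / 255, path)
  cfg <- attr(img, "config")
  meta <- list(resolution = cfg$resolution, h = cfg$h, n = cfg$n,
               gamma = cfg$gamma, origin = cfg$origin, spacing = cfg$spacing,
               plane_z = cfg$plane_z)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Read a depth image written by [write_depth_image()]
#'
#' @param path PNG path; the JSON sidecar is read from the matching `.json`
#'   path when present.
#' @return A [depth_image] (metadata-free if no sidecar exists).
#' @export
read_depth_image <- function(path) {
  if (!file.exists(path)) stop("cannot read depth image: no such file: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  px <- round_half_up(a * 255)
  cfg <- NULL
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    m <- jsonlite::read_json(sc, simplifyVector = TRUE)
    cfg <- projection_config(resolution = m$resolution, h = m$h, n = m$n,
                             gamma = m$gamma, origin = m$origin,
                             spacing = m$spacing, plane_z = m$plane_z)
  }
  depth_image(px, cfg)
}
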