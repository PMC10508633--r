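#' Stabilization constants of the structural similarity index
#'
#' @param c1,c2 positive constants on the 0-255 pixel scale (defaults 6.5
#'   and 58.5).
#' @return An object of class `ssim_params`.
#' @export
ssim_params <- function(c1 = 6.5, c2 = 58.5) {
  if (c1 <= 0 || c2 <= 0) stop("SSIM constants must be positive")
  structure(list(c1 = c1, c2 = c2), class = "ssim_params")
}

check_same_dim <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) {
    stop("image dimensions differ: ", paste(dim(x), collapse = "x"), " vs ",
         paste(dim(y), collapse = "x"))
  }
  list(x = x, y = y)
}

#' Mean squared error between two images
#'
#' @param x,y numeric matrices of equal dimension (0-255 scale).
#' @return `(1/mn) * sum((x - y)^2)`.
#' @export
mse <- function(x, y) {
  p <- check_same_dim(x, y)
  mean((p$x - p$y)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(255^2 / MSE)`; identical images give `Inf`.
#'
#' @inheritParams mse
#' @param max_value peak pixel value (255 for 8-bit images).
#' @return PSNR in dB (`Inf` when MSE is 0).
#' @export
psnr <- function(x, y, max_value = 255) {
  m <- mse(x, y)
  if (m == 0) return(Inf)
  10 * log10(max_value^2 / m)
}

#' Structural similarity index (global statistics)
#'
#' `SSIM = (2 mu_x mu_y + c1)(2 s_xy + c2) /
#'   ((mu_x^2 + mu_y^2 + c1)(s_x^2 + s_y^2 + c2))`
#' computed from the means, variances and covariance of the whole image
#' (one value per pair — no sliding window), using population (1/n) moments.
#' Symmetric in its arguments; equals 1 exactly when the images are identical.
#'
#' @inheritParams mse
#' @param params a [ssim_params].
#' @return SSIM value in `[-1, 1]`.
#' @export
ssim <- function(x, y, params = ssim_params()) {
  p <- check_same_dim(x, y)
  n <- length(p$x)
  mx <- mean(p$x)
  my <- mean(p$y)
  vx <- mean(p$x^2) - mx^2
  vy <- mean(p$y^2) - my^2
  cxy <- mean(p$x * p$y) - mx * my
  ((2 * mx * my + params$c1) * (2 * cxy + params$c2)) /
    ((mx^2 + my^2 + params$c1) * (vx + vy + params$c2))
}

#' Image-quality report for one generated/target pair
#'
#' @param generated,target file paths of 8-bit PNG images, or matrices /
#'   [depth_image] objects on the 0-255 scale.
#' @param params a [ssim_params].
#' @return Tibble with one row: `mse`, `psnr_db`, `ssim`.
#' @export
evaluate_pair <- function(generated, target, params = ssim_params()) {
  g <- if (is.character(generated)) read_depth_image(generated) else generated
  t_ <- if (is.character(target)) read_depth_image(target) else target
  tibble::tibble(mse = mse(g, t_), psnr_db = psnr(g, t_),
                 ssim = ssim(g, t_, params))
}

#' Batch image-quality evaluation
#'
#' @param pairs data frame with columns `generated` and `target` (paths),
#'   optionally `id`.
#' @param csv optional output CSV path (columns id, mse, psnr_db, ssim;
#'   infinite PSNR serialized as `"inf"`).
#' @inheritParams evaluate_pair
#' @return Tibble with one row per pair.
#' @export
evaluate_batch <- function(pairs, csv = NULL, params = ssim_params()) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- evaluate_pair(pairs$generated[i], pairs$target[i], params)
    tibble::tibble(id = if ("id" %in% names(pairs)) pairs$id[i] else
      as.character(i), r)
  })
  out <- do.call(rbind, rows)
  if (!is.null(csv)) {
    ser <- out
    ser$psnr_db <- ifelse(is.infinite(ser$psnr_db), "inf",
                          format(ser$psnr_db, digits = 10))
    utils::write.csv(ser, csv, row.names = FALSE, quote = FALSE)
  }
  out
}

# signed nearest-surface distance from points (n x 3) to a mesh: magnitude of
# the exact point-to-triangle distance, minimized over faces; the sign is the
# side of the nearest face (its normal direction). Vectorized over points,
# looped over faces.
point_mesh_distance <- function(pts, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0) stop("reference mesh has no faces")
  np <- nrow(pts)
  best <- rep(Inf, np)
  best_sign <- rep(1, np)
  seg_dist <- function(px, py, pz, a, dir) {
    len2 <- max(sum(dir^2), 1e-30)
    t <- ((px - a[1]) * dir[1] + (py - a[2]) * dir[2] + (pz - a[3]) * dir[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    sqrt((px - a[1] - t * dir[1])^2 + (py - a[2] - t * dir[2])^2 +
           (pz - a[3] - t * dir[3])^2)
  }
  for (t in seq_len(nrow(f))) {
    a <- v[f[t, 1], ]
    b <- v[f[t, 2], ]
    c_ <- v[f[t, 3], ]
    ab <- b - a
    ac <- c_ - a
    nrm <- c(ab[2] * ac[3] - ab[3] * ac[2],
             ab[3] * ac[1] - ab[1] * ac[3],
             ab[1] * ac[2] - ab[2] * ac[1])
    nlen <- sqrt(sum(nrm^2))
    if (nlen < 1e-30) next
    nrm <- nrm / nlen
    apx <- pts[, 1] - a[1]
    apy <- pts[, 2] - a[2]
    apz <- pts[, 3] - a[3]
    h <- apx * nrm[1] + apy * nrm[2] + apz * nrm[3]   # signed plane distance
    # barycentric coordinates of the in-plane projection
    d00 <- sum(ab * ab); d01 <- sum(ab * ac); d11 <- sum(ac * ac)
    d20 <- apx * ab[1] + apy * ab[2] + apz * ab[3]
    d21 <- apx * ac[1] + apy * ac[2] + apz * ac[3]
    denom <- d00 * d11 - d01 * d01
    vb <- (d11 * d20 - d01 * d21) / denom
    wb <- (d00 * d21 - d01 * d20) / denom
    inside <- vb >= 0 & wb >= 0 & (vb + wb) <= 1
    d_edge <- pmin(seg_dist(pts[, 1], pts[, 2], pts[, 3], a, ab),
                   seg_dist(pts[, 1], pts[, 2], pts[, 3], a, ac),
                   seg_dist(pts[, 1], pts[, 2], pts[, 3], b, c_ - b))
    di <- ifelse(inside, abs(h), d_edge)
    upd <- di < best
    if (any(upd)) {
      best[upd] <- di[upd]
      best_sign[upd] <- ifelse(h[upd] >= 0, 1, -1)
    }
  }
  best * best_sign
}

#' Surface-deviation statistics of a point cloud against a reference mesh
#'
#' Computes the signed nearest-point distance of every cloud point to the
#' reference surface (sign = side of the nearest face) and summarizes it by
#' its standard deviation and the root-mean-square error `sqrt(mean(d^2))`
#' (both mm). The two measure different moments: a constant offset gives
#' RMSE equal to the offset but SD zero.
#'
#' @param cloud a [point_cloud].
#' @param reference a [triangle_mesh].
#' @return List of class `deviation_report`: `distances`, `sd`, `rmse`, `n`.
#' @export
surface_deviation <- function(cloud, reference) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(reference, "triangle_mesh"))
  if (nrow(cloud$points) == 0) stop("empty point cloud")
  d <- point_mesh_distance(cloud$points, reference)
  structure(list(distances = d, sd = stats::sd(d),
                 rmse = sqrt(mean(d^2)), n = length(d)),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("<deviation_report: n = %d, SD = %.4f mm, RMSE = %.4f mm>\n",
              x$n, x$sd, x$rmse))
  invisible(x)
}
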