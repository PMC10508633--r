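test_that("distance-to-pixel mapping matches its closed form", {
  expect_identical(pixel_from_distance(0), 255L)
  expect_identical(pixel_from_distance(6.5), 0L)
  # d = h/2 at n = 1.4: round(255 - 255 * 0.5^1.4) = 158
  expect_identical(pixel_from_distance(3.25, 6.5, 1.4), 158L)
  expect_identical(pixel_from_distance(10, 6.5), 0L)  # beyond the limit plane
  expect_error(pixel_from_distance(-0.1), "non-negative")
  expect_error(distance_from_pixel(300), "\\[0, 255\\]")
  expect_identical(distance_from_pixel(255), 0)
  expect_identical(distance_from_pixel(0, h = 6.5), 6.5)
})

test_that("pixel mapping is monotone and inverts exactly on all 256 levels", {
  expect_identical(pixel_from_distance(distance_from_pixel(0:255)), 0:255)
  set.seed(99)
  for (i in 1:10) {
    h <- stats::runif(1, 1, 12)
    n <- stats::runif(1, 0.3, 3)
    expect_identical(pixel_from_distance(distance_from_pixel(0:255, h, n), h, n),
                     0:255)
  }
  d <- seq(0, 6.5, length.out = 200)
  expect_true(all(diff(pixel_from_distance(d)) <= 0))
})

test_that("projection of a constant-height surface is a constant image", {
  flat <- grid_mesh(12, 12, sx = 10, sy = 10, z = function(x, y) 2 + 0 * x)
  img <- project_mesh(flat, projection_config(resolution = 32, gamma = 1))
  inside <- img[3:30, 3:30]   # avoid the 5% margin ring
  expect_equal(length(unique(as.vector(inside))), 1)
  # plane sits gamma above the surface -> d = 1 everywhere on the crown
  expect_identical(inside[1, 1], pixel_from_distance(1))
})

test_that("surfaces beyond the limit-plane window project to zero", {
  flat <- grid_mesh(8, 8, sx = 10, sy = 10, z = function(x, y) 0 * x)
  img <- project_mesh(flat, projection_config(resolution = 16, plane_z = 20))
  expect_true(all(img == 0L))
})

test_that("the image maximum lands at the tallest cusp apex", {
  spec <- random_tooth_spec(7, grid_resolution = 96)
  mesh <- generate_tooth_mesh(spec)
  img <- project_mesh(mesh, projection_config(resolution = 128))
  cfg <- attr(img, "config")
  iv <- which.max(mesh$vertices[, 3])
  jj <- round((mesh$vertices[iv, 1] - cfg$origin[1]) / cfg$spacing) + 1
  ii <- round((cfg$origin[2] - mesh$vertices[iv, 2]) / cfg$spacing) + 1
  peaks <- which(unclass(img) == max(img), arr.ind = TRUE)
  d2 <- (peaks[, 1] - ii)^2 + (peaks[, 2] - jj)^2
  expect_lte(min(sqrt(d2)), 2)
})

test_that("projection is translation-equivariant on a fixed raster", {
  spec <- random_tooth_spec(5, grid_resolution = 48)
  mesh <- generate_tooth_mesh(spec)
  base <- project_mesh(mesh, projection_config(resolution = 64))
  cfg <- attr(base, "config")
  shifted <- triangle_mesh(sweep(mesh$vertices, 2, c(cfg$spacing, 0, 0), "+"),
                           mesh$faces)
  img2 <- project_mesh(shifted, projection_config(
    resolution = 64, origin = cfg$origin, spacing = cfg$spacing,
    plane_z = cfg$plane_z))
  # the image content moves one pixel to the right (one column over)
  expect_identical(unclass(base)[, 1:62], unclass(img2)[, 2:63])
})

test_that("back-projection inverts projection up to quantization", {
  spec <- random_tooth_spec(7, grid_resolution = 64)
  mesh <- generate_tooth_mesh(spec)
  img <- project_mesh(mesh, projection_config(resolution = 96), raw = TRUE)
  cfg <- attr(img, "config")
  d_raw <- attr(img, "distances")
  nz <- which(unclass(img) != 0L, arr.ind = TRUE)
  p <- img[nz]
  err <- abs(distance_from_pixel(p, cfg$h, cfg$n) - d_raw[nz])
  bound <- cfg$h / (255 * cfg$n) * (1 - p / 255)^(1 / cfg$n - 1)
  expect_true(all(err <= bound + 1e-12))

  cloud <- backproject(img)
  expect_equal(nrow(cloud$points), sum(img != 0L))

  # z recovered within the same per-pixel bound
  ztrue <- cfg$plane_z - d_raw[nz]
  expect_true(all(abs(cloud$points[, 3] - ztrue) <= bound + 1e-12))
})

test_that("back-projection handles empty and constant images", {
  cfg <- projection_config(resolution = 8, origin = c(0, 7), spacing = 1,
                           plane_z = 5)
  empty <- depth_image(matrix(0L, 8, 8), cfg)
  expect_equal(nrow(backproject(empty)$points), 0)

  const <- depth_image(matrix(100L, 8, 8), cfg)
  cl <- backproject(const)
  expect_equal(nrow(cl$points), 64)
  expect_equal(length(unique(cl$points[, 3])), 1)
  expect_error(backproject(depth_image(matrix(1L, 4, 4),
                                       projection_config(resolution = 4))),
               "metadata")
})

test_that("image entropy matches closed forms and is permutation-invariant", {
  expect_identical(image_entropy(matrix(7L, 10, 10)), 0)
  expect_equal(image_entropy(matrix(0:255, 16, 16)), 8)
  expect_equal(image_entropy(matrix(c(0L, 255L), 16, 16)), 1)
  set.seed(4)
  img <- matrix(sample(0:255, 400, replace = TRUE), 20)
  e1 <- image_entropy(img)
  expect_true(e1 >= 0 && e1 <= 8)
  expect_identical(image_entropy(matrix(sample(img), 20)), e1)
})

test_that("entropy-based selection returns the arg-max exponent", {
  meshes <- lapply(1:2, function(s) {
    generate_tooth_mesh(random_tooth_spec(s, grid_resolution = 32))
  })
  grid <- seq(0.2, 3, by = 0.4)
  sel <- select_enhancement(meshes, grid, projection_config(resolution = 48))
  expect_equal(sel$n, sel$curve$n[which.max(sel$curve$entropy)])
  expect_equal(nrow(sel$curve), length(grid))
  # the curve rises and falls around the optimum on molar-like surfaces
  expect_true(which.max(sel$curve$entropy) > 1)

  expect_equal(select_enhancement(meshes, 1.7,
                                  projection_config(resolution = 32))$n, 1.7)
  # constant surface: all entropies 0, smallest candidate wins the tie
  flat <- grid_mesh(6, 6, sx = 5, sy = 5, z = function(x, y) 1 + 0 * x)
  self <- select_enhancement(list(flat), c(0.5, 1, 2),
                             projection_config(resolution = 16))
  expect_true(all(self$curve$entropy == 0))
  expect_equal(self$n, 0.5)
  expect_error(select_enhancement(list(), 1:2), "at least one")
})

test_that("depth images round trip through PNG with their metadata", {
  spec <- random_tooth_spec(2, grid_resolution = 24)
  img <- project_mesh(generate_tooth_mesh(spec),
                      projection_config(resolution = 32))
  p <- tempfile(fileext = ".png")
  write_depth_image(img, p)
  img2 <- read_depth_image(p)
  expect_identical(unclass(img2)[, ], unclass(img)[, ])
  cfg <- attr(img2, "config")
  expect_equal(cfg$plane_z, attr(img, "config")$plane_z)
  expect_equal(cfg$spacing, attr(img, "config")$spacing)
})
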