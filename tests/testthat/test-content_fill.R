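test_that("blank pixels are exactly the all-zero triplets", {
  img <- array(10, c(5, 5, 3))
  img[2, 3, ] <- 0
  img[4, 4, 1] <- 0  # one zero channel only: not blank
  m <- blank_mask(img)
  expect_equal(sum(m), 1)
  expect_equal(m[2, 3], 1)
})

test_that("edge colour averages the four border lines per channel", {
  img <- array(0, c(6, 6, 3))
  img[, , 1] <- 5; img[, , 2] <- 10; img[, , 3] <- 15
  ec <- edge_color(img)
  expect_equal(ec$avg, c(5, 10, 15), tolerance = 1e-12)
  # raise the top row by 8: the top mean moves by 8, and the left/right
  # columns (which share the two corner pixels) by 8/6 each
  img[1, , ] <- img[1, , ] + 8
  ec2 <- edge_color(img)
  expect_equal(ec2$avg, c(5, 10, 15) + (8 + 2 * 8 / 6) / 4,
               tolerance = 1e-12)
})

test_that("fully blank border sides are excluded from the fill colour", {
  img <- array(100, c(6, 6, 3))
  img[, 6, ] <- 0  # right column fully blank
  expect_message(ec <- edge_color(img, blank = blank_mask(img)),
                 "right")
  expect_equal(ec$avg, c(100, 100, 100))
})

test_that("coarse fill writes the colour exactly on the mask", {
  img <- array(7, c(5, 5, 3))
  mask <- matrix(0, 5, 5); mask[2:3, 4] <- 1
  out <- coarse_fill(img, mask, c(1, 2, 3))
  for (c in 1:3) {
    expect_true(all(out[, , c][mask == 1] == c))
    expect_true(all(out[, , c][mask == 0] == 7))
  }
})

test_that("Poisson refinement reconstructs a linear ramp through a hole", {
  # a hole cut from a linear ramp, coarsely filled with a constant:
  # the harmonic (zero-Laplacian) extension of the boundary is the ramp
  # itself, so the refinement must recover it
  h <- 24; w <- 24
  ramp <- outer(seq_len(h), seq_len(w), function(i, j) 40 + 4 * j)
  img <- array(rep(ramp, 3), c(h, w, 3))
  mask <- matrix(0, h, w); mask[8:16, 8:16] <- 1
  filled <- coarse_fill(img, mask, rep(mean(ramp), 3))
  refined <- poisson_refine(filled, mask)
  expect_lt(max(abs(refined - img)), 2)
})

test_that("refined interior satisfies the discrete Laplace equation", {
  set.seed(31)
  h <- 20; w <- 20
  img <- array(runif(h * w * 3, 50, 200), c(h, w, 3))
  mask <- matrix(0, h, w); mask[6:14, 6:14] <- 1
  filled <- coarse_fill(img, mask, c(120, 120, 120))
  refined <- poisson_refine(filled, mask)
  lap <- function(m) {
    4 * m[2:(h - 1), 2:(w - 1)] - m[1:(h - 2), 2:(w - 1)] -
      m[3:h, 2:(w - 1)] - m[2:(h - 1), 1:(w - 2)] - m[2:(h - 1), 3:w]
  }
  interior <- mask[2:(h - 1), 2:(w - 1)] == 1 &
    mask[1:(h - 2), 2:(w - 1)] == 1 & mask[3:h, 2:(w - 1)] == 1 &
    mask[2:(h - 1), 1:(w - 2)] == 1 & mask[2:(h - 1), 3:w] == 1
  for (c in 1:3)
    expect_lt(max(abs(lap(refined[, , c])[interior])), 1)
})

test_that("augmented images contain no residual padding pixels", {
  cfg <- phantom_config(image_size = 64)
  acfg <- augment_config()
  for (seed in 1:6) {
    ph <- generate_phantom(cfg, seed = seed)
    expect_equal(sum(blank_mask(ph$image)), 0)  # phantoms have no zeros
    aug <- augment_image(ph$image, ph$boxes, acfg, seed = seed * 17)
    expect_equal(sum(blank_mask(aug$image)), 0)
    expect_true(all(aug$image >= 0 & aug$image <= 255))
    validate_norm_boxes(aug$boxes)
  }
})

test_that("the identity transform is a byte-exact no-op", {
  cfg <- phantom_config(image_size = 48)
  ph <- generate_phantom(cfg, seed = 2)
  acfg <- augment_config(rotation_range = 0, translate_range = 0,
                         hflip_prob = 0, vflip_prob = 0)
  aug <- augment_image(ph$image, ph$boxes, acfg, seed = 1)
  expect_identical(aug$image, ph$image)
  expect_equal(aug$boxes, ph$boxes, ignore_attr = TRUE)
  expect_identical(aug$report$filled_pixels, 0L)
})

test_that("augmentation is deterministic given a seed", {
  cfg <- phantom_config(image_size = 48)
  ph <- generate_phantom(cfg, seed = 9)
  acfg <- augment_config()
  a <- augment_image(ph$image, ph$boxes, acfg, seed = 5)
  b <- augment_image(ph$image, ph$boxes, acfg, seed = 5)
  expect_identical(a$image, b$image)
  expect_equal(a$boxes, b$boxes)
})

test_that("box transform commutes with the raster warp", {
  # warp a filled rectangle and compare the transformed box with the
  # bounding box of the warped rectangle mask
  h <- 64; w <- 64
  img <- array(0, c(h, w, 3))
  img[21:36, 11:30, ] <- 255
  b <- box_abs_to_norm(data.frame(x1 = 10, y1 = 20, x2 = 30, y2 = 36), w, h)
  m <- affine_compose(affine_rotation(12, w, h), affine_translation(3, -2))
  wimg <- warp_affine(img, m)
  tb <- box_norm_to_abs(transform_boxes(b, m, w, h), w, h)
  on <- which(wimg[, , 1] > 127, arr.ind = TRUE)
  rast <- c(min(on[, 2]) - 1, min(on[, 1]) - 1, max(on[, 2]), max(on[, 1]))
  expect_lt(max(abs(rast - as.numeric(tb[c("x1", "y1", "x2", "y2")]))), 2)
})

test_that("augment_dataset writes variants plus a JSON report", {
  src <- withr::local_tempdir(); dst <- withr::local_tempdir()
  generate_phantom_dataset(phantom_config(image_size = 48), 2, src,
                           seed = 4, overwrite = TRUE)
  rp <- augment_dataset(src, dst, per_image = 2, seed = 6, overwrite = TRUE)
  expect_length(list.files(file.path(dst, "images")), 4)
  rep <- jsonlite::fromJSON(rp)
  expect_length(rep, 4)
  expect_true(all(vapply(rep, function(r) r$filled_pixels >= 0, TRUE)))
})
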