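test_that("planar convolution matches a brute-force oracle", {
  set.seed(21)
  m <- matrix(rnorm(15 * 13), 15, 13)
  for (spec in list(list(k = matrix(rnorm(9), 3, 3), d = 1),
                    list(k = matrix(rnorm(21), 21, 1), d = 1),
                    list(k = matrix(rnorm(49), 7, 7), d = 3))) {
    expect_equal(conv2d_plane(m, spec$k, spec$d),
                 brute_conv2d(m, spec$k, spec$d), tolerance = 1e-12)
  }
})

test_that("strip and dilated convolutions have the intended receptive span", {
  # impulse response support = receptive field of the kernel
  n <- 41
  impulse <- matrix(0, n, n); impulse[21, 21] <- 1
  strip <- conv2d_plane(impulse, matrix(1, 21, 1))    # 21 x 1 vertical strip
  expect_equal(sum(strip != 0), 21)
  expect_equal(range(which(rowSums(strip) > 0)), c(11, 31))
  dil <- conv2d_plane(impulse, matrix(1, 7, 7), dilation = 3)
  on <- which(dil != 0, arr.ind = TRUE)
  expect_equal(max(on) - min(on) + 1, 1 + 6 * 3)      # 19-pixel span
})

test_that("deformable convolution reproduces the frozen reference fixture", {
  y <- deform_conv3x3(fix_x, fix_off, array(fix_w, c(2, 1, 3, 3)), fix_b,
                      depthwise = TRUE)
  expect_lt(max(abs(y - fix_y)), 1e-6)
})

test_that("zero offsets reduce the deformable conv to a plain convolution", {
  set.seed(8)
  x <- feature_tensor(rnorm(3 * 10 * 10), c(1, 3, 10, 10))
  w <- array(rnorm(3 * 9), c(3, 1, 3, 3))
  b <- rnorm(3)
  off <- array(0, c(1, 18, 10, 10))
  got <- deform_conv3x3(x, off, w, b, depthwise = TRUE)
  want <- conv2d_depthwise(x, array(w, c(3, 3, 3)), bias = b)
  expect_lt(max(abs(got - want)), 1e-5)
})

test_that("the block output is exactly input plus refined features", {
  cfg <- bone_msca_config(8)
  blk <- bone_msca(cfg, seed = 1)
  x <- feature_tensor(rnorm(2 * 8 * 7 * 7), c(2, 8, 7, 7))
  r <- bone_msca_forward(blk, x, intermediates = TRUE)
  expect_identical(dim(r$output), dim(x))
  expect_equal(r$output, x + r$refined, tolerance = 1e-12)
})

test_that("constant input gives an interior edge-gate multiplier of 1.5", {
  cfg <- bone_msca_config(4)
  blk <- bone_msca(cfg, seed = 2)
  x <- feature_tensor(rep(3, 4 * 12 * 12), c(1, 4, 12, 12))
  r <- bone_msca_forward(blk, x, intermediates = TRUE)
  # away from the zero-padded frame the Sobel response of a constant is 0,
  # so the gate is sigmoid(0) = 0.5 and the multiplier exactly 1.5
  interior <- r$edge_map[1, , 2:11, 2:11]
  expect_identical(unique(as.numeric(1 + interior)), 1.5)
  # edges are amplified, never attenuated: gate in [1.5, 2)
  expect_true(all(1 + r$edge_map >= 1.5 & 1 + r$edge_map < 2))
})

test_that("an edge raises the gate above the flat-region response", {
  cfg <- bone_msca_config(4)
  blk <- bone_msca(cfg, seed = 3)
  plane <- matrix(0, 10, 10); plane[, 6:10] <- 4  # vertical step edge
  x <- array(0, c(1, 4, 10, 10))
  for (c in 1:4) x[1, c, , ] <- plane
  r <- bone_msca_forward(blk, x, intermediates = TRUE)
  expect_gt(r$edge_map[1, 1, 5, 5], r$edge_map[1, 1, 5, 3])
})

test_that("closed-form parameter count equals block introspection", {
  for (ch in c(4, 8, 16)) {
    cfg <- bone_msca_config(ch)
    blk <- bone_msca(cfg, seed = ch)
    expect_identical(bone_msca_parameter_count(cfg),
                     bone_msca_num_weights(blk))
  }
})

test_that("the default 256-channel block carries 114,002 parameters", {
  expect_identical(bone_msca_parameter_count(bone_msca_config(256)),
                   114002L)
  expect_identical(bone_msca_parameter_count(256), 114002L)
})

test_that("block MACs scale linearly with spatial area", {
  cfg <- bone_msca_config(16)
  m20 <- bone_msca_macs(cfg, 20, 20)
  m40 <- bone_msca_macs(cfg, 40, 40)
  expect_gt(m20, 0)
  # the squeeze-and-excitation bottleneck works on pooled channels, so its
  # (tiny) MAC share is independent of spatial size; the convolutional part
  # scales exactly with area
  se <- 2 * 16 * (16 / cfg$se_reduction)
  expect_equal((m40 - se) / (m20 - se), 4, tolerance = 1e-12)
})

test_that("forward pass is deterministic and seed-dependent at init", {
  cfg <- bone_msca_config(4)
  a <- bone_msca(cfg, seed = 7)
  b <- bone_msca(cfg, seed = 7)
  c <- bone_msca(cfg, seed = 8)
  x <- feature_tensor(rnorm(4 * 36), c(1, 4, 6, 6))
  expect_identical(bone_msca_forward(a, x), bone_msca_forward(b, x))
  expect_false(identical(bone_msca_forward(a, x), bone_msca_forward(c, x)))
})
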