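test_that("IoU matches exact raster counting on integer boxes", {
  set.seed(101)
  for (i in 1:200) {
    a <- rand_int_box(40); b <- rand_int_box(40)
    expect_equal(box_iou(matrix(a, 1), matrix(b, 1)), raster_iou(a, b),
                 tolerance = 1e-12)
  }
  expect_error(box_iou(matrix(c(5, 5, 5, 9), 1), matrix(1:4, 1)),
               "degenerate")
})

test_that("the angle cost hits its landmark values exactly", {
  base <- c(0, 0, 10, 10)
  shift <- function(dx, dy) base + c(dx, dy, dx, dy)
  expect_equal(angle_cost(matrix(base, 1), matrix(shift(7, 0), 1)), 0)
  expect_equal(angle_cost(matrix(base, 1), matrix(shift(0, 7), 1)), 0)
  expect_equal(angle_cost(matrix(base, 1), matrix(shift(5, 5), 1)), 1)
  expect_equal(angle_cost(matrix(base, 1), matrix(base, 1)), 0)
})

test_that("the distance cost equals its closed form on an aligned pair", {
  # horizontally aligned centers: Lambda = 0, gamma = 2; the enclosing box
  # is 20 x 10, the center offsets (10, 0), so rho = (0.25, 0) and
  # Delta = 1 - exp(-0.5)
  a <- matrix(c(0, 0, 10, 10), 1)
  b <- matrix(c(10, 0, 20, 10), 1)
  expect_equal(distance_cost(a, b), 1 - exp(-0.5), tolerance = 1e-12)
  expect_equal(shape_cost(a, b), 0)
  expect_equal(siou_loss(a, b), 1 - 0 + (1 - exp(-0.5)) / 2,
               tolerance = 1e-12)
})

test_that("every variant vanishes on identical boxes except the focal ones", {
  b <- matrix(c(3, 4, 20, 17), 1)
  for (v in c("iou", "ciou", "siou"))
    expect_equal(box_loss(b, b, loss_config(v)), 0, tolerance = 1e-12)
  # focal weight at IoU = 1 is -0^tau * log(1) = 0
  for (v in c("focal_iou", "focal_ciou", "focal_siou"))
    expect_equal(box_loss(b, b, loss_config(v)), 0, tolerance = 1e-12)
})

test_that("the focal weight matches its formula at IoU = 0.5", {
  expect_equal(focal_weight(0.5, loss_config(tau = 0.5)),
               sqrt(0.5) * log(2), tolerance = 1e-12)
  expect_equal(focal_weight(0.5, loss_config(tau = 0)), log(2),
               tolerance = 1e-12)
})

test_that("SIoU and Focal-SIoU match a scripted transcription over 1000 pairs", {
  set.seed(77)
  worst_s <- 0; worst_f <- 0
  for (i in 1:1000) {
    a <- rand_int_box(64); b <- rand_int_box(64)
    iou <- raster_iou(a, b)
    s_got <- box_loss(matrix(a, 1), matrix(b, 1), loss_config("siou"))
    f_got <- box_loss(matrix(a, 1), matrix(b, 1), loss_config("focal_siou"))
    worst_s <- max(worst_s, abs(s_got - scripted_siou(a, b, iou)))
    worst_f <- max(worst_f, abs(f_got - scripted_siou(a, b, iou,
                                                      focal = TRUE)))
  }
  expect_lt(worst_s, 1e-3)
  expect_lt(worst_f, 1e-3)
})

test_that("SIoU is invariant to translation and uniform scaling", {
  set.seed(13)
  for (i in 1:50) {
    a <- rand_int_box(50); b <- rand_int_box(50)
    base <- box_loss(matrix(a, 1), matrix(b, 1), loss_config("siou"))
    t <- c(17.3, -4.2, 17.3, -4.2)
    expect_equal(box_loss(matrix(a + t, 1), matrix(b + t, 1),
                          loss_config("siou")), base, tolerance = 1e-9)
    expect_equal(box_loss(matrix(a * 3.7, 1), matrix(b * 3.7, 1),
                          loss_config("siou")), base, tolerance = 1e-9)
  }
})

test_that("the literal unsquared distance-cost switch changes the loss", {
  a <- matrix(c(0, 0, 10, 10), 1); b <- matrix(c(10, 0, 20, 10), 1)
  canon <- distance_cost(a, b)
  literal <- distance_cost(a, b, paper_literal = TRUE)
  expect_equal(literal, 1 - exp(-2 * 0.5), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(canon, literal)))
  expect_error(box_loss_grad(c(0, 0, 10, 10), c(10, 0, 20, 10),
                             loss_config("siou", paper_literal = TRUE)),
               "canonical")
})

test_that("analytic gradients match central finite differences", {
  set.seed(29)
  for (variant in c("iou", "siou", "focal_siou")) {
    cfg <- loss_config(variant)
    for (i in 1:40) {
      # overlapping, non-degenerate pair with all costs active
      g <- rand_int_box(30)
      p <- g + runif(4, -3, 3)
      if (p[3] - p[1] < 1) p[3] <- p[1] + 1.5
      if (p[4] - p[2] < 1) p[4] <- p[2] + 1.5
      got <- box_loss_grad(p, g, cfg)
      fd <- vapply(1:4, function(k) {
        e <- 1e-6; pp <- p; pm <- p
        pp[k] <- pp[k] + e; pm[k] <- pm[k] - e
        (box_loss(matrix(pp, 1), matrix(g, 1), cfg) -
           box_loss(matrix(pm, 1), matrix(g, 1), cfg)) / (2 * e)
      }, 0)
      expect_equal(got$grad, fd, tolerance = 1e-3)
      expect_equal(got$loss,
                   box_loss(matrix(p, 1), matrix(g, 1), cfg),
                   tolerance = 1e-9)
    }
  }
})

test_that("batched losses equal the per-pair losses", {
  set.seed(5)
  preds <- t(vapply(1:20, function(i) rand_int_box(40), numeric(4)))
  gts <- t(vapply(1:20, function(i) rand_int_box(40), numeric(4)))
  cfg <- loss_config("focal_siou")
  batched <- batch_box_loss(preds, gts, cfg)
  single <- vapply(1:20, function(i)
    box_loss(preds[i, , drop = FALSE], gts[i, , drop = FALSE], cfg), 0)
  expect_equal(batched$per_pair, single, tolerance = 1e-12)
  expect_equal(batched$loss, mean(single), tolerance = 1e-12)
})

test_that("CIoU reduces to IoU loss plus penalties", {
  a <- matrix(c(0, 0, 10, 10), 1); b <- matrix(c(2, 3, 12, 13), 1)
  l_iou <- box_loss(a, b, loss_config("iou"))
  l_ciou <- box_loss(a, b, loss_config("ciou"))
  expect_gt(l_ciou, l_iou)
  # same aspect ratio: v = 0, so CIoU = IoU loss + d^2/c^2
  d2 <- (2 - 0)^2 + (3 - 0)^2
  c2 <- 12^2 + 13^2
  expect_equal(l_ciou, l_iou + d2 / c2, tolerance = 1e-9)
})
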