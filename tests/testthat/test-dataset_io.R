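test_that("normalized boxes validate their invariants", {
  b <- norm_boxes(cx = c(0.5, 0.2), cy = c(0.5, 0.8), w = c(0.2, 0.1),
                  h = c(0.1, 0.3))
  expect_identical(nrow(b), 2L)
  expect_error(norm_boxes(cx = 1.2, cy = 0.5, w = 0.1, h = 0.1),
               "outside")
  expect_error(norm_boxes(cx = 0.5, cy = 0.5, w = 0, h = 0.1),
               "width/height")
  expect_error(norm_boxes(cx = 0.5, cy = 0.5, w = 0.1, h = 0.1,
                          class_id = -1L), "class id")
})

test_that("normalized/absolute conversion round-trips and clips", {
  b <- norm_boxes(cx = c(0.3, 0.71), cy = c(0.42, 0.5), w = c(0.2, 0.14),
                  h = c(0.36, 0.5))
  ab <- box_norm_to_abs(b, 640, 480)
  back <- box_abs_to_norm(ab, 640, 480)
  expect_equal(back, b, tolerance = 1e-12)
  # clipping drops collapsed boxes and counts them
  wide <- data.frame(class_id = 0L, cx = c(0.5, 1.0), cy = c(0.5, 0.5),
                     w = c(1.2, 0.0001), h = c(0.5, 0.0001))
  cl <- clip_norm_boxes(wide, min_area = 1e-6)
  expect_identical(nrow(cl), 1L)
  expect_identical(attr(cl, "dropped"), 1L)
  expect_equal(cl$w, 1)
})

test_that("label files round-trip through the YOLO text format", {
  b <- norm_boxes(cx = c(0.123456, 0.5), cy = c(0.654321, 0.25),
                  w = c(0.111111, 0.2), h = c(0.222222, 0.4))
  f <- withr::local_tempfile(fileext = ".txt")
  write_yolo_labels(b, f)
  r <- read_yolo_labels(f)
  expect_equal(r, b, tolerance = 1e-6)
  # empty label set round-trips as zero rows
  write_yolo_labels(norm_boxes(), f)
  expect_identical(nrow(read_yolo_labels(f)), 0L)
})

test_that("malformed label lines raise errors naming file and line", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0.5 0.5 0.2 0.2", "0 0.5 0.5 0.2"), f)
  expect_error(read_yolo_labels(f), "line 2")
  writeLines(c("0 0.5 abc 0.2 0.2"), f)
  expect_error(read_yolo_labels(f), "non-numeric")
  writeLines(c("0 1.5 0.5 0.2 0.2"), f)
  expect_error(read_yolo_labels(f), "outside")
})

test_that("PNG image io round-trips 8-bit values exactly", {
  img <- array(sample(0:255, 12 * 10 * 3, replace = TRUE), c(12, 10, 3))
  f <- withr::local_tempfile(fileext = ".png")
  write_image_png(img, f)
  back <- read_image_png(f)
  expect_identical(dim(back), dim(img))
  expect_equal(back, img, tolerance = 0)
})

test_that("dataset write/read round-trips images and labels", {
  root <- withr::local_tempdir()
  items <- list(
    list(image = array(100, c(8, 8, 3)),
         boxes = norm_boxes(0.5, 0.5, 0.25, 0.25), name = "a"),
    list(image = array(50, c(8, 8, 3)), boxes = norm_boxes(), name = "b"))
  write_yolo_dataset(items, root, overwrite = TRUE)
  expect_true(file.exists(file.path(root, "data.yaml")))
  back <- read_yolo_dataset(root)
  expect_length(back, 2)
  expect_equal(back[[1]]$boxes$cx, 0.5, tolerance = 1e-6)
  expect_identical(nrow(back[[2]]$boxes), 0L)
  # a missing label file warns and yields an empty box set
  unlink(file.path(root, "labels", "b.txt"))
  expect_warning(back2 <- read_yolo_dataset(root), "missing label")
  expect_identical(nrow(back2[[2]]$boxes), 0L)
  # refuse to clobber a non-empty directory without overwrite
  expect_error(write_yolo_dataset(items, root), "not empty")
})

test_that("split sizes follow the floor/round/remainder convention", {
  items <- sprintf("img_%05d.png", seq_len(14267))
  sp <- split_dataset(items, ratios = c(7, 2, 1), seed = 11)
  expect_identical(lengths(sp[c("train", "val", "test")]),
                   c(train = 9987L, val = 2854L, test = 1426L))
  all_items <- c(sp$train, sp$val, sp$test)
  expect_setequal(all_items, items)
  expect_identical(anyDuplicated(all_items), 0L)
})

test_that("splits are deterministic in the seed and reshuffled across seeds", {
  items <- sprintf("i%03d", 1:100)
  a <- split_dataset(items, seed = 7)
  b <- split_dataset(items, seed = 7)
  c <- split_dataset(items, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$train, c$train))
  expect_error(split_dataset(items[1:2]), "at least")
})
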