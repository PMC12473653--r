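#' Read a YOLO-layout detection dataset
#'
#' Expects `root/images/` with PNG images and `root/labels/` with one
#' whitespace-separated text file per image (`class cx cy w h`, normalized).
#' Images without a label file get an empty box list with a warning;
#' malformed label lines raise an error naming the file and line, they are
#' never silently dropped.
#'
#' @param root Dataset directory containing `images/` and `labels/`.
#' @return A list of labeled images, each a list with elements
#'   `image_path`, `width`, `height` and `boxes` (a [norm_boxes()] frame).
#' @export
read_yolo_dataset <- function(root) {
  img_dir <- file.path(root, "images")
  lab_dir <- file.path(root, "labels")
  if (!dir.exists(img_dir)) stop("no images/ directory under ", root)
  imgs <- sort(list.files(img_dir, pattern = "\\.png$", ignore.case = TRUE))
  if (length(imgs) == 0) stop("no PNG images under ", img_dir)
  lapply(imgs, function(f) {
    path <- file.path(img_dir, f)
    px <- png::readPNG(path)
    hw <- dim(px)[1:2]
    lab <- file.path(lab_dir, paste0(tools::file_path_sans_ext(f), ".txt"))
    if (!file.exists(lab)) {
      warning("missing label file for ", f, "; assuming no boxes")
      boxes <- norm_boxes()
    } else {
      boxes <- read_yolo_labels(lab)
    }
    list(image_path = path, width = hw[2], height = hw[1], boxes = boxes)
  })
}

#' Read one YOLO label file
#'
#' @param path Label file path.
#' @return A normalized box `data.frame`.
#' @export
read_yolo_labels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(norm_boxes())
  rows <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) != 5)
      stop(path, " line ", i, ": expected 5 fields, got ", length(fields))
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)))
      stop(path, " line ", i, ": non-numeric field")
    vals
  })
  m <- do.call(rbind, rows)
  boxes <- data.frame(class_id = as.integer(m[, 1]), cx = m[, 2],
                      cy = m[, 3], w = m[, 4], h = m[, 5])
  validate_norm_boxes(boxes, where = path)
  boxes
}

#' Write one YOLO label file
#'
#' Coordinates are serialized with six decimal places, enough for lossless
#' round-trips at the 1e-6 tolerance the rest of the toolkit assumes.
#'
#' @param boxes Normalized box `data.frame`.
#' @param path Output file path.
#' @export
write_yolo_labels <- function(boxes, path) {
  if (nrow(boxes) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  validate_norm_boxes(boxes)
  writeLines(sprintf("%d %.6f %.6f %.6f %.6f", boxes$class_id, boxes$cx,
                     boxes$cy, boxes$w, boxes$h), path)
  invisible(path)
}

#' Write a YOLO-layout dataset
#'
#' Creates `root/images/` and `root/labels/`, copies (or writes) each image
#' and its label file, and drops a `data.yaml` manifest describing the single
#' "Fracture" class.
#'
#' @param items List of labeled images as returned by [read_yolo_dataset()];
#'   each element may carry either `image_path` (file is copied) or `image`
#'   (an `H x W x 3` array in `[0, 255]`, written as PNG) plus a `name`.
#' @param root Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @export
write_yolo_dataset <- function(items, root, overwrite = FALSE) {
  prepare_out_dir(root, overwrite)
  img_dir <- file.path(root, "images")
  lab_dir <- file.path(root, "labels")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(lab_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(items)) {
    it <- items[[i]]
    name <- if (!is.null(it$name)) it$name
            else if (!is.null(it$image_path))
              tools::file_path_sans_ext(basename(it$image_path))
            else sprintf("img_%05d", i)
    dst <- file.path(img_dir, paste0(name, ".png"))
    if (!is.null(it$image)) {
      write_image_png(it$image, dst)
    } else {
      if (!file.copy(it$image_path, dst, overwrite = TRUE))
        stop("cannot copy ", it$image_path, " to ", dst)
    }
    write_yolo_labels(it$boxes, file.path(lab_dir, paste0(name, ".txt")))
  }
  manifest <- list(path = normalizePath(root), train = "images",
                   val = "images", nc = 1L, names = list(`0` = "Fracture"))
  yaml::write_yaml(manifest, file.path(root, "data.yaml"))
  invisible(root)
}

prepare_out_dir <- function(root, overwrite) {
  if (dir.exists(root) && length(list.files(root)) > 0 && !overwrite)
    stop("output directory ", root, " is not empty; use overwrite = TRUE")
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
}

#' Write an image array as 8-bit PNG
#'
#' @param image `H x W` or `H x W x 3` numeric array with values in
#'   `[0, 255]`.
#' @param path Output path.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(round(image) / 255, path)
  invisible(path)
}

#' Read an 8-bit PNG into a `[0, 255]` array
#'
#' Grayscale images are replicated to three channels so downstream stages
#' always see `H x W x 3`.
#'
#' @param path PNG file path.
#' @return `H x W x 3` numeric array with integer values in `[0, 255]`.
#' @export
read_image_png <- function(path) {
  px <- png::readPNG(path)
  px <- round(px * 255)
  if (length(dim(px)) == 2) px <- array(px, dim = c(dim(px), 3))
  if (dim(px)[3] == 1) px <- array(px[, , 1], dim = c(dim(px)[1:2], 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]
  px
}

#' Split a dataset into train/validation/test partitions
#'
#' Membership is a deterministic function of `(length(items), ratios, seed)`.
#' The partition sizes follow the convention that uniquely reproduces the
#' published 9987/2854/1426 split of 14,267 images at 7:2:1:
#' `|test| = floor(r_test * N)`, `|train| = round(r_train * N)`,
#' `|val| = N - |train| - |test|`.
#'
#' @param items List (or vector) of dataset items.
#' @param ratios Three positive numbers, normalized internally.
#' @param seed Integer seed for the shuffle.
#' @return An object of class `yolo_split`: a list with elements `train`,
#'   `val`, `test` (disjoint subsets of `items`), `sizes`, `ratios`, `seed`.
#' @export
#' @examples
#' split_dataset(seq_len(10), c(7, 2, 1), seed = 1)$sizes
split_dataset <- function(items, ratios = c(7, 2, 1), seed = 0L) {
  n <- length(items)
  if (n < 3) stop("need at least 3 items to split, got ", n)
  if (length(ratios) != 3 || any(!is.finite(ratios)) || any(ratios <= 0))
    stop("ratios must be three positive numbers")
  r <- ratios / sum(ratios)
  n_test <- floor(r[3] * n)
  n_train <- round(r[1] * n)
  n_val <- n - n_train - n_test
  if (n_val < 0) stop("degenerate ratios: empty validation partition")
  idx <- with_seed(seed, sample.int(n))
  take <- function(i) if (is.list(items)) items[i] else items[i]
  out <- list(train = take(idx[seq_len(n_train)]),
              val = take(idx[n_train + seq_len(n_val)]),
              test = take(idx[n_train + n_val + seq_len(n_test)]),
              sizes = c(train = as.integer(n_train), val = as.integer(n_val),
                        test = as.integer(n_test)),
              ratios = r, seed = as.integer(seed))
  class(out) <- "yolo_split"
  out
}

#' @export
print.yolo_split <- function(x, ...) {
  cat(sprintf("YOLO dataset split (seed %d): train %d / val %d / test %d\n",
              x$seed, x$sizes["train"], x$sizes["val"], x$sizes["test"]))
  invisible(x)
}
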