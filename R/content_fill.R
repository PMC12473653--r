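#' Content-aware fill augmentation
#'
#' Geometric augmentation (rotation, translation, flips) pads the frame with
#' exact-zero pixels. The fill pipeline detects those pixels, infers a fill
#' colour from the border of the valid region, covers the holes with a coarse
#' mean fill, and then refines the result in the gradient domain so the fill
#' blends seamlessly into the surrounding tissue.
#'
#' @name content_fill
NULL

#' Detect blank (padding) pixels
#'
#' A pixel is blank iff all three channels are exactly zero -- the value the
#' warp assigns to positions outside the source frame. Blankness is defined
#' purely by value, so an interpolated pixel that happens to hit exact zero
#' is indistinguishable from padding.
#'
#' @param image `H x W x 3` numeric array.
#' @return `H x W` binary matrix (1 = blank).
#' @export
blank_mask <- function(image) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  (image[, , 1] == 0) * (image[, , 2] == 0) * (image[, , 3] == 0)
}

#' Infer a fill colour from the image border
#'
#' Per-channel means over the first row, last row, first column and last
#' column, optionally restricted to non-blank pixels, averaged per Eq-style
#' edge statistics: `avg = (top + bottom + left + right) / 4`. A border line
#' with no valid pixel is excluded and the average renormalized over the
#' remaining sides (with a message).
#'
#' @param image `H x W x 3` numeric array.
#' @param blank Optional `H x W` binary mask of blank pixels (1 = blank) to
#'   exclude from the border statistics.
#' @return A list with per-channel numeric vectors `top`, `bottom`, `left`,
#'   `right` and their average `avg`.
#' @export
edge_color <- function(image, blank = NULL) {
  d <- dim(image)
  stopifnot(length(d) == 3, d[3] == 3)
  valid <- if (is.null(blank)) matrix(TRUE, d[1], d[2]) else blank == 0
  side_mean <- function(rows, cols) {
    v <- valid[rows, cols]
    if (!any(v)) return(NULL)
    vapply(1:3, function(c) mean(image[rows, cols, c][v]), 0)
  }
  sides <- list(top = side_mean(1, seq_len(d[2])),
                bottom = side_mean(d[1], seq_len(d[2])),
                left = side_mean(seq_len(d[1]), 1),
                right = side_mean(seq_len(d[1]), d[2]))
  present <- !vapply(sides, is.null, TRUE)
  if (!any(present)) stop("no valid border pixels to infer a fill colour")
  if (!all(present))
    message("excluding fully blank border side(s): ",
            paste(names(sides)[!present], collapse = ", "))
  avg <- Reduce(`+`, sides[present]) / sum(present)
  c(sides, list(avg = avg))
}

#' Coarse mean fill of blank pixels
#'
#' Sets masked pixels exactly to `color`; all other pixels are returned
#' bit-identical.
#'
#' @param image `H x W x 3` numeric array.
#' @param mask `H x W` binary matrix (1 = fill).
#' @param color Per-channel fill values (length 3, or 1 recycled).
#' @return Filled `H x W x 3` array.
#' @export
coarse_fill <- function(image, mask, color) {
  stopifnot(all(dim(mask) == dim(image)[1:2]))
  color <- rep_len(color, 3)
  out <- image
  idx <- mask == 1
  for (c in 1:3) {
    plane <- out[, , c]
    plane[idx] <- color[c]
    out[, , c] <- plane
  }
  out
}

#' Poisson (gradient-domain) refinement of a coarse fill
#'
#' Solves, per channel, the discrete Poisson equation on the masked region:
#' the output's 4-neighbour Laplacian matches the Laplacian of the guide
#' field inside the hole, with Dirichlet boundary values taken from the
#' surrounding valid pixels. The guide gradients are those of the
#' coarse-filled patch itself (near-zero inside a mean-filled hole), so the
#' refinement behaves as harmonic inpainting seeded by the mean colour.
#' Solved directly as a sparse symmetric positive-definite system.
#'
#' @param coarse `H x W x 3` array with holes already coarse-filled.
#' @param mask `H x W` binary matrix (1 = refine).
#' @return `H x W x 3` array, clipped to `[0, 255]`; pixels outside the mask
#'   are returned unchanged.
#' @export
poisson_refine <- function(coarse, mask) {
  d <- dim(coarse)
  stopifnot(all(dim(mask) == d[1:2]))
  idx <- which(mask == 1)
  if (length(idx) == 0) return(coarse)
  h <- d[1]; w <- d[2]
  n <- length(idx)
  id_of <- integer(h * w)
  id_of[idx] <- seq_len(n)
  ri <- ((idx - 1) %% h) + 1
  ci <- ((idx - 1) %/% h) + 1
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  deg <- numeric(n)
  bnd <- matrix(0, n, 3)    # Dirichlet contributions per channel
  guide <- matrix(0, n, 3)  # guide Laplacian (intra-hole gradients only)
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  for (o in offs) {
    rn <- ri + o[1]; cn <- ci + o[2]
    inframe <- rn >= 1 & rn <= h & cn >= 1 & cn <= w
    nidx <- (cn - 1) * h + rn
    nid <- integer(n)
    nid[inframe] <- id_of[nidx[inframe]]
    deg <- deg + inframe
    inhole <- inframe & nid > 0
    # off-diagonal entries for masked neighbours
    trip_i <- c(trip_i, which(inhole))
    trip_j <- c(trip_j, nid[inhole])
    trip_x <- c(trip_x, rep(-1, sum(inhole)))
    onbnd <- inframe & nid == 0
    for (c in 1:3) {
      plane <- coarse[, , c]
      if (any(onbnd))
        bnd[onbnd, c] <- bnd[onbnd, c] + plane[nidx[onbnd]]
      # guide gradients between pixels of the filled patch only
      if (any(inhole))
        guide[inhole, c] <- guide[inhole, c] +
          (plane[idx[inhole]] - plane[nidx[inhole]])
    }
  }
  a <- Matrix::sparseMatrix(i = c(seq_len(n), trip_i),
                            j = c(seq_len(n), trip_j),
                            x = c(deg, trip_x), dims = c(n, n))
  out <- coarse
  sol <- Matrix::solve(a, guide + bnd)
  sol <- as.matrix(sol)
  for (c in 1:3) {
    plane <- out[, , c]
    plane[idx] <- pmin(pmax(sol[, c], 0), 255)
    out[, , c] <- plane
  }
  out
}

#' Configuration for the geometric augmentation stage
#'
#' Defaults mirror plausible clinical variation in positioning: rotations up
#' to +/-15 degrees, shifts up to 10% of the frame, frequent horizontal and
#' rare vertical mirroring. All values are configurable.
#'
#' @param rotation_range Maximum absolute rotation, degrees.
#' @param translate_range Maximum absolute shift, fraction of image size.
#' @param hflip_prob,vflip_prob Flip probabilities in `[0, 1]`.
#' @param min_box_area Minimum normalized box area kept after clipping.
#' @param seed Default seed used by [augment_image()].
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(rotation_range = 15, translate_range = 0.1,
                           hflip_prob = 0.5, vflip_prob = 0.1,
                           min_box_area = 1e-4, seed = NULL) {
  stopifnot(rotation_range >= 0, translate_range >= 0,
            hflip_prob >= 0, hflip_prob <= 1,
            vflip_prob >= 0, vflip_prob <= 1)
  structure(list(rotation_range = rotation_range,
                 translate_range = translate_range,
                 hflip_prob = hflip_prob, vflip_prob = vflip_prob,
                 min_box_area = min_box_area, seed = seed),
            class = "augment_config")
}

#' Random geometric transform of an image and its boxes
#'
#' Samples a rotation about the center (uniform in the configured range), a
#' translation and flips, applies them to the raster with bilinear
#' interpolation and exact-zero padding, and transforms every box by mapping
#' its corners through the same matrix.
#'
#' @param image `H x W x 3` numeric array.
#' @param boxes Normalized box `data.frame`.
#' @param cfg An [augment_config()].
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return A list with `image`, `boxes` (attribute `"dropped"` carries the
#'   clipped-away box count) and the sampled `params`.
#' @export
random_geometric <- function(image, boxes, cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "augment_config"))
  d <- dim(image)
  params <- with_seed(seed, list(
    degrees = runif(1, -cfg$rotation_range, cfg$rotation_range),
    tx = runif(1, -cfg$translate_range, cfg$translate_range) * d[2],
    ty = runif(1, -cfg$translate_range, cfg$translate_range) * d[1],
    hflip = runif(1) < cfg$hflip_prob,
    vflip = runif(1) < cfg$vflip_prob))
  m <- affine_compose(affine_flip(params$hflip, params$vflip, d[2], d[1]),
                      affine_rotation(params$degrees, d[2], d[1]),
                      affine_translation(params$tx, params$ty))
  identity_m <- max(abs(m - diag(3))) < 1e-12
  out_img <- if (identity_m) image else warp_affine(image, m)
  out_boxes <- if (identity_m) {
    attr(boxes, "dropped") <- 0L
    boxes
  } else transform_boxes(boxes, m, d[2], d[1], cfg$min_box_area)
  list(image = out_img, boxes = out_boxes, params = params, matrix = m)
}

#' Full content-aware augmentation of one labelled image
#'
#' Pipeline: random geometric transform, blank-area detection, edge-colour
#' inference, coarse mean fill, Poisson refinement. When the input contains
#' no exact-zero pixels, the output contains none either (all padding holes
#' are filled).
#'
#' @inheritParams random_geometric
#' @return A list with `image` (integer values in `[0, 255]`), `boxes`,
#'   `params`, and `report` (dropped box count, number of filled pixels,
#'   fill colour).
#' @export
augment_image <- function(image, boxes, cfg = augment_config(),
                          seed = cfg$seed) {
  geo <- random_geometric(image, boxes, cfg, seed = seed)
  mask <- blank_mask(geo$image)
  n_blank <- sum(mask)
  if (n_blank > 0) {
    ec <- edge_color(geo$image, blank = mask)
    filled <- coarse_fill(geo$image, mask, ec$avg)
    refined <- poisson_refine(filled, mask)
    out <- round(pmin(pmax(refined, 0), 255))
    color <- ec$avg
  } else {
    out <- geo$image
    color <- NULL
  }
  list(image = out, boxes = geo$boxes, params = geo$params,
       report = list(dropped_boxes = attr(geo$boxes, "dropped"),
                     filled_pixels = n_blank, fill_color = color))
}

#' Augment a whole YOLO dataset
#'
#' Writes `per_image` augmented variants of every source image to a new
#' dataset in YOLO layout, plus a JSON report with per-image dropped-box
#' counts and filled-pixel counts.
#'
#' @param in_root Source dataset directory (YOLO layout).
#' @param out_root Output dataset directory.
#' @param cfg An [augment_config()].
#' @param per_image Number of augmented variants per source image.
#' @param seed Master seed.
#' @param overwrite Allow writing into a non-empty output directory.
#' @return Path of the JSON report, invisibly.
#' @export
augment_dataset <- function(in_root, out_root, cfg = augment_config(),
                            per_image = 1L, seed = 0L, overwrite = FALSE) {
  items <- read_yolo_dataset(in_root)
  out_items <- list()
  report <- list()
  for (i in seq_along(items)) {
    img <- read_image_png(items[[i]]$image_path)
    base <- tools::file_path_sans_ext(basename(items[[i]]$image_path))
    for (k in seq_len(per_image)) {
      aug <- augment_image(img, items[[i]]$boxes, cfg,
                           seed = derive_seed(seed, paste0(base, "_", k)))
      name <- sprintf("%s_aug%02d", base, k)
      out_items[[length(out_items) + 1L]] <-
        list(image = aug$image, boxes = aug$boxes, name = name)
      report[[name]] <- list(dropped_boxes = aug$report$dropped_boxes,
                             filled_pixels = aug$report$filled_pixels)
    }
  }
  write_yolo_dataset(out_items, out_root, overwrite = overwrite)
  rp <- file.path(out_root, "augment_report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA)
  invisible(rp)
}
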