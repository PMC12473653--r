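#' Affine transforms of images and boxes
#'
#' Geometry convention: a pixel `(i, j)` (1-based array indices) sits at the
#' continuous 0-based point `(x = j - 1, y = i - 1)`. Affine matrices are
#' `3 x 3` and map input points to output points as column vectors
#' `(x, y, 1)`.
#'
#' @name warp
NULL

#' 3x3 affine matrix helpers
#'
#' `affine_rotation` rotates by `degrees` about the image center,
#' `affine_translation` shifts by `(tx, ty)` pixels, `affine_flip` mirrors
#' horizontally and/or vertically about the center, and `affine_compose`
#' multiplies matrices left to right (first argument applied first).
#'
#' @param degrees Rotation angle (counter-clockwise in the x-right/y-down
#'   pixel frame).
#' @param width,height Image dimensions in pixels.
#' @param tx,ty Translation in pixels.
#' @param horizontal,vertical Logical flip switches.
#' @param ... Matrices, applied first-to-last.
#' @return A `3 x 3` numeric matrix.
#' @export
affine_rotation <- function(degrees, width, height) {
  th <- degrees * pi / 180
  cx <- (width - 1) / 2; cy <- (height - 1) / 2
  r <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  t1 <- affine_translation(-cx, -cy); t2 <- affine_translation(cx, cy)
  t2 %*% r %*% t1
}

#' @rdname affine_rotation
#' @export
affine_translation <- function(tx, ty) {
  matrix(c(1, 0, 0, 0, 1, 0, tx, ty, 1), 3, 3)
}

#' @rdname affine_rotation
#' @export
affine_flip <- function(horizontal, vertical, width, height) {
  m <- diag(3)
  if (horizontal) { m[1, 1] <- -1; m[1, 3] <- width - 1 }
  if (vertical) { m[2, 2] <- -1; m[2, 3] <- height - 1 }
  m
}

#' @rdname affine_rotation
#' @export
affine_compose <- function(...) {
  ms <- list(...)
  out <- diag(3)
  for (m in ms) out <- m %*% out
  out
}

#' Warp an image by an affine matrix with bilinear interpolation
#'
#' Inverse-mapping warp: every output pixel is sampled from the input at the
#' inverse-transformed position. Positions that fall outside the input frame
#' are padded with exact zeros, the marker the content-aware fill stage
#' later detects.
#'
#' @param image `H x W x C` (or `H x W`) numeric array.
#' @param m `3 x 3` affine matrix mapping input points to output points.
#' @return Warped array of the same dimensions.
#' @export
warp_affine <- function(image, m) {
  d <- dim(image)
  h <- d[1]; w <- d[2]
  inv <- solve(m)
  xo <- matrix(rep(0:(w - 1), each = h), h, w)
  yo <- matrix(rep(0:(h - 1), times = w), h, w)
  xs <- inv[1, 1] * xo + inv[1, 2] * yo + inv[1, 3]
  ys <- inv[2, 1] * xo + inv[2, 2] * yo + inv[2, 3]
  outside <- xs < 0 | xs > (w - 1) | ys < 0 | ys > (h - 1)
  if (length(d) == 2) {
    out <- bilinear_sample(image, ys, xs)
    out[outside] <- 0
    return(out)
  }
  out <- array(0, dim = d)
  for (c in seq_len(d[3])) {
    plane <- bilinear_sample(image[, , c], ys, xs)
    plane[outside] <- 0
    out[, , c] <- plane
  }
  out
}

#' Transform normalized boxes by an affine matrix
#'
#' Each box's four corners are mapped through `m`; the axis-aligned
#' enclosing box is taken and clipped to the frame. Boxes whose transformed
#' center leaves the frame, or whose clipped normalized area falls below
#' `min_box_area`, are dropped; the count is attached as attribute
#' `"dropped"`.
#'
#' @param boxes Normalized box `data.frame`.
#' @param m `3 x 3` affine matrix (pixel coordinates).
#' @param width,height Image dimensions in pixels.
#' @param min_box_area Minimum normalized area kept.
#' @return Transformed normalized boxes with attribute `"dropped"`.
#' @export
transform_boxes <- function(boxes, m, width, height, min_box_area = 0) {
  if (nrow(boxes) == 0) {
    attr(boxes, "dropped") <- 0L
    return(boxes)
  }
  ab <- box_norm_to_abs(boxes, width, height)
  # the half-open pixel box [x1, x2) spans continuous points x1 .. x2 - 1;
  # corners are mapped at pixel centers to commute with the raster warp
  map_pt <- function(x, y) {
    list(x = m[1, 1] * x + m[1, 2] * y + m[1, 3],
         y = m[2, 1] * x + m[2, 2] * y + m[2, 3])
  }
  xs1 <- ab$x1; xs2 <- ab$x2 - 1; ys1 <- ab$y1; ys2 <- ab$y2 - 1
  p <- list(map_pt(xs1, ys1), map_pt(xs2, ys1), map_pt(xs1, ys2),
            map_pt(xs2, ys2))
  px <- cbind(p[[1]]$x, p[[2]]$x, p[[3]]$x, p[[4]]$x)
  py <- cbind(p[[1]]$y, p[[2]]$y, p[[3]]$y, p[[4]]$y)
  nx1 <- apply(px, 1, min); nx2 <- apply(px, 1, max) + 1
  ny1 <- apply(py, 1, min); ny2 <- apply(py, 1, max) + 1
  ctr <- map_pt((ab$x1 + ab$x2) / 2, (ab$y1 + ab$y2) / 2)
  inside <- ctr$x >= 0 & ctr$x <= width & ctr$y >= 0 & ctr$y <= height
  cx1 <- pmax(0, nx1); cx2 <- pmin(width, nx2)
  cy1 <- pmax(0, ny1); cy2 <- pmin(height, ny2)
  area <- pmax(0, cx2 - cx1) * pmax(0, cy2 - cy1) / (width * height)
  keep <- inside & area >= min_box_area & (cx2 > cx1) & (cy2 > cy1)
  out <- box_abs_to_norm(data.frame(class_id = ab$class_id[keep],
                                    x1 = cx1[keep], y1 = cy1[keep],
                                    x2 = cx2[keep], y2 = cy2[keep]),
                         width, height)
  attr(out, "dropped") <- sum(!keep)
  out
}
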