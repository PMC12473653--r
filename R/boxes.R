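#' Normalized bounding boxes
#'
#' Detection labels follow the YOLO text convention: each box is stored as a
#' class id plus center/size coordinates (`cx`, `cy`, `w`, `h`) expressed as
#' fractions of the image width and height. Boxes are kept in a plain
#' `data.frame` with those five columns, so standard subsetting and binding
#' work unchanged.
#'
#' @param class_id Integer class ids (default all 0, the single "Fracture"
#'   class).
#' @param cx,cy Box centers in `[0, 1]`.
#' @param w,h Box sizes in `(0, 1]`.
#' @return A `data.frame` with columns `class_id`, `cx`, `cy`, `w`, `h`.
#' @export
#' @examples
#' norm_boxes(cx = 0.5, cy = 0.5, w = 0.2, h = 0.1)
norm_boxes <- function(cx = numeric(), cy = numeric(), w = numeric(),
                       h = numeric(), class_id = 0L) {
  n <- length(cx)
  stopifnot(length(cy) == n, length(w) == n, length(h) == n)
  df <- data.frame(class_id = as.integer(rep_len(class_id, n)),
                   cx = as.numeric(cx), cy = as.numeric(cy),
                   w = as.numeric(w), h = as.numeric(h))
  validate_norm_boxes(df)
  df
}

#' Validate normalized boxes
#'
#' Checks the invariants of the YOLO label convention: centers in `[0, 1]`,
#' strictly positive sizes no larger than 1, non-negative integer class ids.
#'
#' @param boxes A box `data.frame` as returned by [norm_boxes()].
#' @param where Optional label (file/line) used in error messages.
#' @return `boxes`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_norm_boxes <- function(boxes, where = NULL) {
  need <- c("class_id", "cx", "cy", "w", "h")
  if (!is.data.frame(boxes) || !all(need %in% names(boxes)))
    stop("boxes must be a data.frame with columns ",
         paste(need, collapse = ", "))
  tag <- if (is.null(where)) "" else paste0(" [", where, "]")
  if (nrow(boxes) == 0) return(invisible(boxes))
  if (any(!is.finite(as.matrix(boxes[need[-1]]))))
    stop("non-finite box coordinates", tag)
  if (any(boxes$class_id < 0))
    stop("negative class id", tag)
  if (any(boxes$cx < 0 | boxes$cx > 1 | boxes$cy < 0 | boxes$cy > 1))
    stop("box center outside [0, 1]", tag)
  if (any(boxes$w <= 0 | boxes$h <= 0 | boxes$w > 1 | boxes$h > 1))
    stop("box width/height outside (0, 1]", tag)
  invisible(boxes)
}

#' Convert normalized boxes to absolute pixel corners
#'
#' Pixel boxes use a 0-based, half-open corner convention
#' `[x1, x2) x [y1, y2)` in continuous pixel units, which keeps
#' intersection-over-union arithmetic free of off-by-one adjustments.
#'
#' @param boxes Normalized box `data.frame`.
#' @param width,height Image size in pixels.
#' @return A `data.frame` with columns `class_id`, `x1`, `y1`, `x2`, `y2`.
#' @export
box_norm_to_abs <- function(boxes, width, height) {
  data.frame(class_id = boxes$class_id,
             x1 = (boxes$cx - boxes$w / 2) * width,
             y1 = (boxes$cy - boxes$h / 2) * height,
             x2 = (boxes$cx + boxes$w / 2) * width,
             y2 = (boxes$cy + boxes$h / 2) * height)
}

#' Convert absolute pixel corners to normalized boxes
#'
#' @param abs_boxes `data.frame` with columns `x1`, `y1`, `x2`, `y2` and
#'   optionally `class_id`.
#' @param width,height Image size in pixels.
#' @return A normalized box `data.frame`.
#' @export
box_abs_to_norm <- function(abs_boxes, width, height) {
  cls <- if ("class_id" %in% names(abs_boxes)) abs_boxes$class_id else 0L
  data.frame(class_id = as.integer(rep_len(cls, nrow(abs_boxes))),
             cx = (abs_boxes$x1 + abs_boxes$x2) / 2 / width,
             cy = (abs_boxes$y1 + abs_boxes$y2) / 2 / height,
             w = (abs_boxes$x2 - abs_boxes$x1) / width,
             h = (abs_boxes$y2 - abs_boxes$y1) / height)
}

#' Clip normalized boxes to the unit frame and drop degenerate ones
#'
#' Corners are clipped to `[0, 1]`; boxes whose width or height collapses to
#' zero after clipping break IoU computations and are dropped. The number of
#' dropped boxes is attached as attribute `"dropped"`.
#'
#' @param boxes Normalized box `data.frame`.
#' @param min_area Minimum normalized area kept after clipping.
#' @return Clipped box `data.frame` with attribute `"dropped"`.
#' @export
clip_norm_boxes <- function(boxes, min_area = 0) {
  if (nrow(boxes) == 0) {
    attr(boxes, "dropped") <- 0L
    return(boxes)
  }
  x1 <- pmax(0, boxes$cx - boxes$w / 2); x2 <- pmin(1, boxes$cx + boxes$w / 2)
  y1 <- pmax(0, boxes$cy - boxes$h / 2); y2 <- pmin(1, boxes$cy + boxes$h / 2)
  w <- x2 - x1; h <- y2 - y1
  keep <- w > 0 & h > 0 & (w * h) >= min_area
  out <- data.frame(class_id = boxes$class_id[keep],
                    cx = (x1 + x2)[keep] / 2, cy = (y1 + y2)[keep] / 2,
                    w = w[keep], h = h[keep])
  attr(out, "dropped") <- sum(!keep)
  out
}
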