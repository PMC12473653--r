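#' Bounding-box regression losses: IoU, CIoU, SIoU and Focal variants
#'
#' Boxes are absolute corner boxes `(x1, y1, x2, y2)` with `x2 > x1`,
#' `y2 > y1`, supplied as length-4 vectors or `n x 4` matrices. The SIoU
#' loss augments `1 - IoU` with an angle cost (how far the center offset is
#' from an axis), a distance cost modulated by that angle, and a shape cost
#' on the width/height mismatch:
#' `L = 1 - IoU + (Delta + Omega) / 2`.
#' The Focal variants multiply a base loss by `-(1 - IoU)^tau * log(IoU)`,
#' down-weighting easy (high-IoU) pairs.
#'
#' @name losses
NULL

as_box_matrix <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  b <- as.matrix(b)
  stopifnot(ncol(b) == 4)
  if (any(!is.finite(b))) stop("non-finite box coordinates")
  if (any(b[, 3] <= b[, 1] | b[, 4] <= b[, 2]))
    stop("degenerate box: require x2 > x1 and y2 > y1")
  b
}

#' Intersection over union of corner boxes
#'
#' @param a,b Boxes as length-4 vectors `(x1, y1, x2, y2)` or `n x 4`
#'   matrices (rows are paired).
#' @return Numeric vector of IoU values in `[0, 1]`; 0 for disjoint pairs.
#' @export
#' @examples
#' box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
box_iou <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  iw <- pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1])
  ih <- pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  union <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2]) +
    (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) - inter
  inter / union
}

box_geom <- function(b) {
  list(cx = (b[, 1] + b[, 3]) / 2, cy = (b[, 2] + b[, 4]) / 2,
       w = b[, 3] - b[, 1], h = b[, 4] - b[, 2])
}

#' SIoU angle cost
#'
#' `Lambda = 1 - 2 sin^2(arcsin(x) - pi/4)` with `x = c_h / sigma`, the
#' sine of the angle between the center line and the horizontal axis
#' (`c_h` = absolute vertical center offset, `sigma` = Euclidean center
#' distance). Zero when the centers are axis-aligned, one on the 45-degree
#' diagonal; coincident centers define `Lambda = 0`.
#'
#' @inheritParams box_iou
#' @return Numeric vector in `[0, 1]`.
#' @export
angle_cost <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  ga <- box_geom(a); gb <- box_geom(b)
  dx <- gb$cx - ga$cx; dy <- gb$cy - ga$cy
  sigma <- sqrt(dx^2 + dy^2)
  x <- ifelse(sigma > 0, abs(dy) / sigma, 0)
  ifelse(sigma > 0, 1 - 2 * sin(asin(pmin(x, 1)) - pi / 4)^2, 0)
}

#' SIoU distance cost
#'
#' `Delta = sum_t (1 - exp(-gamma * rho_t))` with `gamma = 2 - Lambda` and
#' `rho_x = ((gt_cx - cx) / c_w)^2` (`c_w`, `c_h` the enclosing-box
#' dimensions). `paper_literal = TRUE` uses the unsquared ratio instead of
#' the squared one.
#'
#' @inheritParams box_iou
#' @param lambda Angle cost; computed from the boxes when missing.
#' @param paper_literal Use the unsquared `rho` ratios.
#' @return Numeric vector in `[0, 2]` (canonical form).
#' @export
distance_cost <- function(a, b, lambda = NULL, paper_literal = FALSE) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  if (is.null(lambda)) lambda <- angle_cost(a, b)
  ga <- box_geom(a); gb <- box_geom(b)
  cw <- pmax(a[, 3], b[, 3]) - pmin(a[, 1], b[, 1])
  ch <- pmax(a[, 4], b[, 4]) - pmin(a[, 2], b[, 2])
  rx <- (gb$cx - ga$cx) / cw
  ry <- (gb$cy - ga$cy) / ch
  if (!paper_literal) { rx <- rx^2; ry <- ry^2 }
  gamma <- 2 - lambda
  (1 - exp(-gamma * rx)) + (1 - exp(-gamma * ry))
}

#' SIoU shape cost
#'
#' `Omega = sum_t (1 - exp(-varpi_t))^theta` with
#' `varpi_w = |w - w_gt| / max(w, w_gt)` (and the analogous height term);
#' symmetric in the two boxes.
#'
#' @inheritParams box_iou
#' @param theta Shape exponent (default 1).
#' @return Numeric vector in `[0, 2]` for `theta = 1`.
#' @export
shape_cost <- function(a, b, theta = 1) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  ga <- box_geom(a); gb <- box_geom(b)
  vw <- abs(ga$w - gb$w) / pmax(ga$w, gb$w)
  vh <- abs(ga$h - gb$h) / pmax(ga$h, gb$h)
  (1 - exp(-vw))^theta + (1 - exp(-vh))^theta
}

#' Loss configuration for the IoU family
#'
#' @param variant One of `"iou"`, `"ciou"`, `"siou"`, `"focal_iou"`,
#'   `"focal_ciou"`, `"focal_siou"`.
#' @param theta Shape-cost exponent (> 0).
#' @param tau Focal balancing exponent (>= 0).
#' @param eps Positive clamp applied to the IoU before the focal log.
#' @param paper_literal Use the unsquared distance-cost ratios.
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(variant = c("focal_siou", "siou", "iou", "ciou",
                                    "focal_iou", "focal_ciou"),
                        theta = 1, tau = 0.5, eps = 1e-7,
                        paper_literal = FALSE) {
  variant <- match.arg(variant)
  stopifnot(theta > 0, tau >= 0, eps > 0)
  structure(list(variant = variant, theta = theta, tau = tau, eps = eps,
                 paper_literal = paper_literal), class = "loss_config")
}

#' SIoU loss
#'
#' `L = 1 - IoU + (Delta + Omega) / 2`; zero iff the boxes coincide.
#'
#' @inheritParams box_iou
#' @param cfg A [loss_config()] (its `theta` and `paper_literal` are used).
#' @return Numeric vector of losses (>= 0).
#' @export
siou_loss <- function(a, b, cfg = loss_config("siou")) {
  lam <- angle_cost(a, b)
  delta <- distance_cost(a, b, lam, paper_literal = cfg$paper_literal)
  omega <- shape_cost(a, b, theta = cfg$theta)
  1 - box_iou(a, b) + (delta + omega) / 2
}

#' Complete IoU (CIoU) loss
#'
#' `L = 1 - IoU + d^2 / c^2 + alpha v`, where `d` is the center distance,
#' `c` the enclosing-box diagonal, `v` the aspect-ratio consistency term
#' `(4 / pi^2) (atan(w_gt / h_gt) - atan(w / h))^2` and
#' `alpha = v / (1 - IoU + v)`.
#'
#' @inheritParams box_iou
#' @param eps Stabilizer added to the `alpha` denominator.
#' @return Numeric vector of losses (>= 0).
#' @export
ciou_loss <- function(a, b, eps = 1e-9) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  iou <- box_iou(a, b)
  ga <- box_geom(a); gb <- box_geom(b)
  d2 <- (gb$cx - ga$cx)^2 + (gb$cy - ga$cy)^2
  cw <- pmax(a[, 3], b[, 3]) - pmin(a[, 1], b[, 1])
  ch <- pmax(a[, 4], b[, 4]) - pmin(a[, 2], b[, 2])
  c2 <- cw^2 + ch^2
  v <- 4 / pi^2 * (atan(gb$w / gb$h) - atan(ga$w / ga$h))^2
  alpha <- v / (1 - iou + v + eps)
  1 - iou + d2 / c2 + alpha * v
}

#' Focal weighting of a base loss
#'
#' `L_focal = -(1 - IoU)^tau * log(IoU) * base`; zero at IoU = 1, finite
#' for IoU >= eps (natural logarithm).
#'
#' @param base_loss Base loss values.
#' @param iou IoU values in `[0, 1]`.
#' @param cfg A [loss_config()] (its `tau` and `eps` are used).
#' @return Weighted losses.
#' @export
focal_weighted <- function(base_loss, iou, cfg = loss_config()) {
  focal_weight(iou, cfg) * base_loss
}

#' @rdname focal_weighted
#' @export
focal_weight <- function(iou, cfg = loss_config()) {
  i <- pmin(pmax(iou, cfg$eps), 1)
  -(1 - i)^cfg$tau * log(i)
}

#' Dispatch a box-regression loss by variant
#'
#' @inheritParams box_iou
#' @param cfg A [loss_config()].
#' @return Numeric vector of per-pair losses.
#' @export
box_loss <- function(a, b, cfg = loss_config()) {
  iou <- box_iou(a, b)
  base <- switch(sub("^focal_", "", cfg$variant),
                 iou = 1 - iou,
                 ciou = ciou_loss(a, b),
                 siou = siou_loss(a, b, cfg))
  if (grepl("^focal_", cfg$variant)) focal_weighted(base, iou, cfg) else base
}

#' Mean loss over matched prediction/target pairs
#'
#' @param preds,targets `n x 4` corner-box matrices, rows paired.
#' @param cfg A [loss_config()].
#' @return A list with `loss` (mean) and `per_pair`.
#' @export
batch_box_loss <- function(preds, targets, cfg = loss_config()) {
  preds <- as_box_matrix(preds); targets <- as_box_matrix(targets)
  if (nrow(preds) != nrow(targets))
    stop("preds and targets must have the same number of rows")
  pp <- box_loss(preds, targets, cfg)
  list(loss = mean(pp), per_pair = pp)
}

# ---- analytic gradients -------------------------------------------------

# gradient of IoU w.r.t. the predicted box (x1, y1, x2, y2); gt fixed
iou_grad <- function(p, g) {
  iw <- min(p[3], g[3]) - max(p[1], g[1])
  ih <- min(p[4], g[4]) - max(p[2], g[2])
  w <- p[3] - p[1]; h <- p[4] - p[2]
  ag <- (g[3] - g[1]) * (g[4] - g[2])
  if (iw <= 0 || ih <= 0) {
    inter <- 0; d_inter <- numeric(4)
  } else {
    inter <- iw * ih
    d_iw <- c(-(p[1] > g[1]), 0, (p[3] < g[3]), 0)
    d_ih <- c(0, -(p[2] > g[2]), 0, (p[4] < g[4]))
    d_inter <- ih * d_iw + iw * d_ih
  }
  u <- w * h + ag - inter
  d_area <- c(-h, -w, h, w)
  d_u <- d_area - d_inter
  iou <- inter / u
  list(value = iou, grad = (d_inter * u - inter * d_u) / u^2)
}

siou_grad_terms <- function(p, g, theta = 1) {
  d_cx <- c(0.5, 0, 0.5, 0); d_cy <- c(0, 0.5, 0, 0.5)
  d_w <- c(-1, 0, 1, 0); d_h <- c(0, -1, 0, 1)
  cx <- (p[1] + p[3]) / 2; cy <- (p[2] + p[4]) / 2
  w <- p[3] - p[1]; h <- p[4] - p[2]
  gcx <- (g[1] + g[3]) / 2; gcy <- (g[2] + g[4]) / 2
  gw <- g[3] - g[1]; gh <- g[4] - g[2]
  dxc <- gcx - cx; dyc <- gcy - cy
  sigma <- sqrt(dxc^2 + dyc^2)
  # Lambda = 2 x sqrt(1 - x^2), x = |dyc| / sigma
  if (sigma > 0) {
    x <- min(abs(dyc) / sigma, 1 - 1e-12)
    lambda <- 2 * x * sqrt(1 - x^2)
    dlam_dx <- 2 * (1 - 2 * x^2) / sqrt(1 - x^2)
    dx_ddxc <- -abs(dyc) * dxc / sigma^3
    dx_ddyc <- sign(dyc) / sigma - abs(dyc) * dyc / sigma^3
    d_lambda <- dlam_dx * (dx_ddxc * (-d_cx) + dx_ddyc * (-d_cy))
  } else {
    lambda <- 0; d_lambda <- numeric(4)
  }
  cw <- max(p[3], g[3]) - min(p[1], g[1])
  ch <- max(p[4], g[4]) - min(p[2], g[2])
  d_cw <- c(-(p[1] < g[1]), 0, (p[3] > g[3]), 0)
  d_ch <- c(0, -(p[2] < g[2]), 0, (p[4] > g[4]))
  rx <- (dxc / cw)^2; ry <- (dyc / ch)^2
  d_rx <- 2 * (dxc / cw) * ((-d_cx) / cw - dxc * d_cw / cw^2)
  d_ry <- 2 * (dyc / ch) * ((-d_cy) / ch - dyc * d_ch / ch^2)
  gam <- 2 - lambda; d_gam <- -d_lambda
  delta <- (1 - exp(-gam * rx)) + (1 - exp(-gam * ry))
  d_delta <- exp(-gam * rx) * (gam * d_rx + rx * d_gam) +
    exp(-gam * ry) * (gam * d_ry + ry * d_gam)
  mw <- max(w, gw); mh <- max(h, gh)
  vw <- abs(w - gw) / mw; vh <- abs(h - gh) / mh
  d_vw <- (sign(w - gw) / mw - abs(w - gw) * (w > gw) / mw^2) * d_w
  d_vh <- (sign(h - gh) / mh - abs(h - gh) * (h > gh) / mh^2) * d_h
  omega <- (1 - exp(-vw))^theta + (1 - exp(-vh))^theta
  d_omega <- theta * (1 - exp(-vw))^(theta - 1) * exp(-vw) * d_vw +
    theta * (1 - exp(-vh))^(theta - 1) * exp(-vh) * d_vh
  list(delta = delta, d_delta = d_delta, omega = omega, d_omega = d_omega)
}

#' Analytic gradient of a box loss w.r.t. the predicted box
#'
#' Supported variants: `"iou"`, `"siou"`, `"focal_siou"` (the canonical,
#' squared distance-cost form). The loss is piecewise smooth; at the measure-
#' zero kinks (equal corners, equal widths, axis-aligned centers) a
#' one-sided derivative is returned.
#'
#' @param pred,gt Length-4 corner boxes `(x1, y1, x2, y2)`.
#' @param cfg A [loss_config()].
#' @return A list with `loss` and `grad` (length-4 vector).
#' @export
box_loss_grad <- function(pred, gt, cfg = loss_config()) {
  stopifnot(length(pred) == 4, length(gt) == 4)
  if (cfg$paper_literal)
    stop("analytic gradients are provided for the canonical form only")
  ig <- iou_grad(pred, gt)
  base_variant <- sub("^focal_", "", cfg$variant)
  if (base_variant == "iou") {
    base <- 1 - ig$value; d_base <- -ig$grad
  } else if (base_variant == "siou") {
    st <- siou_grad_terms(pred, gt, cfg$theta)
    base <- 1 - ig$value + (st$delta + st$omega) / 2
    d_base <- -ig$grad + (st$d_delta + st$d_omega) / 2
  } else {
    stop("analytic gradient not implemented for variant ", cfg$variant)
  }
  if (!grepl("^focal_", cfg$variant))
    return(list(loss = base, grad = d_base))
  i <- min(max(ig$value, cfg$eps), 1)
  fw <- -(1 - i)^cfg$tau * log(i)
  dfw_di <- if (cfg$tau == 0) -1 / i
            else cfg$tau * (1 - i)^(cfg$tau - 1) * log(i) - (1 - i)^cfg$tau / i
  list(loss = fw * base, grad = dfw_di * ig$grad * base + fw * d_base)
}
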