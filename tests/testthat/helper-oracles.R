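# Independent oracle implementations used across the test files. These are
# deliberately written from first principles (naive loops, exact cell
# counting, direct equation transcription) rather than sharing code with the
# package, so agreement is meaningful.

# Naive same-padded 2-D convolution with zero padding (quadruple loop).
brute_conv2d <- function(m, kernel, dilation = 1) {
  h <- nrow(m); w <- ncol(m)
  kh <- nrow(kernel); kw <- ncol(kernel)
  ci <- (kh + 1) / 2; cj <- (kw + 1) / 2
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    acc <- 0
    for (a in 1:kh) for (b in 1:kw) {
      ii <- i + (a - ci) * dilation
      jj <- j + (b - cj) * dilation
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w)
        acc <- acc + kernel[a, b] * m[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# Exact IoU of integer-coordinate corner boxes by counting unit raster cells.
raster_iou <- function(a, b) {
  cells <- function(bx) {
    if (bx[3] <= bx[1] || bx[4] <= bx[2]) return(character(0))
    g <- expand.grid(x = seq(bx[1], bx[3] - 1), y = seq(bx[2], bx[4] - 1))
    paste(g$x, g$y)
  }
  ca <- cells(a); cb <- cells(b)
  u <- length(union(ca, cb))
  if (u == 0) 0 else length(intersect(ca, cb)) / u
}

# Direct transcription of the SIoU angle/distance/shape equations plus the
# focal weighting, taking the IoU value as an input.
scripted_siou <- function(p, g, iou, theta = 1, tau = 0.5, eps = 1e-7,
                          focal = FALSE) {
  pcx <- (p[1] + p[3]) / 2; pcy <- (p[2] + p[4]) / 2
  gcx <- (g[1] + g[3]) / 2; gcy <- (g[2] + g[4]) / 2
  pw <- p[3] - p[1]; ph <- p[4] - p[2]
  gw <- g[3] - g[1]; gh <- g[4] - g[2]
  sigma <- sqrt((gcx - pcx)^2 + (gcy - pcy)^2)
  lam <- if (sigma == 0) 0 else {
    sin_alpha <- min(abs(gcy - pcy) / sigma, 1)
    1 - 2 * sin(asin(sin_alpha) - pi / 4)^2
  }
  cw <- max(p[3], g[3]) - min(p[1], g[1])
  chh <- max(p[4], g[4]) - min(p[2], g[2])
  gam <- 2 - lam
  delta <- (1 - exp(-gam * ((gcx - pcx) / cw)^2)) +
           (1 - exp(-gam * ((gcy - pcy) / chh)^2))
  omega <- (1 - exp(-abs(pw - gw) / max(pw, gw)))^theta +
           (1 - exp(-abs(ph - gh) / max(ph, gh)))^theta
  base <- 1 - iou + (delta + omega) / 2
  if (!focal) return(base)
  i <- min(max(iou, eps), 1)
  (-(1 - i)^tau * log(i)) * base
}

# Interpolated average precision straight from its definition: for every
# achieved recall level, the interpolated precision is the maximum precision
# at any prefix reaching at least that recall.
ap_oracle <- function(tp, n_truth) {
  if (length(tp) == 0 || sum(tp) == 0) return(0)
  prec <- cumsum(tp) / seq_along(tp)
  rec <- cumsum(tp) / n_truth
  ap <- 0; prev_r <- 0
  for (k in seq_along(tp)) {
    if (!tp[k]) next
    r <- rec[k]
    ap <- ap + (r - prev_r) * max(prec[rec >= r])
    prev_r <- r
  }
  ap
}

# Random non-degenerate integer-coordinate box in [0, lim]^2.
rand_int_box <- function(lim = 64) {
  repeat {
    x <- sort(sample(0:lim, 2)); y <- sort(sample(0:lim, 2))
    if (x[1] < x[2] && y[1] < y[2]) return(c(x[1], y[1], x[2], y[2]))
  }
}
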