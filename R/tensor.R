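#' Feature tensors and convolution primitives
#'
#' Feature maps are 4-axis arrays with semantic layout `(B, C, H, W)`:
#' `x[b, c, , ]` is the `H x W` spatial plane of channel `c` in sample `b`.
#' The convolution primitives below are same-padded (zero padding), stride 1,
#' and implemented as vectorized shift-and-add over kernel taps, which is
#' exact and fast for the small kernels the attention block uses.
#'
#' @param values Numeric vector or array of length `B*C*H*W`.
#' @param dim Integer vector `c(B, C, H, W)`.
#' @return A numeric array with class-free `(B, C, H, W)` layout.
#' @export
feature_tensor <- function(values, dim) {
  stopifnot(length(dim) == 4, length(values) == prod(dim))
  array(as.numeric(values), dim = dim)
}

# Zero-padded shift of a matrix: entry (i, j) of the result is
# m[i + di, j + dj] when that index exists, else 0.
shift_mat <- function(m, di, dj) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  i0 <- max(1, 1 - di); i1 <- min(h, h - di)
  j0 <- max(1, 1 - dj); j1 <- min(w, w - dj)
  if (i0 <= i1 && j0 <= j1)
    out[i0:i1, j0:j1] <- m[(i0:i1) + di, (j0:j1) + dj, drop = FALSE]
  out
}

#' Single-plane 2-D convolution (correlation), same-padded
#'
#' @param m `H x W` numeric matrix.
#' @param kernel `kh x kw` numeric matrix.
#' @param dilation Integer dilation rate.
#' @return `H x W` matrix.
#' @export
conv2d_plane <- function(m, kernel, dilation = 1L) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  ci <- (kh + 1) / 2; cj <- (kw + 1) / 2
  if (kh %% 2 == 0 || kw %% 2 == 0)
    stop("kernels must have odd extents for same padding")
  out <- matrix(0, nrow(m), ncol(m))
  for (a in seq_len(kh)) for (b in seq_len(kw)) {
    wgt <- kernel[a, b]
    if (wgt != 0)
      out <- out + wgt * shift_mat(m, (a - ci) * dilation, (b - cj) * dilation)
  }
  out
}

#' Depthwise convolution over a feature tensor
#'
#' Each channel is convolved with its own kernel (`groups = C`), the layout
#' the attention block uses for every spatial convolution.
#'
#' @param x `(B, C, H, W)` tensor.
#' @param kernels `(C, kh, kw)` array of per-channel kernels.
#' @param bias Length-`C` bias vector (default zeros).
#' @param dilation Integer dilation rate.
#' @return `(B, C, H, W)` tensor.
#' @export
conv2d_depthwise <- function(x, kernels, bias = NULL, dilation = 1L) {
  d <- dim(x)
  stopifnot(dim(kernels)[1] == d[2])
  if (is.null(bias)) bias <- numeric(d[2])
  out <- array(0, dim = d)
  for (b in seq_len(d[1])) for (c in seq_len(d[2])) {
    k <- matrix(kernels[c, , ], dim(kernels)[2], dim(kernels)[3])
    out[b, c, , ] <- conv2d_plane(x[b, c, , ], k, dilation) + bias[c]
  }
  out
}

#' Full (channel-mixing) convolution over a feature tensor
#'
#' @param x `(B, Cin, H, W)` tensor.
#' @param weights `(Cout, Cin, kh, kw)` array.
#' @param bias Length-`Cout` bias vector (default zeros).
#' @param dilation Integer dilation rate.
#' @return `(B, Cout, H, W)` tensor.
#' @export
conv2d_full <- function(x, weights, bias = NULL, dilation = 1L) {
  d <- dim(x); dw <- dim(weights)
  stopifnot(dw[2] == d[2])
  if (is.null(bias)) bias <- numeric(dw[1])
  out <- array(0, dim = c(d[1], dw[1], d[3], d[4]))
  for (b in seq_len(d[1])) for (co in seq_len(dw[1])) {
    acc <- matrix(bias[co], d[3], d[4])
    for (ci in seq_len(d[2])) {
      k <- matrix(weights[co, ci, , ], dw[3], dw[4])
      acc <- acc + conv2d_plane(x[b, ci, , ], k, dilation)
    }
    out[b, co, , ] <- acc
  }
  out
}

#' Bilinear sampling of a matrix at fractional coordinates
#'
#' Samples `m` at 0-based positions `(y, x)`; positions outside the grid
#' contribute zero (zero padding), matching the convention of both the
#' geometric augmentation warp and the deformable convolution.
#'
#' @param m `H x W` numeric matrix.
#' @param y,x Numeric vectors/matrices of 0-based row/column coordinates.
#' @return Sampled values with the shape of `y`.
#' @export
bilinear_sample <- function(m, y, x) {
  h <- nrow(m); w <- ncol(m)
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  val <- function(yi, xi) {
    inside <- yi >= 0 & yi <= (h - 1) & xi >= 0 & xi <= (w - 1)
    idx <- (pmin(pmax(xi, 0), w - 1)) * h + pmin(pmax(yi, 0), h - 1) + 1
    v <- m[idx]
    v[!inside] <- 0
    v
  }
  out <- val(y0, x0) * (1 - fy) * (1 - fx) +
    val(y0, x0 + 1) * (1 - fy) * fx +
    val(y0 + 1, x0) * fy * (1 - fx) +
    val(y0 + 1, x0 + 1) * fy * fx
  if (!is.null(dim(y))) dim(out) <- dim(y)
  out
}

#' Separable Gaussian blur of a matrix
#'
#' Truncated at three standard deviations; `sigma = 0` returns the input
#' unchanged. Built on the package's own same-padded convolution primitive.
#'
#' @param m `H x W` numeric matrix.
#' @param sigma Standard deviation in pixels.
#' @return Blurred `H x W` matrix.
#' @export
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(z) conv2d_plane(conv2d_plane(z, matrix(k, ncol = 1)),
                                    matrix(k, nrow = 1))
  # normalized convolution: renormalize by the blurred all-ones mask so the
  # zero padding does not darken image borders
  blur1(m) / blur1(matrix(1, nrow(m), ncol(m)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))
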