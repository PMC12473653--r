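#' Configuration of the Bone-MSCA attention block
#'
#' Bone-MSCA is a multi-scale convolutional attention block tailored to
#' fracture-like image structure: long directional strip convolutions (1x21
#' and 21x1) respond to elongated bone contours, two dilated 7x7
#' convolutions cover oblique fracture lines at receptive fields `1 + 6 d`,
#' a deformable 3x3 convolution adapts sampling positions to irregular
#' fracture geometry, a fixed Sobel gate amplifies edge responses, a
#' squeeze-and-excitation (SE) stage recalibrates channels, and a residual
#' connection preserves the input. All spatial convolutions are depthwise by
#' default, which is what keeps the block within a ~0.11M parameter budget
#' at 256 channels.
#'
#' @param channels Number of feature channels `C`.
#' @param strip_length Extent of the directional strip kernels.
#' @param diag_kernel Extent of the dilated square kernels.
#' @param dilations Two dilation rates for the square kernels.
#' @param se_reduction SE bottleneck divisor (C must be divisible by it).
#' @param offset_groups Number of offset groups of the deformable stage
#'   (offsets are shared across the channels of a group).
#' @param depthwise Use depthwise (groups = C) spatial convolutions.
#' @param sobel_mode `"magnitude"` gates on `|Gx| + |Gy|`; `"single"` uses
#'   the horizontal kernel alone.
#' @return A list of class `bone_msca_config`.
#' @export
bone_msca_config <- function(channels, strip_length = 21L, diag_kernel = 7L,
                             dilations = c(2L, 3L), se_reduction = 4L,
                             offset_groups = 1L, depthwise = TRUE,
                             sobel_mode = c("magnitude", "single")) {
  sobel_mode <- match.arg(sobel_mode)
  stopifnot(channels %% se_reduction == 0, all(dilations >= 1),
            strip_length %% 2 == 1, diag_kernel %% 2 == 1,
            channels %% offset_groups == 0)
  structure(list(channels = as.integer(channels),
                 strip_length = as.integer(strip_length),
                 diag_kernel = as.integer(diag_kernel),
                 dilations = as.integer(dilations),
                 se_reduction = as.integer(se_reduction),
                 offset_groups = as.integer(offset_groups),
                 depthwise = isTRUE(depthwise), sobel_mode = sobel_mode),
            class = "bone_msca_config")
}

#' Instantiate a Bone-MSCA block with random weights
#'
#' Weights are drawn from centred normals scaled by `1/sqrt(fan-in)`;
#' biases start at zero. The fixed Sobel kernels carry no trainable
#' parameters.
#'
#' @param cfg A [bone_msca_config()], or a channel count.
#' @param seed Integer seed for the initialization.
#' @return A list of class `bone_msca` with elements `cfg` and `weights`.
#' @export
bone_msca <- function(cfg, seed = 0L) {
  if (is.numeric(cfg)) cfg <- bone_msca_config(cfg)
  stopifnot(inherits(cfg, "bone_msca_config"))
  C <- cfg$channels; L <- cfg$strip_length; K <- cfg$diag_kernel
  r <- cfg$se_reduction; noff <- 2L * 9L * cfg$offset_groups
  cin <- if (cfg$depthwise) 1L else C
  rnd <- function(dims, fan) array(rnorm(prod(dims), 0, 1 / sqrt(fan)), dim = dims)
  weights <- with_seed(seed, list(
    vert = rnd(c(C, cin, 1, L), cin * L), vert_b = numeric(C),
    hori = rnd(c(C, cin, L, 1), cin * L), hori_b = numeric(C),
    diag1 = rnd(c(C, cin, K, K), cin * K^2), diag1_b = numeric(C),
    diag2 = rnd(c(C, cin, K, K), cin * K^2), diag2_b = numeric(C),
    offset = rnd(c(noff, C, 3, 3), C * 9), offset_b = numeric(noff),
    deform = rnd(c(C, cin, 3, 3), cin * 9), deform_b = numeric(C),
    se_w1 = rnd(c(C / r, C), C), se_b1 = numeric(C / r),
    se_w2 = rnd(c(C, C / r), C / r), se_b2 = numeric(C)))
  structure(list(cfg = cfg, weights = weights), class = "bone_msca")
}

conv_spatial <- function(x, w, b, dilation, depthwise) {
  if (depthwise) {
    d <- dim(w)
    conv2d_depthwise(x, array(w, dim = c(d[1], d[3], d[4])), b, dilation)
  } else {
    conv2d_full(x, w, b, dilation)
  }
}

#' Directional multi-scale fusion stage
#'
#' `Fuse = Vert + Hori + Diag`, where `Vert` and `Hori` are the 1x21 / 21x1
#' strip convolutions and `Diag` is the sum of the two dilated square
#' convolutions. All stages are same-padded, so spatial dimensions are
#' preserved.
#'
#' @param block A [bone_msca()] block.
#' @param x `(B, C, H, W)` tensor with `C = block$cfg$channels`.
#' @return `(B, C, H, W)` tensor.
#' @export
directional_fuse <- function(block, x) {
  cfg <- block$cfg; w <- block$weights
  if (dim(x)[2] != cfg$channels)
    stop("input has ", dim(x)[2], " channels; block expects ", cfg$channels)
  vert <- conv_spatial(x, w$vert, w$vert_b, 1L, cfg$depthwise)
  hori <- conv_spatial(x, w$hori, w$hori_b, 1L, cfg$depthwise)
  diag1 <- conv_spatial(x, w$diag1, w$diag1_b, cfg$dilations[1], cfg$depthwise)
  diag2 <- conv_spatial(x, w$diag2, w$diag2_b, cfg$dilations[2], cfg$depthwise)
  vert + hori + diag1 + diag2
}

#' Depthwise deformable 3x3 convolution with shared offsets
#'
#' Offsets are per-position, per-kernel-tap `(dy, dx)` pairs (channel
#' `2k - 1` holds the row offset of tap `k`, channel `2k` the column
#' offset; taps are enumerated row-major). Sampling is bilinear with zero
#' padding, so zero offsets reduce the operator exactly to an ordinary
#' same-padded 3x3 convolution.
#'
#' @param x `(B, C, H, W)` tensor.
#' @param offsets `(B, 2 * 9 * G, H, W)` tensor of offsets.
#' @param w Kernel array `(C, cin, 3, 3)`.
#' @param b Length-`C` bias.
#' @param depthwise Depthwise (`cin = 1`) or full convolution.
#' @return `(B, C, H, W)` tensor.
#' @export
deform_conv3x3 <- function(x, offsets, w, b = NULL, depthwise = TRUE) {
  d <- dim(x)
  C <- dim(w)[1]
  G <- dim(offsets)[2] / 18L
  if (is.null(b)) b <- numeric(C)
  out <- array(0, dim = c(d[1], C, d[3], d[4]))
  base_y <- matrix(rep(0:(d[3] - 1), times = d[4]), d[3], d[4])
  base_x <- matrix(rep(0:(d[4] - 1), each = d[3]), d[3], d[4])
  gsize <- C / G
  for (bb in seq_len(d[1])) {
    for (co in seq_len(C)) {
      g <- ((co - 1) %/% gsize)
      acc <- matrix(b[co], d[3], d[4])
      for (a in 1:3) for (bcol in 1:3) {
        k <- (a - 1) * 3 + bcol
        dy <- offsets[bb, g * 18 + 2 * k - 1, , ]
        dx <- offsets[bb, g * 18 + 2 * k, , ]
        sy <- base_y + (a - 2) + dy
        sx <- base_x + (bcol - 2) + dx
        if (depthwise) {
          acc <- acc + w[co, 1, a, bcol] * bilinear_sample(x[bb, co, , ], sy, sx)
        } else {
          for (ci in seq_len(d[2]))
            acc <- acc + w[co, ci, a, bcol] * bilinear_sample(x[bb, ci, , ], sy, sx)
        }
      }
      out[bb, co, , ] <- acc
    }
  }
  out
}

#' Deformable stage of the block
#'
#' A plain 3x3 convolution predicts the offsets from the fused features;
#' the deformable convolution then samples the fused features at those
#' offset positions.
#'
#' @param block A [bone_msca()] block.
#' @param fuse `(B, C, H, W)` output of [directional_fuse()].
#' @return `(B, C, H, W)` tensor.
#' @export
deformable_stage <- function(block, fuse) {
  w <- block$weights
  offsets <- conv2d_full(fuse, w$offset, w$offset_b)
  deform_conv3x3(fuse, offsets, w$deform, w$deform_b,
                 depthwise = block$cfg$depthwise)
}

sobel_kernels <- function() {
  gx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  list(gx = gx, gy = t(gx))
}

#' Sobel edge gating stage
#'
#' Computes a fixed (non-trainable) depthwise Sobel response of the block
#' input, squashes it through a sigmoid, and multiplies the deformable
#' features by `1 + edge_map`. With the default magnitude mode the gate
#' lies in `[1.5, 2)`: flat regions pass with factor 1.5
#' (`sigmoid(0) = 0.5`), edges are amplified towards 2.
#'
#' @param block A [bone_msca()] block.
#' @param x Block input `(B, C, H, W)`.
#' @param deform_feat `(B, C, H, W)` output of [deformable_stage()].
#' @param return_map Also return the edge map.
#' @return `(B, C, H, W)` tensor, or a list with `enhanced` and `edge_map`.
#' @export
edge_enhance <- function(block, x, deform_feat, return_map = FALSE) {
  d <- dim(x)
  sk <- sobel_kernels()
  kx <- array(rep(sk$gx, each = d[2]), dim = c(d[2], 3, 3))
  ky <- array(rep(sk$gy, each = d[2]), dim = c(d[2], 3, 3))
  gx <- conv2d_depthwise(x, kx)
  resp <- if (block$cfg$sobel_mode == "magnitude")
    abs(gx) + abs(conv2d_depthwise(x, ky)) else gx
  edge_map <- sigmoid(resp)
  enhanced <- deform_feat * (1 + edge_map)
  if (return_map) list(enhanced = enhanced, edge_map = edge_map) else enhanced
}

#' Squeeze-and-excitation channel recalibration
#'
#' Global average pooling per channel, a two-layer bottleneck
#' (`C -> C/r -> C`) with ReLU then sigmoid, and per-channel scaling of the
#' input features.
#'
#' @param block A [bone_msca()] block.
#' @param enhanced `(B, C, H, W)` output of [edge_enhance()].
#' @param return_scale Also return the per-channel scale `s`.
#' @return `(B, C, H, W)` tensor, or a list with `refined` and `scale`.
#' @export
channel_recalibrate <- function(block, enhanced, return_scale = FALSE) {
  w <- block$weights
  d <- dim(enhanced)
  out <- array(0, dim = d)
  scales <- matrix(0, d[1], d[2])
  for (bb in seq_len(d[1])) {
    z <- vapply(seq_len(d[2]), function(c) mean(enhanced[bb, c, , ]), 0)
    s1 <- pmax(as.numeric(w$se_w1 %*% z) + w$se_b1, 0)
    s <- sigmoid(as.numeric(w$se_w2 %*% s1) + w$se_b2)
    scales[bb, ] <- s
    for (c in seq_len(d[2])) out[bb, c, , ] <- enhanced[bb, c, , ] * s[c]
  }
  if (return_scale) list(refined = out, scale = scales) else out
}

#' Forward pass of the Bone-MSCA block
#'
#' `output = X + refined_feat`, where `refined_feat` is the result of the
#' directional fusion, deformable, edge-gating and SE stages. Spatial and
#' channel dimensions are preserved throughout.
#'
#' @param block A [bone_msca()] block.
#' @param x `(B, C, H, W)` tensor.
#' @param intermediates Return all stage outputs as a list.
#' @return `(B, C, H, W)` tensor, or a list when `intermediates = TRUE`.
#' @export
bone_msca_forward <- function(block, x, intermediates = FALSE) {
  fuse <- directional_fuse(block, x)
  deform <- deformable_stage(block, fuse)
  ee <- edge_enhance(block, x, deform, return_map = TRUE)
  refined <- channel_recalibrate(block, ee$enhanced)
  output <- x + refined
  if (intermediates)
    list(output = output, fuse = fuse, deform = deform,
         enhanced = ee$enhanced, edge_map = ee$edge_map, refined = refined)
  else output
}

#' Closed-form trainable parameter count of the block
#'
#' Sums, stage by stage: the two strip convolutions, the two dilated square
#' convolutions, the offset-predicting convolution, the deformable
#' convolution and the two SE maps, each with its bias. The fixed Sobel
#' kernels contribute nothing. Must agree exactly with introspection of an
#' instantiated block ([bone_msca_num_weights()]).
#'
#' @param cfg A [bone_msca_config()], or a channel count.
#' @return Integer parameter count.
#' @export
#' @examples
#' bone_msca_parameter_count(256)
bone_msca_parameter_count <- function(cfg) {
  if (is.numeric(cfg)) cfg <- bone_msca_config(cfg)
  C <- cfg$channels; L <- cfg$strip_length; K <- cfg$diag_kernel
  r <- cfg$se_reduction; G <- cfg$offset_groups
  cin <- if (cfg$depthwise) 1 else C
  strips <- 2 * (C * cin * L + C)
  diags <- 2 * (C * cin * K^2 + C)
  offset <- (2 * 9 * G) * C * 9 + 2 * 9 * G
  deform <- C * cin * 9 + C
  se <- C * (C / r) + C / r + (C / r) * C + C
  as.integer(strips + diags + offset + deform + se)
}

#' Parameter count by introspection of an instantiated block
#'
#' @param block A [bone_msca()] block.
#' @return Integer count of weight and bias elements.
#' @export
bone_msca_num_weights <- function(block) {
  sum(vapply(block$weights, length, 0L))
}

#' Multiply-accumulate count of one block forward pass
#'
#' Convolution and SE MACs at a given spatial size (used by the
#' architecture FLOP accounting; the fixed Sobel convolutions are counted
#' since they execute at run time).
#'
#' @param cfg A [bone_msca_config()], or a channel count.
#' @param height,width Spatial size of the feature map.
#' @return MAC count (double).
#' @export
bone_msca_macs <- function(cfg, height, width) {
  if (is.numeric(cfg)) cfg <- bone_msca_config(cfg)
  C <- cfg$channels; L <- cfg$strip_length; K <- cfg$diag_kernel
  r <- cfg$se_reduction; G <- cfg$offset_groups
  cin <- if (cfg$depthwise) 1 else C
  px <- height * width
  per_px <- 2 * C * cin * L + 2 * C * cin * K^2 +
    (2 * 9 * G) * C * 9 + C * cin * 9 +
    (if (cfg$sobel_mode == "magnitude") 2 else 1) * C * 9
  per_px * px + 2 * C * (C / r)
}

#' @export
print.bone_msca <- function(x, ...) {
  cat(sprintf("Bone-MSCA block: C=%d, strips %dx1/1x%d, diag %dx%d @ d=%s,\n",
              x$cfg$channels, x$cfg$strip_length, x$cfg$strip_length,
              x$cfg$diag_kernel, x$cfg$diag_kernel,
              paste(x$cfg$dilations, collapse = ",")),
      sprintf("  %s convs, SE r=%d, %d trainable parameters\n",
              if (x$cfg$depthwise) "depthwise" else "full",
              x$cfg$se_reduction, bone_msca_num_weights(x)))
  invisible(x)
}
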