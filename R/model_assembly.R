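#' Nano detector assembly and parameter/FLOP accounting
#'
#' Builds a structural description of the published YOLOv11 nano detection
#' architecture (backbone / neck / head, with the n-scale width 0.25 and
#' depth 0.5 multipliers) and, for the "bf" variant, inserts one Bone-MSCA
#' block after the final backbone stage (the 256-channel C2PSA output that
#' feeds the neck) -- the placement whose parameter budget matches the
#' published accounting of the fracture detector. Every convolution of
#' every module is enumerated explicitly, which yields exact trainable
#' parameter counts (both as trained, with batch-norm, and as deployed,
#' with batch-norm folded into the convolutions) and exact
#' multiply-accumulate counts at any input size.
#'
#' Reported figures follow the deployment convention of the detector
#' family: parameters of the fused model, and GFLOPs as twice the
#' convolution MAC count.
#'
#' @name model_assembly
NULL

conv_rec <- function(name, c1, c2, k, area, g = 1, bn = TRUE, bias = !bn,
                     trainable = TRUE, params_override = NA_real_,
                     macs_override = NA_real_) {
  data.frame(name = name, c1 = c1, c2 = c2, k = k, g = g, area = area,
             bn = bn, bias = bias, trainable = trainable,
             params_override = params_override,
             macs_override = macs_override)
}

# parameter-free resize; the profiling convention charges one op per
# output element
mod_upsample <- function(name, ch, s_out) {
  conv_rec(name, ch, ch, 0, s_out^2, bn = FALSE, bias = FALSE,
           params_override = 0, macs_override = ch * s_out^2)
}

# conv + batch-norm + activation unit ("Conv" in the detector family)
unit_conv <- function(name, c1, c2, k, s_out, g = 1) {
  conv_rec(name, c1, c2, k, s_out^2, g = g, bn = TRUE)
}

mod_bottleneck <- function(name, c1, c2, s, k = 3, e = 0.5) {
  ch <- floor(c2 * e)
  rbind(unit_conv(paste0(name, ".cv1"), c1, ch, k, s),
        unit_conv(paste0(name, ".cv2"), ch, c2, k, s))
}

mod_c3k <- function(name, c1, c2, s, n = 2) {
  ch <- floor(c2 * 0.5)
  out <- rbind(unit_conv(paste0(name, ".cv1"), c1, ch, 1, s),
               unit_conv(paste0(name, ".cv2"), c1, ch, 1, s),
               unit_conv(paste0(name, ".cv3"), 2 * ch, c2, 1, s))
  for (i in seq_len(n))
    out <- rbind(out, mod_bottleneck(paste0(name, ".m", i), ch, ch, s, e = 1))
  out
}

mod_c3k2 <- function(name, c1, c2, s, n = 1, c3k = FALSE, e = 0.5) {
  ch <- floor(c2 * e)
  out <- rbind(unit_conv(paste0(name, ".cv1"), c1, 2 * ch, 1, s),
               unit_conv(paste0(name, ".cv2"), (2 + n) * ch, c2, 1, s))
  for (i in seq_len(n)) {
    sub <- paste0(name, ".m", i)
    out <- rbind(out, if (c3k) mod_c3k(sub, ch, ch, s)
                      else mod_bottleneck(sub, ch, ch, s, e = 0.5))
  }
  out
}

mod_sppf <- function(name, c1, c2, s) {
  ch <- c1 %/% 2
  rbind(unit_conv(paste0(name, ".cv1"), c1, ch, 1, s),
        unit_conv(paste0(name, ".cv2"), 4 * ch, c2, 1, s))
}

mod_c2psa <- function(name, c1, s, n = 1) {
  ch <- c1 %/% 2
  num_heads <- ch %/% 64
  head_dim <- ch %/% num_heads
  key_dim <- floor(head_dim * 0.5)
  qkv_out <- ch + 2 * key_dim * num_heads
  out <- rbind(unit_conv(paste0(name, ".cv1"), c1, 2 * ch, 1, s),
               unit_conv(paste0(name, ".cv2"), 2 * ch, c1, 1, s))
  for (i in seq_len(n)) {
    sub <- paste0(name, ".m", i)
    out <- rbind(out,
      unit_conv(paste0(sub, ".attn.qkv"), ch, qkv_out, 1, s),
      unit_conv(paste0(sub, ".attn.proj"), ch, ch, 1, s),
      unit_conv(paste0(sub, ".attn.pe"), ch, ch, 3, s, g = ch),
      unit_conv(paste0(sub, ".ffn1"), ch, 2 * ch, 1, s),
      unit_conv(paste0(sub, ".ffn2"), 2 * ch, ch, 1, s))
  }
  out
}

mod_detect <- function(name, nc, ch, sides, reg_max = 16) {
  c2 <- max(16, ch[1] %/% 4, reg_max * 4)
  c3 <- max(ch[1], min(nc, 100))
  out <- NULL
  for (i in seq_along(ch)) {
    s <- sides[i]; x <- ch[i]
    lv <- paste0(name, ".l", i)
    out <- rbind(out,
      unit_conv(paste0(lv, ".box1"), x, c2, 3, s),
      unit_conv(paste0(lv, ".box2"), c2, c2, 3, s),
      conv_rec(paste0(lv, ".box3"), c2, 4 * reg_max, 1, s^2, bn = FALSE,
               bias = TRUE),
      unit_conv(paste0(lv, ".cls_dw1"), x, x, 3, s, g = x),
      unit_conv(paste0(lv, ".cls_pw1"), x, c3, 1, s),
      unit_conv(paste0(lv, ".cls_dw2"), c3, c3, 3, s, g = c3),
      unit_conv(paste0(lv, ".cls_pw2"), c3, c3, 1, s),
      conv_rec(paste0(lv, ".cls_out"), c3, nc, 1, s^2, bn = FALSE,
               bias = TRUE))
  }
  anchors <- sum(sides^2)
  rbind(out, conv_rec(paste0(name, ".dfl"), reg_max, 1, 1, 4 * anchors,
                      bn = FALSE, bias = FALSE, trainable = FALSE))
}

assemble_convs <- function(variant, nc, input_size, msca_cfg) {
  stopifnot(input_size %% 32 == 0)
  w <- c(p1 = 16, p2 = 32, c2 = 64, p3 = 64, c4 = 128, p4 = 128,
         c6 = 128, p5 = 256, c8 = 256)
  s <- input_size / c(2, 4, 8, 16, 32)  # P1..P5 sides
  convs <- rbind(
    unit_conv("b0.conv", 3, 16, 3, s[1]),
    unit_conv("b1.conv", 16, 32, 3, s[2]),
    mod_c3k2("b2.c3k2", 32, 64, s[2], e = 0.25),
    unit_conv("b3.conv", 64, 64, 3, s[3]),
    mod_c3k2("b4.c3k2", 64, 128, s[3], e = 0.25),
    unit_conv("b5.conv", 128, 128, 3, s[4]),
    mod_c3k2("b6.c3k2", 128, 128, s[4], c3k = TRUE),
    unit_conv("b7.conv", 128, 256, 3, s[5]),
    mod_c3k2("b8.c3k2", 256, 256, s[5], c3k = TRUE),
    mod_sppf("b9.sppf", 256, 256, s[5]),
    mod_c2psa("b10.c2psa", 256, s[5]))
  if (variant == "bf")
    convs <- rbind(convs,
      conv_rec("b10a.bone_msca", msca_cfg$channels, msca_cfg$channels,
               0, s[5]^2, bn = FALSE, bias = FALSE,
               params_override = bone_msca_parameter_count(msca_cfg),
               macs_override = bone_msca_macs(msca_cfg, s[5], s[5])))
  head <- rbind(
    mod_upsample("h11.upsample", 256, s[4]),
    mod_c3k2("h13.c3k2", 256 + 128, 128, s[4]),          # cat with P4
    mod_upsample("h14.upsample", 128, s[3]),
    mod_c3k2("h16.c3k2", 128 + 128, 64, s[3]),           # cat with P3
    unit_conv("h17.conv", 64, 64, 3, s[4]),
    mod_c3k2("h19.c3k2", 64 + 128, 128, s[4]),
    unit_conv("h20.conv", 128, 128, 3, s[5]),
    mod_c3k2("h22.c3k2", 128 + 256, 256, s[5], c3k = TRUE),
    mod_detect("h23.detect", nc, c(64, 128, 256), s[3:5]))
  rbind(convs, head)
}

conv_params <- function(cv, fused) {
  kernel <- cv$c1 / cv$g * cv$c2 * cv$k^2
  bn_extra <- if (fused) cv$c2 else 2 * cv$c2
  extra <- ifelse(cv$bn, bn_extra, ifelse(cv$bias, cv$c2, 0))
  ifelse(is.na(cv$params_override), kernel + extra, cv$params_override)
}

conv_macs <- function(cv) {
  ifelse(is.na(cv$macs_override),
         cv$area * cv$c2 * (cv$c1 / cv$g) * cv$k^2, cv$macs_override)
}

#' Build a detector architecture description
#'
#' @param variant `"baseline"` (the plain nano detector) or `"bf"`
#'   (baseline plus one Bone-MSCA block at the backbone terminus and the
#'   Focal-SIoU box loss in the training configuration).
#' @param nc Number of classes (1 for fracture detection).
#' @param input_size Input side in pixels (divisible by 32).
#' @param msca_cfg A [bone_msca_config()] for the inserted block (bf only);
#'   its channel count must match the 256-channel insertion point.
#' @param insertion_point Where the block is inserted; only
#'   `"backbone_end"` (after the C2PSA stage, before the neck) is defined.
#' @param loss A [loss_config()] recorded as the training box loss.
#' @return An object of class `fracdet_model`: the per-convolution layer
#'   table plus metadata.
#' @export
#' @examples
#' m <- build_model("baseline")
#' report_millions(m)
build_model <- function(variant = c("baseline", "bf"), nc = 1L,
                        input_size = 640L,
                        msca_cfg = bone_msca_config(256),
                        insertion_point = "backbone_end",
                        loss = if (identical(variant, "bf"))
                          loss_config("focal_siou") else loss_config("ciou")) {
  variant <- match.arg(variant)
  if (!identical(insertion_point, "backbone_end"))
    stop("unknown insertion point '", insertion_point,
         "'; valid stages: backbone_end")
  if (variant == "bf" && msca_cfg$channels != 256)
    stop("the backbone terminus carries 256 channels; msca_cfg$channels = ",
         msca_cfg$channels)
  layers <- assemble_convs(variant, nc, input_size, msca_cfg)
  structure(list(variant = variant, nc = as.integer(nc),
                 input_size = as.integer(input_size), msca_cfg = msca_cfg,
                 loss = loss, layers = layers,
                 train = list(optimizer = "SGD", batch = 8, workers = 4,
                              epochs = 200, lr_schedule = "cosine")),
            class = "fracdet_model")
}

#' Count model parameters
#'
#' @param model A [build_model()] object.
#' @param fused Count the deployed model (batch-norm folded into the
#'   convolutions, the convention of the detector family's printed
#'   summaries); `FALSE` counts the model as trained.
#' @param trainable_only Exclude fixed (non-trainable) parameters.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model, fused = TRUE, trainable_only = FALSE) {
  cv <- model$layers
  if (trainable_only) cv <- cv[cv$trainable, , drop = FALSE]
  sum(conv_params(cv, fused))
}

#' Parameters in millions, rounded half-up to two decimals
#'
#' @param model A [build_model()] object (or a raw count).
#' @param fused See [count_parameters()].
#' @return A 2-decimal value in units of 1e6 parameters.
#' @export
report_millions <- function(model, fused = TRUE) {
  p <- if (inherits(model, "fracdet_model")) count_parameters(model, fused)
       else model
  floor(p / 1e6 * 100 + 0.5) / 100
}

#' Forward GFLOPs at a given input size
#'
#' Twice the multiply-accumulate count of all convolutions of the deployed
#' model (batch 1), in units of 1e9.
#'
#' @param model A [build_model()] object.
#' @param input_size Input side in pixels; defaults to the model's.
#' @param digits Rounding (1 decimal, the usual reporting precision);
#'   `NA` for the exact value.
#' @return GFLOPs value.
#' @export
estimate_gflops <- function(model, input_size = model$input_size,
                            digits = 1) {
  layers <- if (input_size == model$input_size) model$layers
            else assemble_convs(model$variant, model$nc, input_size,
                                model$msca_cfg)
  g <- 2 * sum(conv_macs(layers)) / 1e9
  if (is.na(digits)) g else round(g, digits)
}

#' Print a parameter/GFLOP report for a model
#'
#' @param model A [build_model()] object.
#' @return Invisibly, a list with the reported numbers.
#' @export
model_info <- function(model) {
  p_fused <- count_parameters(model, fused = TRUE)
  p_train <- count_parameters(model, fused = FALSE)
  g <- estimate_gflops(model)
  cat(sprintf("%s detector (nc=%d, %dpx): %.2fM parameters (fused; %d), %.1f GFLOPs\n",
              model$variant, model$nc, model$input_size,
              report_millions(model), p_fused, g))
  cat(sprintf("  as trained: %d parameters; box loss: %s\n", p_train,
              model$loss$variant))
  invisible(list(params_fused = p_fused, params_unfused = p_train,
                 params_millions = report_millions(model), gflops = g))
}

#' @export
print.fracdet_model <- function(x, ...) {
  model_info(x)
  invisible(x)
}

#' Smoke training (not provided)
#'
#' This toolkit builds architecture descriptions, losses, augmentation and
#' metrics; it deliberately contains no neural-network training engine, so
#' the assembled detector cannot be trained here. The function exists to
#' document that boundary and always raises a condition of class
#' `fracdet_no_training_engine`.
#'
#' @param spec A [build_model()] object.
#' @param dataset Dataset root (YOLO layout).
#' @param epochs,seed Training parameters (unused).
#' @export
smoke_train <- function(spec, dataset, epochs = 30, seed = 0) {
  stop(structure(class = c("fracdet_no_training_engine", "error",
                           "condition"),
                 list(message = paste(
                   "fracdet builds architecture descriptions and training",
                   "components but does not include a neural-network",
                   "training engine; train the assembled architecture in a",
                   "detection framework and evaluate the predictions with",
                   "evaluate_detections()."),
                   call = sys.call(-1))))
}
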