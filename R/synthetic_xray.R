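#' Configuration for the radiograph phantom generator
#'
#' The phantom emulates the statistical structure of limb/trunk radiographs
#' at toy scale: bright capsule-shaped bone bands on a darker soft-tissue
#' background, thin dark fracture lines crossing the bands (optionally with a
#' lateral displacement step mimicking displaced fractures), Gaussian blur,
#' and additive Gaussian noise. Every fracture yields exactly one bounding
#' box that tightly encloses the darkened region plus a 3-pixel margin.
#'
#' @param image_size Square image side in pixels.
#' @param n_bones Number of bone bands per image.
#' @param fracture_probability Per-bone probability of carrying a fracture.
#' @param bone_intensity,background_intensity 8-bit intensity levels; the
#'   bone must be brighter than the background.
#' @param bone_halfwidth Range (pixels) of the capsule half-width.
#' @param fracture_width Range (pixels) of the fracture line width.
#' @param fracture_contrast Intensity drop of fracture pixels relative to the
#'   surrounding band.
#' @param displacement_prob Probability that a fracture displaces one bone
#'   half laterally (2-6 px) instead of being a simple hairline.
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param blur_sigma Gaussian blur standard deviation (applied before noise).
#' @param margin Box margin around the darkened fracture region, pixels.
#' @param seed Default seed used by [generate_phantom()].
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 256L, n_bones = 2L,
                           fracture_probability = 0.7,
                           bone_intensity = 190, background_intensity = 60,
                           bone_halfwidth = c(10, 18),
                           fracture_width = c(2, 4),
                           fracture_contrast = 80,
                           displacement_prob = 0.3,
                           noise_sigma = 6, blur_sigma = 1,
                           margin = 3L, seed = NULL) {
  cfg <- list(image_size = as.integer(image_size), n_bones = as.integer(n_bones),
              fracture_probability = fracture_probability,
              bone_intensity = bone_intensity,
              background_intensity = background_intensity,
              bone_halfwidth = bone_halfwidth,
              fracture_width = fracture_width,
              fracture_contrast = fracture_contrast,
              displacement_prob = displacement_prob,
              noise_sigma = noise_sigma, blur_sigma = blur_sigma,
              margin = as.integer(margin), seed = seed)
  stopifnot(cfg$image_size >= 32,
            cfg$bone_intensity > cfg$background_intensity,
            cfg$fracture_probability >= 0, cfg$fracture_probability <= 1,
            min(cfg$fracture_width) >= 1,
            all(vapply(cfg[!vapply(cfg, is.null, TRUE)],
                       function(v) all(is.finite(unlist(v))), TRUE)))
  class(cfg) <- "phantom_config"
  cfg
}

# distance from every grid point to the segment p1--p2 (0-based pixel coords)
segment_distance <- function(gx, gy, p1, p2) {
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  len2 <- vx^2 + vy^2
  if (len2 == 0) return(sqrt((gx - p1[1])^2 + (gy - p1[2])^2))
  t <- ((gx - p1[1]) * vx + (gy - p1[2]) * vy) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((gx - (p1[1] + t * vx))^2 + (gy - (p1[2] + t * vy))^2)
}

#' Generate one radiograph phantom with exact labels
#'
#' Deterministic given a seed: repeated calls with the same configuration
#' and seed produce byte-identical images and labels.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list with elements `image` (`H x W x 3` array, integer values in
#'   `[0, 255]`, grayscale replicated to three channels), `boxes`
#'   (normalized boxes, one per fracture), `noiseless` (`H x W` matrix before
#'   blur and noise) and `fracture_mask` (`H x W` logical).
#' @export
generate_phantom <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, generate_phantom_impl(config))
}

generate_phantom_impl <- function(cfg) {
  s <- cfg$image_size
  gx <- matrix(rep(0:(s - 1), each = s), s, s)   # column index = x
  gy <- matrix(rep(0:(s - 1), times = s), s, s)  # row index = y
  base <- matrix(cfg$background_intensity, s, s)
  frac_masks <- list()
  n_placed <- 0L
  for (bone in seq_len(cfg$n_bones)) {
    hw <- runif(1, cfg$bone_halfwidth[1], cfg$bone_halfwidth[2])
    seg <- NULL
    for (try in 1:25) {
      theta <- runif(1, 0, pi)
      cx <- runif(1, 0.3 * s, 0.7 * s); cy <- runif(1, 0.3 * s, 0.7 * s)
      u <- c(cos(theta), sin(theta))
      # longest half-length keeping endpoints hw+2 px inside the frame
      lim <- function(c0, d) {
        if (abs(d) < 1e-9) return(Inf)
        max((s - 1 - hw - 2 - c0) / d, (hw + 2 - c0) / d)
      }
      half_max <- min(abs((s - 1 - hw - 2 - cx) / ifelse(u[1] == 0, Inf, u[1])),
                      abs((hw + 2 - cx) / ifelse(u[1] == 0, Inf, u[1])),
                      abs((s - 1 - hw - 2 - cy) / ifelse(u[2] == 0, Inf, u[2])),
                      abs((hw + 2 - cy) / ifelse(u[2] == 0, Inf, u[2])))
      if (!is.finite(half_max)) half_max <- s / 2 - hw - 2
      if (half_max < 2.5 * hw) next
      half <- runif(1, 2.5 * hw, min(half_max, 0.45 * s))
      seg <- list(p1 = c(cx, cy) - half * u, p2 = c(cx, cy) + half * u,
                  u = u, hw = hw)
      break
    }
    if (is.null(seg)) {
      message("bone placement failed after bounded retries; placing ",
              n_placed, " of ", cfg$n_bones, " bones")
      next
    }
    n_placed <- n_placed + 1L
    fractured <- runif(1) < cfg$fracture_probability
    displaced <- fractured && runif(1) < cfg$displacement_prob
    perp <- c(-seg$u[2], seg$u[1])
    tsplit <- runif(1, 0.35, 0.65)
    cpt <- seg$p1 + tsplit * (seg$p2 - seg$p1)
    draw_capsule <- function(p1, p2) {
      d <- segment_distance(gx, gy, p1, p2)
      inside <- d <= seg$hw
      val <- cfg$bone_intensity - 25 * (d / seg$hw)^2
      ifelse(inside, val, -Inf)
    }
    if (displaced) {
      delta <- sample(c(-1, 1), 1) * runif(1, 2, 6)
      off <- delta * perp
      field <- pmax(draw_capsule(seg$p1, cpt), draw_capsule(cpt + off, seg$p2 + off))
      capsule_inside <- is.finite(field)
      frac_p1 <- cpt - 1.2 * seg$hw * perp + off / 2
      frac_p2 <- cpt + 1.2 * seg$hw * perp + off / 2
      wf <- runif(1, cfg$fracture_width[1], cfg$fracture_width[2]) + abs(delta) / 2
    } else {
      field <- draw_capsule(seg$p1, seg$p2)
      capsule_inside <- is.finite(field)
      phi <- runif(1, -pi / 6, pi / 6)
      fdir <- c(perp[1] * cos(phi) - perp[2] * sin(phi),
                perp[1] * sin(phi) + perp[2] * cos(phi))
      frac_p1 <- cpt - 1.3 * seg$hw * fdir
      frac_p2 <- cpt + 1.3 * seg$hw * fdir
      wf <- runif(1, cfg$fracture_width[1], cfg$fracture_width[2])
    }
    base <- pmax(base, ifelse(capsule_inside, field, base))
    if (fractured) {
      fd <- segment_distance(gx, gy, frac_p1, frac_p2)
      fmask <- fd <= wf / 2 & capsule_inside
      if (any(fmask)) {
        base[fmask] <- pmax(base[fmask] - cfg$fracture_contrast, 5)
        frac_masks[[length(frac_masks) + 1L]] <- fmask
      }
    }
  }
  boxes <- norm_boxes()
  for (fm in frac_masks) {
    ys <- range(which(apply(fm, 1, any))) - 1L
    xs <- range(which(apply(fm, 2, any))) - 1L
    x1 <- max(0, xs[1] - cfg$margin); x2 <- min(s - 1, xs[2] + cfg$margin) + 1
    y1 <- max(0, ys[1] - cfg$margin); y2 <- min(s - 1, ys[2] + cfg$margin) + 1
    boxes <- rbind(boxes, box_abs_to_norm(
      data.frame(class_id = 0L, x1 = x1, y1 = y1, x2 = x2, y2 = y2), s, s))
  }
  boxes <- clip_norm_boxes(boxes)
  img <- gaussian_blur(base, cfg$blur_sigma)
  if (cfg$noise_sigma > 0)
    img <- img + matrix(rnorm(s * s, 0, cfg$noise_sigma), s, s)
  img <- round(pmin(pmax(img, 0), 255))
  fm_all <- matrix(FALSE, s, s)
  for (fm in frac_masks) fm_all <- fm_all | fm
  list(image = array(rep(img, 3), dim = c(s, s, 3)),
       boxes = boxes, noiseless = base, fracture_mask = fm_all)
}

#' Generate a phantom dataset in YOLO layout
#'
#' Writes `n` image/label pairs plus a `data.yaml` manifest. Per-image seeds
#' are derived from the master seed, so the whole dataset is reproducible
#' file-for-file.
#'
#' @param config A [phantom_config()].
#' @param n Number of images (>= 1).
#' @param out_root Output directory (refused if non-empty unless
#'   `overwrite`).
#' @param seed Master seed.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return `out_root`, invisibly.
#' @export
generate_phantom_dataset <- function(config, n, out_root, seed = 0L,
                                     overwrite = FALSE) {
  stopifnot(n >= 1)
  items <- lapply(seq_len(n), function(i) {
    ph <- generate_phantom(config, seed = derive_seed(seed, paste0("phantom", i)))
    list(image = ph$image, boxes = ph$boxes, name = sprintf("phantom_%05d", i))
  })
  write_yolo_dataset(items, out_root, overwrite = overwrite)
}
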