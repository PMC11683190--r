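#' Three-layer root-mosaic raster stack
#'
#' A `channel_stack` bundles the red-fluorescence, green-fluorescence and
#' darkfield layers of one plant's root mosaic, all the same shape, together
#' with the pixel scale (mm per pixel) and bit depth.
#'
#' @param red,green,darkfield Numeric matrices of identical dimensions with
#'   non-negative intensities within the declared bit depth.
#' @param pixel_scale Millimetres per pixel.
#' @param bit_depth Integer, 8 or 16.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(red, green, darkfield, pixel_scale, bit_depth = 8L) {
  layers <- list(red = red, green = green, darkfield = darkfield)
  dims <- lapply(layers, dim)
  if (!all(vapply(layers, is.matrix, logical(1))) ||
      !identical(dims$red, dims$green) || !identical(dims$red, dims$darkfield)) {
    stop("red, green and darkfield must be matrices of identical shape",
         call. = FALSE)
  }
  maxdn <- 2^bit_depth - 1
  rng <- range(unlist(lapply(layers, range)))
  if (rng[1] < 0 || rng[2] > maxdn) {
    stop("intensities must lie within [0, ", maxdn, "] for bit depth ",
         bit_depth, call. = FALSE)
  }
  structure(list(red = red, green = green, darkfield = darkfield,
                 pixel_scale = pixel_scale, bit_depth = as.integer(bit_depth)),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$red)
  cat("<channel_stack> ", d[1], "x", d[2], " px, ", x$bit_depth, "-bit, ",
      x$pixel_scale, " mm/px\n", sep = "")
  cat("  mean intensities: red ", round(mean(x$red), 1), ", green ",
      round(mean(x$green), 1), ", darkfield ", round(mean(x$darkfield), 1),
      "\n", sep = "")
  invisible(x)
}

#' Render a plant's nodules into a fluorescence mosaic
#'
#' Draws each ground-truth nodule as a filled disc at its sampled center.
#' Single-infection nodules appear in their assigned fluorophore channel only;
#' mixed-infection nodules are split between the two channels either as an
#' angular sector (fraction of the disc angle equal to the Fix+ partial-area
#' fraction) or as intermingled per-pixel patches, so the per-channel pixel
#' areas match the true partial areas up to rasterization/binomial error.
#' Non-fluorescent nodules are drawn in the darkfield layer only.  Red-channel
#' nodule intensity is `red_green_brightness_factor` times the green-channel
#' intensity, reproducing the channel imbalance of real mosaics, and Gaussian
#' background noise is added to every layer.
#'
#' @param nodules Nodule tibble from [sample_nodule_population()], all rows
#'   from one plant (an empty tibble yields a background-only stack).
#' @param cfg An [effect_config()].
#' @param seed Optional integer seeding the RNG (noise, sector orientation).
#' @return A [channel_stack()].
#' @export
render_mosaic <- function(nodules, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "effect_config"))
  if (!is.null(seed)) set.seed(seed)
  if (nrow(nodules) > 0 && length(unique(nodules$plant_id)) > 1L) {
    stop("render_mosaic() renders one plant at a time", call. = FALSE)
  }
  f <- cfg$frame_px
  maxdn <- 2^cfg$bit_depth - 1
  red <- matrix(cfg$background_level, f, f)
  green <- matrix(cfg$background_level, f, f)
  dark <- matrix(cfg$darkfield_background, f, f)
  if (nrow(nodules) > 0) {
    if (any(nodules$cx - nodules$radius_px < 1 | nodules$cx + nodules$radius_px > f |
            nodules$cy - nodules$radius_px < 1 | nodules$cy + nodules$radius_px > f)) {
      stop("nodule geometry does not fit inside the ", f, "x", f, " frame",
           call. = FALSE)
    }
    sdlog <- sqrt(log(1 + cfg$intensity_cv^2))
    green_base <- cfg$green_intensity
    red_base <- cfg$red_green_brightness_factor * green_base
    for (i in seq_len(nrow(nodules))) {
      nd <- nodules[i, ]
      m <- disc_pixels(nd$cx, nd$cy, nd$radius_px, f)
      bright <- stats::rlnorm(1, -sdlog^2 / 2, sdlog)
      dark[m$idx] <- pmax(dark[m$idx], cfg$darkfield_intensity * bright)
      if (nd$occupancy_kind == "nonfluorescent") next
      if (nd$occupancy_kind == "mixed") {
        p_fp <- nd$true_partial_area_fix_plus / nd$true_total_area
        fp_px <- if (nd$render_style == "sectors") {
          th0 <- stats::runif(1, 0, 2 * pi)
          ang <- (atan2(m$dy, m$dx) - th0) %% (2 * pi)
          ang < 2 * pi * p_fp
        } else {
          stats::runif(length(m$idx)) < p_fp
        }
        fp_chan <- if (nd$color_red_strain == "fix_plus") "red" else "green"
        if (fp_chan == "red") {
          red[m$idx[fp_px]] <- pmax(red[m$idx[fp_px]], red_base * bright)
          green[m$idx[!fp_px]] <- pmax(green[m$idx[!fp_px]], green_base * bright)
        } else {
          green[m$idx[fp_px]] <- pmax(green[m$idx[fp_px]], green_base * bright)
          red[m$idx[!fp_px]] <- pmax(red[m$idx[!fp_px]], red_base * bright)
        }
      } else if (identical(nd$color, "red")) {
        red[m$idx] <- pmax(red[m$idx], red_base * bright)
      } else {
        green[m$idx] <- pmax(green[m$idx], green_base * bright)
      }
    }
  }
  if (cfg$background_noise_sd > 0) {
    red <- red + stats::rnorm(f * f, 0, cfg$background_noise_sd)
    green <- green + stats::rnorm(f * f, 0, cfg$background_noise_sd)
    dark <- dark + stats::rnorm(f * f, 0, cfg$background_noise_sd)
  }
  clip <- function(x) matrix(pmin(pmax(round(x), 0), maxdn), f, f)
  channel_stack(clip(red), clip(green), clip(dark),
                pixel_scale = cfg$pixel_scale, bit_depth = cfg$bit_depth)
}

# Linear indices (and center offsets) of the pixels of a filled disc.
disc_pixels <- function(cx, cy, r, frame) {
  xs <- max(1L, floor(cx - r)):min(frame, ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(frame, ceiling(cy + r))
  dx <- rep(xs - cx, times = length(ys))
  dy <- rep(ys - cy, each = length(xs))
  keep <- dx^2 + dy^2 <= r^2
  # matrices are indexed [row, col] = [y, x]
  idx <- rep(ys, each = length(xs)) + (rep(xs, times = length(ys)) - 1L) * frame
  list(idx = idx[keep], dx = dx[keep], dy = dy[keep])
}
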