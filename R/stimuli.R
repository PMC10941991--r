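# Stimulus generation: luminance-matched square-wave stripe targets and the
# uniform gray control, the two panels of the forced-choice display.

#' Michelson contrast of a periodic pattern
#'
#' `(l_max - l_min) / (l_max + l_min)` on linear 8-bit gray levels: 0 for a
#' uniform field, 1 for full-range stripes. This is the contrast metric used
#' throughout the package; gray levels are assumed proportional to luminance
#' (display gamma is calibrated externally, not modeled here).
#'
#' @param l_max lighter gray level, in `[0, 255]`.
#' @param l_min darker gray level, in `[0, 255]`.
#' @return contrast fraction in `[0, 1]`.
#' @export
#' @examples
#' michelson_contrast(255, 0)   # 1
#' michelson_contrast(140, 60)  # 0.4
michelson_contrast <- function(l_max, l_min) {
  if (!is_scalar_number(l_max) || !is_scalar_number(l_min)) {
    stop_config("gray levels must be single numbers")
  }
  if (l_min < 0 || l_max > 255 || l_min > l_max) {
    stop_config("need 0 <= l_min <= l_max <= 255 (got l_min=%g, l_max=%g)",
                l_min, l_max)
  }
  if (l_max + l_min <= 0) {
    stop_data("contrast is undefined when both gray levels are zero")
  }
  (l_max - l_min) / (l_max + l_min)
}

#' Parametric description of a striped target stimulus
#'
#' The target is a square-wave (hard-edged, 50% duty cycle) stripe pattern
#' whose two gray levels are `mean_luminance * (1 +/- contrast)`, so its
#' space-averaged luminance equals the uniform gray control's: the two
#' panels differ only in pattern, never in overall brightness.
#' Non-integer gray levels are quantized with round-half-even, applied
#' identically to target and control.
#'
#' @param contrast Michelson contrast fraction in `[0, 1]` (the standard
#'   test set uses 0.1-1.0, i.e. 10%-100%).
#' @param mean_luminance mean gray level in `[0, 255]`. The default 127.5
#'   centers the 8-bit range so that 100% contrast renders as 0/255.
#' @param spatial_frequency full stripe pairs across the image, a positive
#'   integer. Default 8 pairs.
#' @param orientation `"vertical"` (stripes vary along width) or
#'   `"horizontal"`.
#' @param width_px,height_px image size in pixels; each must be at least
#'   `2 * spatial_frequency`.
#' @return an object of class `stimulus_spec`.
#' @export
#' @examples
#' stimulus_spec(0.4, mean_luminance = 100)
stimulus_spec <- function(contrast,
                          mean_luminance = 127.5,
                          spatial_frequency = 8L,
                          orientation = c("vertical", "horizontal"),
                          width_px = 512L,
                          height_px = 512L) {
  orientation <- match.arg(orientation)
  if (!is_scalar_number(contrast) || contrast < 0 || contrast > 1) {
    stop_config("contrast must be in [0, 1] (got %s)", format(contrast))
  }
  if (!is_scalar_number(mean_luminance) ||
      mean_luminance < 0 || mean_luminance > 255) {
    stop_config("mean_luminance must be in [0, 255]")
  }
  if (mean_luminance * (1 + contrast) > 255 ||
      mean_luminance * (1 - contrast) < 0) {
    stop_config(
      "unrenderable spec: stripe levels %g and %g fall outside [0, 255]",
      mean_luminance * (1 + contrast), mean_luminance * (1 - contrast))
  }
  if (!is_count(spatial_frequency)) {
    stop_config("spatial_frequency must be a positive integer")
  }
  if (!is_count(width_px) || !is_count(height_px) ||
      width_px < 2 * spatial_frequency || height_px < 2 * spatial_frequency) {
    stop_config("width_px and height_px must be >= 2 * spatial_frequency")
  }
  structure(
    list(contrast = contrast,
         mean_luminance = mean_luminance,
         spatial_frequency = as.integer(spatial_frequency),
         orientation = orientation,
         width_px = as.integer(width_px),
         height_px = as.integer(height_px)),
    class = "stimulus_spec")
}

# square-wave profile: gray levels along one axis of n pixels
stripe_profile <- function(n, pairs, l_hi, l_lo) {
  band <- floor((seq_len(n) - 1) * 2 * pairs / n)
  ifelse(band %% 2 == 0, l_hi, l_lo)
}

#' Render a striped target image
#'
#' Produces the 8-bit grayscale square-wave image described by a
#' [stimulus_spec()]: stripe levels `round(mean_luminance * (1 +/- contrast))`
#' (round-half-even), exactly `spatial_frequency` full stripe pairs along
#' the axis perpendicular to the stripe orientation. Rendering is
#' deterministic; identical specs give bit-identical images.
#'
#' @param spec a [stimulus_spec()].
#' @return an object of class `stimulus_image`: a list with `pixels` (an
#'   integer matrix, rows = height) and `spec`.
#' @export
#' @examples
#' img <- make_stripe_image(stimulus_spec(0.4, mean_luminance = 100))
#' range(img$pixels)  # 60 140
make_stripe_image <- function(spec) {
  if (!inherits(spec, "stimulus_spec")) {
    stop_config("spec must be a stimulus_spec")
  }
  l_hi <- round(spec$mean_luminance * (1 + spec$contrast))
  l_lo <- round(spec$mean_luminance * (1 - spec$contrast))
  if (l_hi > 255 || l_lo < 0) {
    stop_config("unrenderable spec: quantized levels outside [0, 255]")
  }
  if (spec$orientation == "vertical") {
    row <- stripe_profile(spec$width_px, spec$spatial_frequency, l_hi, l_lo)
    pixels <- matrix(rep(row, each = spec$height_px),
                     nrow = spec$height_px, ncol = spec$width_px)
  } else {
    col <- stripe_profile(spec$height_px, spec$spatial_frequency, l_hi, l_lo)
    pixels <- matrix(rep(col, times = spec$width_px),
                     nrow = spec$height_px, ncol = spec$width_px)
  }
  structure(list(pixels = pixels, spec = spec), class = "stimulus_image")
}

#' Render the uniform gray control image
#'
#' The control panel: a uniform field at the quantized mean luminance, the
#' same round-half-even rule as the stripe renderer so the two panels'
#' means agree to within one gray level.
#'
#' @param mean_luminance gray level in `[0, 255]`.
#' @param width_px,height_px image size in pixels.
#' @return a `stimulus_image` whose `spec` carries `control = TRUE`.
#' @export
make_control_image <- function(mean_luminance = 127.5,
                               width_px = 512L, height_px = 512L) {
  if (!is_scalar_number(mean_luminance) ||
      mean_luminance < 0 || mean_luminance > 255) {
    stop_config("mean_luminance must be in [0, 255]")
  }
  if (!is_count(width_px) || !is_count(height_px)) {
    stop_config("image dimensions must be positive integers")
  }
  level <- round(mean_luminance)
  pixels <- matrix(level, nrow = height_px, ncol = width_px)
  spec <- list(control = TRUE, mean_luminance = mean_luminance,
               width_px = as.integer(width_px),
               height_px = as.integer(height_px))
  structure(list(pixels = pixels, spec = spec), class = "stimulus_image")
}

#' The standard ten-level contrast set
#'
#' Ten stimulus specs at contrasts 0.1, 0.2, ..., 1.0 (10% to 100%),
#' identical in every other field; the image set presented against the
#' gray control during the experimental phase.
#'
#' @inheritParams stimulus_spec
#' @return list of ten [stimulus_spec()] objects.
#' @export
standard_contrast_set <- function(mean_luminance = 127.5,
                                  spatial_frequency = 8L,
                                  orientation = "vertical",
                                  width_px = 512L, height_px = 512L) {
  lapply(seq(0.1, 1.0, by = 0.1), stimulus_spec,
         mean_luminance = mean_luminance,
         spatial_frequency = spatial_frequency,
         orientation = orientation,
         width_px = width_px, height_px = height_px)
}

#' Mean gray level of a rendered image
#' @param image a `stimulus_image`.
#' @return mean pixel value.
#' @export
image_mean <- function(image) {
  stopifnot(inherits(image, "stimulus_image"))
  mean(image$pixels)
}

#' Achieved Michelson contrast of a rendered image
#'
#' Computed from the image's extreme pixel values; for a rendered stripe
#' image this differs from the spec contrast only by 8-bit quantization
#' (at most 1/255 at mid-gray).
#'
#' @param image a `stimulus_image`.
#' @return contrast fraction.
#' @export
achieved_contrast <- function(image) {
  stopifnot(inherits(image, "stimulus_image"))
  michelson_contrast(max(image$pixels), min(image$pixels))
}

#' Write a stimulus image as an 8-bit grayscale PNG
#' @param image a `stimulus_image`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stimulus_png <- function(image, path) {
  stopifnot(inherits(image, "stimulus_image"))
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

#' Write the full stimulus set (ten contrasts plus control) as PNG files
#'
#' File names encode the contrast level: `stripe_c010.png` ... `stripe_c100.png`
#' plus `control.png`.
#'
#' @param dir output directory (created if absent).
#' @param contrasts contrast fractions; default the standard ten levels.
#' @inheritParams stimulus_spec
#' @return invisibly, the written file paths.
#' @export
write_stimulus_set <- function(dir,
                               contrasts = seq(0.1, 1.0, by = 0.1),
                               mean_luminance = 127.5,
                               spatial_frequency = 8L,
                               orientation = "vertical",
                               width_px = 512L, height_px = 512L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (ct in contrasts) {
    spec <- stimulus_spec(ct, mean_luminance, spatial_frequency,
                          orientation, width_px, height_px)
    p <- file.path(dir, sprintf("stripe_c%03d.png", round(ct * 100)))
    write_stimulus_png(make_stripe_image(spec), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "control.png")
  write_stimulus_png(make_control_image(mean_luminance, width_px, height_px), p)
  invisible(c(paths, p))
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "<stimulus_spec> contrast %.0f%%, mean gray %.1f, %d stripe pairs (%s), %dx%d px\n",
    100 * x$contrast, x$mean_luminance, x$spatial_frequency,
    x$orientation, x$width_px, x$height_px))
  invisible(x)
}

#' @export
print.stimulus_image <- function(x, ...) {
  kind <- if (isTRUE(x$spec$control)) "control (uniform gray)" else
    sprintf("stripes at %.0f%% contrast", 100 * x$spec$contrast)
  cat(sprintf("<stimulus_image> %s, %dx%d px, gray levels [%d, %d]\n",
              kind, ncol(x$pixels), nrow(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}
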