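# Six-area classification of (contrast, percent-correct) points. Rows:
# performance >= 75% (trained, informative), 50-75% (trained but weak CS),
# < 50% (below chance: random or weak training). Columns: low vs high
# contrast. The contrast split between columns is not fixed by the
# protocol; the default is the midpoint of the tested range (50%) and is
# configurable.

AREA_BANDS <- c(A1 = "good_moderate", A2 = "good_moderate",
                A3 = "weak_cs", A4 = "weak_cs",
                A5 = "weak_training", A6 = "weak_training")

#' Classification rule for the six CS-function areas
#'
#' Boundary conventions, all documented and fixed: percent correct exactly
#' at `upper_band_min_pc` (75) falls in the upper band; exactly at
#' `chance_pc` (50) falls in the weak-CS band; contrast exactly at the
#' split falls in the low-contrast column.
#'
#' @param contrast_split boundary between the low- and high-contrast
#'   columns, a fraction strictly inside (0, 1); default 0.5.
#' @param upper_band_min_pc lower edge of the good/moderate band in
#'   percent; default 75.
#' @return object of class `classification_rule`. The chance level is
#'   fixed at 50% by the two-choice design.
#' @export
classification_rule <- function(contrast_split = 0.5,
                                upper_band_min_pc = 75) {
  if (!is_scalar_number(contrast_split) ||
      contrast_split <= 0 || contrast_split >= 1) {
    stop_config("contrast_split must lie strictly inside (0, 1)")
  }
  if (!is_scalar_number(upper_band_min_pc) ||
      upper_band_min_pc <= 50 || upper_band_min_pc > 100) {
    stop_config("upper_band_min_pc must lie in (50, 100]")
  }
  structure(list(contrast_split = contrast_split,
                 upper_band_min_pc = upper_band_min_pc,
                 chance_pc = 50),
            class = "classification_rule")
}

#' Classify performance points into the six CS-function areas
#'
#' * `A1` - high accuracy at low contrast: good CS function.
#' * `A2` - high accuracy only at high contrast: moderate CS function.
#' * `A3`/`A4` - accuracy between chance and 75%: trained, but weak CS.
#' * `A5`/`A6` - below-chance accuracy: random picking or weak training.
#'
#' Every valid point maps to exactly one area (the areas partition the
#' `[0,1] x [0,100]` rectangle).
#'
#' @param contrast contrast fraction(s) in `[0, 1]`.
#' @param percent_correct percent correct value(s) in `[0, 100]`.
#' @param rule a [classification_rule()].
#' @return data frame with columns `contrast`, `percent_correct`, `area`
#'   (`A1`-`A6`), `band` (`good_moderate`, `weak_cs`, `weak_training`).
#' @export
#' @examples
#' classify_point(c(0.2, 0.8, 0.9), c(90, 60, 40))$area  # A1 A4 A6
classify_point <- function(contrast, percent_correct,
                           rule = classification_rule()) {
  stopifnot(inherits(rule, "classification_rule"))
  if (!is.numeric(contrast) || !is.numeric(percent_correct) ||
      length(contrast) != length(percent_correct) || length(contrast) == 0) {
    stop_config("contrast and percent_correct must be numeric, same length")
  }
  if (anyNA(contrast) || any(contrast < 0 | contrast > 1)) {
    stop_config("contrast values must lie in [0, 1]")
  }
  if (anyNA(percent_correct) ||
      any(percent_correct < 0 | percent_correct > 100)) {
    stop_config("percent_correct values must lie in [0, 100]")
  }
  high <- contrast > rule$contrast_split
  area <- ifelse(
    percent_correct >= rule$upper_band_min_pc, ifelse(high, "A2", "A1"),
    ifelse(percent_correct >= rule$chance_pc, ifelse(high, "A4", "A3"),
           ifelse(high, "A6", "A5")))
  data.frame(contrast = contrast,
             percent_correct = percent_correct,
             area = area,
             band = unname(AREA_BANDS[area]),
             stringsAsFactors = FALSE)
}

#' Per-area and per-band counts of performance points
#'
#' @param points data frame with columns `contrast` and `percent_correct`
#'   (e.g. from [per_contrast_performance()]), or the output of
#'   [classify_point()].
#' @param rule a [classification_rule()].
#' @return object of class `band_summary`: a list with `points` (labeled),
#'   `area_counts` (named, A1-A6), `band_counts`, `band_fractions`, `n`.
#' @export
band_summary <- function(points, rule = classification_rule()) {
  if (!is.data.frame(points) ||
      !all(c("contrast", "percent_correct") %in% names(points))) {
    stop_data("points must have columns contrast and percent_correct")
  }
  if (nrow(points) == 0) stop_data("no points to classify")
  labeled <- classify_point(points$contrast, points$percent_correct, rule)
  area_counts <- table(factor(labeled$area, levels = names(AREA_BANDS)))
  band_counts <- table(factor(labeled$band,
                              levels = unique(unname(AREA_BANDS))))
  structure(list(points = labeled,
                 area_counts = c(area_counts),
                 band_counts = c(band_counts),
                 band_fractions = c(band_counts) / nrow(labeled),
                 n = nrow(labeled)),
            class = "band_summary")
}

#' @export
print.band_summary <- function(x, ...) {
  cat(sprintf("<band_summary> %d points\n", x$n))
  cat("  areas: ", paste(sprintf("%s=%d", names(x$area_counts),
                                 x$area_counts), collapse = " "), "\n")
  cat("  bands: ", paste(sprintf("%s=%d", names(x$band_counts),
                                 x$band_counts), collapse = " "), "\n")
  invisible(x)
}
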