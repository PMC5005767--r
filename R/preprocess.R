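#' Split a chemogram into its RGB channels
#'
#' The red channel makes the black shadow artifacts stand out against the
#' bright arterial wall; the green channel is where lipid areas are most
#' perceptible (the display colormap runs red, at no lipid, to yellow, at
#' high lipid probability, so green carries the lipid signal).
#'
#' @param chem a [chemogram()].
#' @return Named list of three `H x W` numeric matrices: `red`, `green`,
#'   `blue`, values in `[0, 255]`.
#' @export
split_channels <- function(chem) {
  stopifnot(inherits(chem, "chemogram"))
  list(red = chem$red, green = chem$green, blue = chem$blue)
}

#' Contrast-stretching intensity adjustment
#'
#' Maps intensities of a grayscale channel image `I` to new values `J` such
#' that a fraction of the data is saturated at the low and high ends
#' (default 1% each): values at or below the `low_frac` quantile map to 0,
#' values at or above the `1 - high_frac` quantile map to 255, and the rest
#' are rescaled linearly. This increases the contrast of the image ahead of
#' thresholding. The map is monotone non-decreasing and output is rounded to
#' the integer range `[0, 255]`.
#'
#' @param img numeric matrix (or vector) with values in `[0, 255]`.
#' @param low_frac,high_frac saturated fractions at the two ends;
#'   `low_frac + high_frac < 1`.
#' @param quantile_type order-statistic interpolation rule passed to
#'   [stats::quantile()] (default 7, linear interpolation). The exact
#'   convention is not fixed by the method, so it is exposed.
#' @return Matrix of the same dimension. A constant (zero-contrast) image is
#'   returned unchanged with attribute `degenerate = TRUE`: empty-ROI
#'   chemograms must not crash the pipeline.
#' @export
adjust_intensity <- function(img, low_frac = 0.01, high_frac = 0.01,
                             quantile_type = 7) {
  stopifnot(is.numeric(img), low_frac >= 0, high_frac >= 0,
            low_frac + high_frac < 1)
  lo <- as.numeric(quantile(img, low_frac, type = quantile_type, names = FALSE))
  hi <- as.numeric(quantile(img, 1 - high_frac, type = quantile_type,
                            names = FALSE))
  if (hi <= lo) {
    attr(img, "degenerate") <- TRUE
    attr(img, "stretch_scale") <- 1
    return(img)
  }
  out <- round(clip255((img - lo) / (hi - lo) * 255))
  # gray-level gain of the linear map; lets callers translate differences
  # specified on the raw 8-bit scale onto the adjusted scale
  attr(out, "stretch_scale") <- 255 / (hi - lo)
  out
}
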