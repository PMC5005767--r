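#' Construct a calibrated chemogram
#'
#' A chemogram is a two-dimensional map of a coronary artery produced by a
#' NIRS pullback: the x-axis is mm along the vessel, the y-axis degrees of
#' catheter rotation, and a red-to-yellow colour scale encodes the probability
#' that lipid core plaque is present.
#'
#' @param red,green,blue numeric `H x W` matrices with values in `[0, 255]`.
#' @param mm_per_column millimetres of pullback covered by one pixel column
#'   (must be `> 0`). Calibration is supplied externally: exported chemogram
#'   rasters carry no pixel-pitch metadata.
#' @param pullback_speed_mm_per_s informational acquisition speed, default 0.5.
#' @return An object of class `chemogram`: list with the three channel
#'   matrices, `mm_per_column`, `degrees_per_row` (`= 360 / H`) and
#'   `pullback_length_mm` (`= W * mm_per_column`).
#' @export
chemogram <- function(red, green, blue, mm_per_column,
                      pullback_speed_mm_per_s = 0.5) {
  if (!is.matrix(red) || !is.matrix(green) || !is.matrix(blue))
    stop("channels must be matrices", call. = FALSE)
  if (!all(dim(red) == dim(green)) || !all(dim(red) == dim(blue)))
    stop("channel dimensions differ", call. = FALSE)
  if (nrow(red) < 1L || ncol(red) < 1L)
    stop("chemogram must have at least one row and column", call. = FALSE)
  rng <- range(red, green, blue)
  if (rng[1] < 0 || rng[2] > 255)
    stop("channel values must lie in [0, 255]", call. = FALSE)
  if (!is.numeric(mm_per_column) || length(mm_per_column) != 1L ||
      !is.finite(mm_per_column) || mm_per_column <= 0)
    stop("mm_per_column must be a single positive number", call. = FALSE)
  h <- nrow(red); w <- ncol(red)
  structure(
    list(red = red, green = green, blue = blue,
         mm_per_column = mm_per_column,
         degrees_per_row = 360 / h,
         pullback_length_mm = w * mm_per_column,
         pullback_speed_mm_per_s = pullback_speed_mm_per_s),
    class = "chemogram")
}

#' @export
print.chemogram <- function(x, ...) {
  cat(sprintf("chemogram: %d rows (%.3f deg/row) x %d cols (%.4g mm/col), %.4g mm pullback\n",
              nrow(x$red), x$degrees_per_row, ncol(x$red),
              x$mm_per_column, x$pullback_length_mm))
  invisible(x)
}

#' @export
dim.chemogram <- function(x) dim(x$red)

#' Region of interest along the pullback
#'
#' Half-open interval `[start_mm, end_mm)` along the pullback axis, e.g. the
#' stented segment selected by the physician.
#'
#' @param start_mm,end_mm millimetres along the pullback, `0 <= start < end`.
#' @return An object of class `roi`.
#' @export
roi <- function(start_mm, end_mm) {
  if (!is.numeric(start_mm) || !is.numeric(end_mm) ||
      !is.finite(start_mm) || !is.finite(end_mm))
    stop("ROI bounds must be finite numbers", call. = FALSE)
  if (start_mm < 0 || start_mm >= end_mm)
    stop("ROI requires 0 <= start_mm < end_mm", call. = FALSE)
  structure(list(start_mm = start_mm, end_mm = end_mm), class = "roi")
}

#' Map a region of interest to pixel columns
#'
#' Columns are half-open in mm: the returned 1-based index range covers
#' `[floor(start_mm / mm_per_column), ceiling(end_mm / mm_per_column))` in
#' 0-based column coordinates, and is never empty for a valid ROI.
#' Enlarging the ROI never shrinks the range.
#'
#' @param r an [roi()].
#' @param chem a [chemogram()].
#' @return Integer vector of 1-based column indices.
#' @export
roi_to_columns <- function(r, chem) {
  stopifnot(inherits(r, "roi"), inherits(chem, "chemogram"))
  if (r$end_mm > chem$pullback_length_mm + 1e-9)
    stop("ROI extends beyond the pullback length", call. = FALSE)
  first <- floor(r$start_mm / chem$mm_per_column) + 1L
  last  <- ceiling(r$end_mm / chem$mm_per_column)
  w <- ncol(chem$red)
  first <- max(1L, as.integer(first))
  last  <- min(w, as.integer(last))
  if (last < first) stop("ROI maps to an empty column range", call. = FALSE)
  seq.int(first, last)
}

#' Full-pullback region of interest for a chemogram
#' @param chem a [chemogram()].
#' @return An [roi()] spanning `[0, pullback_length_mm)`.
#' @export
full_roi <- function(chem) roi(0, chem$pullback_length_mm)
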