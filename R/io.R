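#' Read a chemogram image from disk
#'
#' Reads an RGB PNG or TIFF raster and attaches the supplied calibration.
#' Grayscale (or otherwise non-3-channel) images are rejected: the pipeline
#' analyses the red and green channels separately and needs true colour input.
#'
#' @param path path to a PNG or TIFF file (extension decides the decoder).
#' @param mm_per_column pullback millimetres per pixel column.
#' @param pullback_speed_mm_per_s informational, default 0.5.
#' @return A [chemogram()].
#' @export
read_chemogram <- function(path, mm_per_column, pullback_speed_mm_per_s = 0.5) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (PNG or TIFF required)",
         call. = FALSE))
  if (length(dim(arr)) != 3L || dim(arr)[3] != 3L)
    stop("chemogram images must have exactly 3 (RGB) channels", call. = FALSE)
  v <- round(arr * 255)
  chemogram(red = v[, , 1, drop = TRUE], green = v[, , 2, drop = TRUE],
            blue = v[, , 3, drop = TRUE],
            mm_per_column = mm_per_column,
            pullback_speed_mm_per_s = pullback_speed_mm_per_s)
}

#' Write a chemogram to a lossless PNG
#'
#' Round-trips bit-exactly through [read_chemogram()] because channel values
#' are 8-bit integers and PNG is lossless.
#'
#' @param chem a [chemogram()].
#' @param path output path (`.png`).
#' @export
write_chemogram <- function(chem, path) {
  stopifnot(inherits(chem, "chemogram"))
  h <- nrow(chem$red); w <- ncol(chem$red)
  arr <- array(0, dim = c(h, w, 3))
  arr[, , 1] <- chem$red / 255
  arr[, , 2] <- chem$green / 255
  arr[, , 3] <- chem$blue / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' Write a binary mask as a 0/255 grayscale PNG
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Write an LCBI report as JSON / read it back
#'
#' The JSON round-trips losslessly: `read_report(write_report(x))` restores
#' an equal structure.
#'
#' @param report named list as produced by [run_pipeline()].
#' @param path output `.json` path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}

#' Write an overlay image with segmented areas outlined
#'
#' Reproduces the "outlined segmented areas" view: the chemogram with the
#' combined lipid contour drawn in white and the artifact contour in blue.
#'
#' @param chem a [chemogram()].
#' @param masks named list with logical matrices; `lipid_combined` and/or
#'   `artifact` are drawn if present. All masks must match the chemogram
#'   dimensions.
#' @param path output `.png` path.
#' @export
write_overlay <- function(chem, masks, path) {
  stopifnot(inherits(chem, "chemogram"), is.list(masks))
  h <- nrow(chem$red); w <- ncol(chem$red)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m) || !all(dim(m) == c(h, w)))
      stop("mask '", nm, "' does not match the chemogram dimensions",
           call. = FALSE)
  }
  arr <- array(0, dim = c(h, w, 3))
  arr[, , 1] <- chem$red / 255
  arr[, , 2] <- chem$green / 255
  arr[, , 3] <- chem$blue / 255
  paint <- function(arr, outline, rgb) {
    idx <- which(outline)
    for (k in 1:3) {
      ch <- arr[, , k]
      ch[idx] <- rgb[k]
      arr[, , k] <- ch
    }
    arr
  }
  if (!is.null(masks$artifact))
    arr <- paint(arr, mask_outline(masks$artifact), c(0, 0, 1))
  if (!is.null(masks$lipid_combined))
    arr <- paint(arr, mask_outline(masks$lipid_combined), c(1, 1, 1))
  png::writePNG(arr, path)
  invisible(path)
}

# Boundary pixels of a mask: in-mask pixels with at least one 4-neighbour
# outside it (rows wrap cyclically, columns do not).
mask_outline <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  up    <- mask[c(h, seq_len(h - 1L)), , drop = FALSE]
  down  <- mask[c(seq_len(h)[-1L], 1L), , drop = FALSE]
  left  <- cbind(mask[, 1L, drop = FALSE], mask[, -w, drop = FALSE])
  right <- cbind(mask[, -1L, drop = FALSE], mask[, w, drop = FALSE])
  mask & !(up & down & left & right)
}
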