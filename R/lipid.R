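#' Detect clearly visible lipid regions
#'
#' Otsu threshold computed over the non-artifact pixels of the adjusted
#' green channel (artifact pixels would bias the dark class of the
#' histogram); pixels strictly above the threshold and outside the artifact
#' mask are marked as visible lipid. Lipid is bright in the green channel
#' because the display colormap runs red (no lipid) to yellow (lipid).
#'
#' @param adjusted_green contrast-adjusted green channel.
#' @param artifact_mask logical artifact mask of the same dimension.
#' @param min_contrast minimum separation, in gray levels, between the mean
#'   of the bright (lipid) class and the mean of the dark (wall) class for
#'   the split to count as a real lipid class. Otsu assumes a bimodal
#'   histogram; on a chemogram with little or no visible lipid it will split
#'   the wall texture itself, so a split with less contrast than this is
#'   rejected (empty mask, attribute `low_contrast = TRUE`). `0` disables
#'   the guard.
#' @return Logical mask of visible lipid with attributes `threshold` and
#'   `class_contrast`. If all non-artifact pixels are constant, the mask is
#'   empty with attribute `degenerate = TRUE`.
#' @export
detect_visible_lipid <- function(adjusted_green, artifact_mask,
                                 min_contrast = 0) {
  stopifnot(is.numeric(adjusted_green), is.logical(artifact_mask),
            all(dim(adjusted_green) == dim(artifact_mask)))
  vals <- adjusted_green[!artifact_mask]
  empty <- matrix(FALSE, nrow(adjusted_green), ncol(adjusted_green))
  if (length(vals) == 0L) {
    attr(empty, "degenerate") <- TRUE
    return(empty)
  }
  t <- otsu_threshold(vals)
  if (isTRUE(attr(t, "degenerate"))) {
    attr(empty, "degenerate") <- TRUE
    return(empty)
  }
  t <- as.numeric(t)
  contrast <- mean(vals[vals > t]) - mean(vals[vals <= t])
  if (contrast < min_contrast) {
    attr(empty, "low_contrast") <- TRUE
    attr(empty, "threshold") <- t
    attr(empty, "class_contrast") <- contrast
    return(empty)
  }
  out <- adjusted_green > t & !artifact_mask
  attr(out, "threshold") <- t
  attr(out, "class_contrast") <- contrast
  out
}

#' Detect lipid hidden under artifacts
#'
#' Shadowed lipid leaves an intensity trace inside the black artifact
#' regions. Per artifact region, independently: the 256-bin histogram of the
#' region's pixels is computed and its highest peak taken as the background
#' intensity of the region (ties broken toward the lower, darker gray level);
#' pixels whose value exceeds the background by more than `delta_threshold`
#' are marked as hidden lipid. Marking is per pixel, so a partial lipid
#' patch inside a large shadow is recovered at its own extent.
#'
#' With pixel noise the raw 256-bin mode of a small region is a
#' high-variance estimate — two histogram peaks of similar mass can swap by
#' chance — so the peak is located on the histogram smoothed with a moving
#' window of `± mode_bandwidth` gray levels (about the noise SD). Set
#' `mode_bandwidth = 0` for the raw mode.
#'
#' @param adjusted_green contrast-adjusted channel to analyse inside the
#'   artifact regions (green by default in [run_pipeline()], where lipid is
#'   most perceptible; configurable).
#' @param regions artifact region list from [detect_artifacts()].
#' @param delta_threshold gray-level difference above the region background
#'   required to call lipid (default 25, chosen to clear more than 3 standard
#'   deviations of typical pixel noise).
#' @param mode_bandwidth half-width, in gray levels, of the moving window
#'   used to smooth the region histogram before locating its highest peak
#'   (default 5).
#' @return Logical mask of hidden lipid, a subset of the artifact pixels.
#' @export
detect_hidden_lipid <- function(adjusted_green, regions, delta_threshold = 25,
                                mode_bandwidth = 5) {
  stopifnot(is.numeric(adjusted_green), is.matrix(adjusted_green),
            delta_threshold > 0, mode_bandwidth >= 0)
  out <- matrix(FALSE, nrow(adjusted_green), ncol(adjusted_green))
  for (reg in regions) {
    vals <- as.integer(round(clip255(adjusted_green[reg$pixels])))
    counts <- tabulate(vals + 1L, nbins = 256L)
    if (mode_bandwidth > 0) {
      cs <- cumsum(c(0, counts))
      idx <- seq_len(256L)
      counts <- cs[pmin(idx + mode_bandwidth, 256L) + 1L] -
        cs[pmax(idx - mode_bandwidth - 1L, 0L) + 1L]
    }
    background <- which.max(counts) - 1L   # first (lowest) peak wins ties
    hit <- vals - background > delta_threshold
    out[reg$pixels[hit]] <- TRUE
  }
  out
}

#' Combine visible and hidden lipid masks
#'
#' Pixel-wise union, plus the connected lipid components (8-connectivity,
#' cyclic rows) used downstream for lipid-arc computation. Hidden-lipid
#' detection can bridge a blob split by an artifact stripe back into a
#' single component.
#'
#' @param visible,hidden logical masks of identical dimension.
#' @return List with `mask` (the union) and `regions` (connected components).
#' @export
combine_lipid <- function(visible, hidden) {
  if (!all(dim(visible) == dim(hidden)))
    stop("lipid mask dimensions differ", call. = FALSE)
  m <- visible | hidden
  cc <- cyclic_components(m)
  list(mask = m, regions = cc$regions)
}
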