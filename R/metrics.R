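#' Total Lipid Core Burden Index
#'
#' `LCBI_total = 1000 * Area_lipid / Area_valid` within the region of
#' interest: the fraction of valid pixels assigned to lipid core plaque,
#' scaled to `[0, 1000]`. What counts as valid is the caller's choice of
#' `valid_mask`; [run_pipeline()] reports both conventions (artifact pixels
#' reclaimed as hidden lipid counted as valid, or all artifact pixels
#' excluded).
#'
#' @param lipid_mask,valid_mask logical matrices of identical dimension.
#' @param cols integer vector of ROI columns ([roi_to_columns()]).
#' @return Index in `[0, 1000]`.
#' @export
lcbi_total <- function(lipid_mask, valid_mask, cols = seq_len(ncol(lipid_mask))) {
  stopifnot(is.logical(lipid_mask), is.logical(valid_mask),
            all(dim(lipid_mask) == dim(valid_mask)))
  v <- valid_mask[, cols, drop = FALSE]
  l <- lipid_mask[, cols, drop = FALSE] & v
  nv <- sum(v)
  if (nv == 0L)
    stop("LCBI undefined: no valid pixels in the region of interest",
         call. = FALSE)
  1000 * sum(l) / nv
}

#' Maximal LCBI in a window of fixed length
#'
#' `maxLCBI_2mm` / `maxLCBI_4mm`: the maximal LCBI over windows of
#' `window_mm` along the pullback. In `blocked` mode the ROI is partitioned
#' into consecutive non-overlapping tiles anchored at the ROI start (a
#' trailing partial tile is excluded: it would not be a full-length
#' segment). In `sliding` mode every window position at `stride_mm` steps
#' (default one pixel column) inside the ROI is evaluated. Sliding max is
#' always `>=` blocked max for the same window length, since the blocked
#' windows are a subset of the sliding ones; this is the mechanism behind
#' discrepancies between block-based and window-based maxima. Ties go to the
#' smallest window start.
#'
#' @param lipid_mask,valid_mask logical matrices.
#' @param chem the source [chemogram()] (for calibration).
#' @param r an [roi()]; default full pullback.
#' @param window_mm window length in mm (2 or 4 in routine use).
#' @param mode `"sliding"` (default) or `"blocked"`.
#' @param stride_mm sliding step in mm; default one pixel column.
#' @return List with `value` (index in `[0, 1000]`) and `start_mm`.
#' @export
max_lcbi_window <- function(lipid_mask, valid_mask, chem, r = full_roi(chem),
                            window_mm = 4,
                            mode = c("sliding", "blocked"),
                            stride_mm = chem$mm_per_column) {
  mode <- match.arg(mode)
  cols <- roi_to_columns(r, chem)
  wpx <- max(1L, as.integer(round(window_mm / chem$mm_per_column)))
  if (wpx > length(cols))
    stop("window (", window_mm, " mm) longer than the region of interest",
         call. = FALSE)
  v <- valid_mask[, cols, drop = FALSE]
  l <- lipid_mask[, cols, drop = FALSE] & v
  cv <- c(0, cumsum(colSums(v)))
  cl <- c(0, cumsum(colSums(l)))
  if (mode == "blocked") {
    starts <- seq.int(1L, length(cols) - wpx + 1L, by = wpx)
  } else {
    spx <- max(1L, as.integer(round(stride_mm / chem$mm_per_column)))
    starts <- seq.int(1L, length(cols) - wpx + 1L, by = spx)
  }
  nv <- cv[starts + wpx] - cv[starts]
  nl <- cl[starts + wpx] - cl[starts]
  val <- ifelse(nv > 0, 1000 * nl / nv, NA_real_)
  if (all(is.na(val)))
    stop("LCBI undefined in every window: no valid pixels", call. = FALSE)
  best <- which.max(val)                     # first maximum = smallest start
  list(value = val[best],
       start_mm = (cols[starts[best]] - 1L) * chem$mm_per_column,
       window_mm = window_mm, mode = mode)
}

#' Four-colour block classification of LCP probability
#'
#' The block chemogram display classes: red `p < 0.57`, orange
#' `0.57 <= p <= 0.84`, tan `0.84 < p <= 0.98`, yellow `p > 0.98`. The
#' published intervals overlap at 0.84 and 0.98; those boundary values are
#' assigned to the lower class (orange, tan) by fixed convention. Monotone:
#' higher probability never yields a lower class.
#'
#' @param p numeric vector of probabilities in `[0, 1]`.
#' @return Ordered factor with levels `red < orange < tan < yellow`.
#' @export
classify_block <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("block probability must lie in [0, 1]", call. = FALSE)
  cls <- ifelse(p < 0.57, "red",
         ifelse(p <= 0.84, "orange",
         ifelse(p <= 0.98, "tan", "yellow")))
  factor(cls, levels = c("red", "orange", "tan", "yellow"), ordered = TRUE)
}

#' Block chemogram: per-2 mm summary of a probability map
#'
#' Tiles the ROI into `block_mm` segments anchored at the ROI start; each
#' block's value is the 90th percentile (linear-interpolation order
#' statistic) of all pixel values in the segment, and the value is mapped to
#' the four-colour class via [classify_block()]. A trailing partial block is
#' reported with `partial = TRUE` and no colour class.
#'
#' @param value_map `H x W` numeric matrix of LCP probabilities in `[0, 1]`
#'   (see [chemogram_probability()] for recovering probabilities from pixel
#'   colours); `NA` entries (off-colormap pixels, e.g. artifacts) are ignored.
#' @param chem the source [chemogram()].
#' @param r an [roi()]; default full pullback.
#' @param block_mm block length in mm, default 2.
#' @param percentile percentile summarised per block, default 0.9.
#' @param quantile_type passed to [stats::quantile()] (default 7).
#' @return `data.frame` with `start_mm`, `value`, `class`, `partial`.
#' @export
block_chemogram <- function(value_map, chem, r = full_roi(chem), block_mm = 2,
                            percentile = 0.9, quantile_type = 7) {
  stopifnot(is.numeric(value_map), all(dim(value_map) == dim(chem$red)))
  cols <- roi_to_columns(r, chem)
  bpx <- max(1L, as.integer(round(block_mm / chem$mm_per_column)))
  if (length(cols) < bpx)
    stop("region of interest shorter than one block", call. = FALSE)
  starts <- seq.int(1L, length(cols), by = bpx)
  out <- lapply(starts, function(s) {
    e <- min(s + bpx - 1L, length(cols))
    partial <- (e - s + 1L) < bpx
    vals <- value_map[, cols[s:e], drop = FALSE]
    vals <- vals[is.finite(vals)]
    bv <- if (length(vals)) as.numeric(quantile(vals, percentile,
                                                type = quantile_type,
                                                names = FALSE)) else NA_real_
    data.frame(start_mm = (cols[s] - 1L) * chem$mm_per_column,
               value = bv,
               class = if (partial || !is.finite(bv)) NA_character_
                       else as.character(classify_block(bv)),
               partial = partial, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Longest cyclically-contiguous run of TRUE in a logical vector, in elements.
cyclic_max_run <- function(x) {
  n <- length(x)
  if (!any(x)) return(0L)
  if (all(x)) return(n)
  r <- rle(x)
  runs <- r$lengths[r$values]
  if (x[1] && x[n])  # first and last runs wrap into one
    runs <- c(runs[-c(1L, length(runs))], runs[1L] + runs[length(runs)])
  max(runs)
}

#' Maximal lipid arc per block
#'
#' For each pixel column the lipid arc is the angular extent (in degrees of
#' catheter rotation) of the largest cyclically-contiguous run of lipid rows
#' — runs wrapping the 0/360 degree seam count as one. Each block's arc is
#' the maximum over its columns. With `method = "union"` the arc is instead
#' the total angular coverage (number of lipid rows) per column.
#'
#' @param lipid_mask logical matrix.
#' @param chem the source [chemogram()].
#' @param r an [roi()]; default full pullback.
#' @param block_mm block length in mm, default 2.
#' @param method `"max_run"` (default) or `"union"`.
#' @return `data.frame` with `start_mm` and `arc_deg` in `[0, 360]`.
#' @export
max_lipid_arc <- function(lipid_mask, chem, r = full_roi(chem), block_mm = 2,
                          method = c("max_run", "union")) {
  method <- match.arg(method)
  stopifnot(is.logical(lipid_mask), all(dim(lipid_mask) == dim(chem$red)))
  cols <- roi_to_columns(r, chem)
  col_arc <- vapply(cols, function(j) {
    x <- lipid_mask[, j]
    n <- if (method == "max_run") cyclic_max_run(x) else sum(x)
    n * chem$degrees_per_row
  }, numeric(1))
  bpx <- max(1L, as.integer(round(block_mm / chem$mm_per_column)))
  starts <- seq.int(1L, length(cols), by = bpx)
  data.frame(
    start_mm = (cols[starts] - 1L) * chem$mm_per_column,
    arc_deg = vapply(starts, function(s) {
      e <- min(s + bpx - 1L, length(cols))
      max(col_arc[s:e])
    }, numeric(1)))
}
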