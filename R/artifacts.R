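#' Otsu threshold of a grayscale image
#'
#' Computes the threshold `T` that maximizes the between-class variance of
#' the two-class split of the 256-bin integer histogram (equivalently,
#' minimizes the combined within-class variance). Pixels with value `<= T`
#' form the dark class. Deterministic: among tied maxima the smallest `T`
#' is returned.
#'
#' @param img numeric matrix or vector, values in `[0, 255]` (binned to
#'   integers; no histogram smoothing).
#' @return Threshold in `[0, 255]`. A constant image yields that constant
#'   with attribute `degenerate = TRUE` (no two-class split exists).
#' @export
otsu_threshold <- function(img) {
  v <- as.vector(img)
  stopifnot(length(v) >= 1L, all(is.finite(v)))
  v <- as.integer(round(clip255(v)))
  counts <- tabulate(v + 1L, nbins = 256L)
  levels <- 0:255
  n <- length(v)
  if (sum(counts > 0L) == 1L) {
    t <- levels[counts > 0L]
    attr(t, "degenerate") <- TRUE
    return(t)
  }
  w0 <- cumsum(counts) / n                 # P(value <= t), t = 0..255
  m0 <- cumsum(counts * levels) / n        # cumulative first moment
  mu <- m0[256]
  w1 <- 1 - w0
  # between-class variance for each candidate t (both classes non-empty)
  ok <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, 256)
  sigma_b[ok] <- (mu * w0[ok] - m0[ok])^2 / (w0[ok] * w1[ok])
  levels[which.max(sigma_b)]               # which.max takes the first maximum
}

#' Connected components of a binary mask with cyclic rows
#'
#' 8-connectivity within the plane plus wrap-around across the 0/360 degree
#' row seam: the rotation axis is periodic, so a region touching both the
#' first and last rows in neighbouring columns is a single component.
#'
#' @param mask logical matrix.
#' @param min_area_px components smaller than this many pixels are dropped.
#' @return List with `mask` (the retained pixels), `labels` (integer matrix,
#'   0 = background) and `regions`, a list of regions each holding `pixels`
#'   (linear indices, column-major), `area`, and `col_range` (1-based
#'   inclusive bounding columns).
#' @export
cyclic_components <- function(mask, min_area_px = 1L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  labels <- matrix(0L, h, w)
  if (length(idx) == 0L)
    return(list(mask = mask, labels = labels, regions = list()))
  row <- ((idx - 1L) %% h) + 1L
  col <- ((idx - 1L) %/% h) + 1L
  # undirected neighbour offsets covering 8-connectivity: down, right,
  # down-right, up-right; row steps wrap cyclically
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    if (h == 1L && o[1] != 0L) next      # single row: no vertical neighbours
    nr <- ((row - 1L + o[1]) %% h) + 1L
    nc <- col + o[2]
    keep <- nc >= 1L & nc <= w
    ni <- (nc[keep] - 1L) * h + nr[keep]
    hit <- mask[ni]
    from <- c(from, idx[keep][hit])
    to <- c(to, ni[hit])
  }
  g <- igraph::make_graph(as.vector(rbind(match(from, idx), match(to, idx))),
                          n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  keep_sizes <- tabulate(memb)
  regions <- list()
  out_mask <- matrix(FALSE, h, w)
  lab <- 0L
  for (m in seq_along(keep_sizes)) {
    if (keep_sizes[m] < min_area_px) next
    lab <- lab + 1L
    px <- idx[memb == m]
    labels[px] <- lab
    out_mask[px] <- TRUE
    pc <- ((px - 1L) %/% h) + 1L
    regions[[lab]] <- list(pixels = px, area = length(px),
                           col_range = range(pc))
  }
  list(mask = out_mask, labels = labels, regions = regions)
}

#' Detect black artifact regions in the adjusted red channel
#'
#' Guide-wire shadows and calcification shadows appear as contiguous black
#' regions: pixels without enough NIRS signal. On the contrast-adjusted red
#' channel the artifacts are the dark class of the Otsu split; pixels with
#' value `<= T` are artifact candidates (ties assigned to the artifact
#' class by fixed convention). Connected components (8-connectivity, cyclic
#' rows) smaller than `min_area_px` are discarded as pixel noise.
#'
#' @param adjusted_red contrast-adjusted red channel ([adjust_intensity()]).
#' @param min_area_px minimum component area in pixels (default 8).
#' @return List with `mask` (logical artifact mask) and `regions` (see
#'   [cyclic_components()]). A degenerate (constant) channel yields an empty
#'   mask with attribute `degenerate = TRUE` on the result.
#' @export
detect_artifacts <- function(adjusted_red, min_area_px = 8L) {
  stopifnot(is.numeric(adjusted_red), is.matrix(adjusted_red))
  t <- otsu_threshold(adjusted_red)
  if (isTRUE(attr(t, "degenerate"))) {
    res <- list(mask = matrix(FALSE, nrow(adjusted_red), ncol(adjusted_red)),
                regions = list(), threshold = as.numeric(t))
    attr(res, "degenerate") <- TRUE
    return(res)
  }
  cand <- adjusted_red <= t
  cc <- cyclic_components(cand, min_area_px = min_area_px)
  list(mask = cc$mask, regions = cc$regions, threshold = as.numeric(t))
}
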