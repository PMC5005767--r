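#' Chemogram display colormap: probability to RGB and back
#'
#' The display colour scale runs linearly from red `(255, 0, 0)` at LCP
#' probability 0 to yellow `(255, 255, 0)` at probability 1, so the green
#' channel carries the probability (`green = round(255 p)`). This linear
#' red-to-yellow map is the package's invertible stand-in for the
#' proprietary console colormap and can be swapped out. The inverse recovers
#' `p = green / 255` for pixels on the colormap locus (`red = 255`,
#' `blue = 0` within `tol`) and returns `NA` for off-locus pixels such as
#' black artifacts; `colormap_inverse(colormap_forward(p))` is within
#' `1/255` of `p`.
#'
#' @param p numeric vector of probabilities in `[0, 1]`.
#' @return `colormap_forward`: `length(p) x 3` matrix of 8-bit RGB values.
#' @export
colormap_forward <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("probability must lie in [0, 1]", call. = FALSE)
  cbind(red = rep(255, length(p)), green = round(255 * p),
        blue = rep(0, length(p)))
}

#' @rdname colormap_forward
#' @param red,green,blue numeric vectors of 8-bit channel values.
#' @param tol per-channel tolerance for the locus test (default 0, exact;
#'   raise for noisy real exports — see [chemogram_probability()]).
#' @return `colormap_inverse`: probabilities, `NA` where the pixel is off
#'   the colormap locus.
#' @export
colormap_inverse <- function(red, green, blue, tol = 0) {
  p <- green / 255
  p[abs(red - 255) > tol | abs(blue) > tol] <- NA_real_
  p
}

#' Recover the LCP probability map of a chemogram
#'
#' Applies [colormap_inverse()] pixel-wise. For synthetic noiseless images
#' the default `tol = 0` is exact; real or noisy exports need a tolerance
#' so that pixels jittered off the exact red-to-yellow locus still invert —
#' an approximation whose error grows with the tolerance (off-colormap
#' colours within `tol` would be misread), so artifact-black pixels must be
#' far darker than `255 - tol`.
#'
#' @param chem a [chemogram()].
#' @param tol per-channel locus tolerance in gray levels.
#' @return `H x W` matrix of probabilities with `NA` at off-locus pixels.
#' @export
chemogram_probability <- function(chem, tol = 0) {
  stopifnot(inherits(chem, "chemogram"))
  p <- colormap_inverse(chem$red, chem$green, chem$blue, tol = tol)
  p[!is.na(p)] <- clip01(p[!is.na(p)])
  matrix(p, nrow(chem$red), ncol(chem$red))
}

#' Specify a synthetic chemogram scene
#'
#' Describes a latent lipid scene: elliptical probability plateaus with
#' steep logistic rims (the sharp plaque borders of displayed chemograms),
#' black artifact bands (guide-wire shadows spanning the pullback,
#' calcification shadows localized over lipid), pixel noise, and a seed.
#'
#' @param H,W image height (rows = degrees, cyclic) and width (columns = mm).
#' @param mm_per_column calibration, default 0.2 mm.
#' @param blobs list of lipid blobs, each
#'   `list(row, col, r_row, r_col, peak, edge_px)`: centre (pixels; rows
#'   wrap), radii (pixels), peak probability in `[0, 1]`, and rim sharpness
#'   in pixels (optional, default 0.25: the probability falls from 90% to 10%
#'   of the peak across about `4.4 * edge_px` pixels, emulating the sharp
#'   plaque borders seen on displayed chemograms).
#' @param bands list of artifact bands, each
#'   `list(row_start, row_end, col_start, col_end, darkness)`; the row range
#'   may wrap (`row_start > row_end` crosses the 0/360 seam), `darkness` is
#'   the band's gray level (default 25: near-black, but with enough headroom
#'   that additive noise is not clipped at 0 and the region's histogram mode
#'   stays at the true background level).
#' @param noise_sd additive Gaussian noise per channel, gray levels
#'   (default 8).
#' @param hidden_contrast green-channel bump of shadowed lipid above the
#'   artifact darkness, gray levels (default 60): the attenuated trace the
#'   hidden-lipid detector looks for.
#' @param base_prob baseline LCP probability of the arterial wall
#'   (default 0: pure red background). Real chemograms show a mottled
#'   low-probability wall rather than uniform red.
#' @param texture_amp amplitude of a smooth low-frequency modulation of the
#'   wall baseline (default 0; must not exceed `base_prob`). The modulation
#'   is cyclic in rows so the wall texture is continuous across the 0/360
#'   degree seam.
#' @param seed integer seed governing the whole scene.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(H, W, mm_per_column = 0.2, blobs = list(),
                       bands = list(), noise_sd = 8, hidden_contrast = 60,
                       base_prob = 0, texture_amp = 0, seed = 1L) {
  stopifnot(H >= 1, W >= 1, mm_per_column > 0, noise_sd >= 0,
            hidden_contrast >= 0, base_prob >= 0, texture_amp >= 0,
            texture_amp <= base_prob, base_prob + texture_amp < 0.5)
  for (b in blobs) {
    stopifnot(b$peak >= 0, b$peak <= 1, b$r_row > 0, b$r_col > 0)
    if (b$col < 1 || b$col > W)
      stop("blob centre column outside image bounds", call. = FALSE)
  }
  for (a in bands) {
    stopifnot(a$row_start >= 1, a$row_start <= H,
              a$row_end >= 1, a$row_end <= H)
    if (a$col_start < 1 || a$col_end > W || a$col_start > a$col_end)
      stop("artifact band columns outside image bounds", call. = FALSE)
  }
  structure(list(H = as.integer(H), W = as.integer(W),
                 mm_per_column = mm_per_column, blobs = blobs, bands = bands,
                 noise_sd = noise_sd, hidden_contrast = hidden_contrast,
                 base_prob = base_prob, texture_amp = texture_amp,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# rows of a band, honouring wrap across the 0/360 seam
band_rows <- function(a, H) {
  if (a$row_start <= a$row_end) a$row_start:a$row_end
  else c(a$row_start:H, 1:a$row_end)
}

#' Generate a synthetic chemogram with ground truth
#'
#' Builds the latent LCP-probability map by superposing the scene's blobs
#' (elliptical plateaus with logistic rims, cyclic in rows, clipped to
#' `[0, 1]`), renders
#' it through the red-to-yellow colormap, paints artifact bands near-black
#' — with shadowed lipid leaving a green-channel trace of
#' `hidden_contrast` gray levels — and adds clipped Gaussian pixel noise.
#' Ground-truth masks are taken before noise: `lipid_truth` is the latent
#' probability at the 0.6 LCBI cut, `hidden_truth = artifact & lipid`.
#' Deterministic given the scene seed.
#'
#' @param spec a [scene_spec()].
#' @return List with `chemogram` (a [chemogram()]) and `truth`: a list with
#'   `probability_map`, masks `lipid`, `artifact`, `hidden`, `valid`
#'   (non-artifact pixels plus shadowed lipid, the pixels carrying lipid
#'   information), `lipid_fraction` over valid pixels, and true
#'   `lcbi_total`, `max_lcbi_2mm`, `max_lcbi_4mm` (sliding windows).
#' @export
generate_chemogram <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  H <- spec$H; W <- spec$W
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(rep(seq_len(W), each = H), H, W)
  p <- matrix(spec$base_prob, H, W)
  if (spec$texture_amp > 0) {
    # smooth mottling of the wall; integer row frequency keeps the texture
    # continuous across the 0/360 degree seam
    k <- sample(1:3, 1)
    m <- sample(1:4, 1)
    phi_r <- runif(1, 0, 2 * pi)
    phi_c <- runif(1, 0, 2 * pi)
    p <- p + spec$texture_amp *
      cos(2 * pi * k * rows / H + phi_r) * cos(2 * pi * m * cols / W + phi_c)
  }
  for (b in spec$blobs) {
    dr <- abs(rows - b$row)
    dr <- pmin(dr, H - dr)                     # cyclic row distance
    dc <- cols - b$col
    rho <- sqrt((dr / b$r_row)^2 + (dc / b$r_col)^2)
    edge <- if (is.null(b$edge_px)) 0.25 else b$edge_px
    # plateau at peak inside the ellipse, logistic fall-off ~edge_px wide
    t <- (rho - 1) * min(b$r_row, b$r_col) / edge
    p <- p + b$peak * stats::plogis(-t)
  }
  p <- clip01(p)
  lipid <- p >= 0.6
  artifact <- matrix(FALSE, H, W)
  darkness <- matrix(0, H, W)
  for (a in spec$bands) {
    rr <- band_rows(a, H)
    cc <- a$col_start:a$col_end
    artifact[rr, cc] <- TRUE
    dk <- if (is.null(a$darkness)) 25 else a$darkness
    darkness[rr, cc] <- dk
  }
  hidden <- artifact & lipid
  rgb <- colormap_forward(as.vector(p))
  r <- matrix(rgb[, 1], H, W)
  g <- matrix(rgb[, 2], H, W)
  b <- matrix(rgb[, 3], H, W)
  r[artifact] <- darkness[artifact]
  g[artifact] <- darkness[artifact]
  b[artifact] <- darkness[artifact]
  g[hidden] <- darkness[hidden] + spec$hidden_contrast
  if (spec$noise_sd > 0) {
    r <- r + rnorm(H * W, 0, spec$noise_sd)
    g <- g + rnorm(H * W, 0, spec$noise_sd)
    b <- b + rnorm(H * W, 0, spec$noise_sd)
  }
  chem <- chemogram(red = round(clip255(r)), green = round(clip255(g)),
                    blue = round(clip255(b)),
                    mm_per_column = spec$mm_per_column)
  valid <- !artifact | hidden
  lf <- sum(lipid & valid) / sum(valid)
  truth <- list(probability_map = p, lipid = lipid, artifact = artifact,
                hidden = hidden, valid = valid, lipid_fraction = lf,
                lcbi_total = 1000 * lf)
  pb <- chem$pullback_length_mm
  if (pb >= 2)
    truth$max_lcbi_2mm <- max_lcbi_window(lipid, valid, chem,
                                          window_mm = 2, mode = "sliding")
  if (pb >= 4)
    truth$max_lcbi_4mm <- max_lcbi_window(lipid, valid, chem,
                                          window_mm = 4, mode = "sliding")
  list(chemogram = chem, truth = truth)
}

#' Draw a random scene specification
#'
#' Samples the study conditions emulated by the generator: 1-4 lipid blobs
#' with steep borders and peak probability 0.85-1, sized so that LCBI_total
#' falls in the tens-to-low-hundreds range typical of clinical pullbacks,
#' a mottled arterial-wall background at baseline LCP probability 0.08-0.28,
#' one guide-wire shadow band 15-30 degrees tall spanning the full pullback, up to two
#' calcification shadows partially covering lipid blobs (each shadow extends
#' well beyond the lipid it covers — a calcium shadow darkens everything
#' behind the calcium, lipid and wall alike — so the region's modal gray
#' level is the shadow background, as the hidden-lipid detector assumes),
#' and pixel noise of 8 gray levels.
#'
#' @param seed integer seed.
#' @param H,W image size (default 180 rows x 250 columns, i.e. 2 degrees per
#'   row and 50 mm at 0.2 mm per column).
#' @param mm_per_column calibration, default 0.2.
#' @param noise_sd noise level, default 8.
#' @param n_calc_shadows number of calcification shadows (`0:2` sampled if
#'   `NULL`).
#' @return A [scene_spec()].
#' @export
random_scene_spec <- function(seed, H = 180L, W = 250L, mm_per_column = 0.2,
                              noise_sd = 8, n_calc_shadows = NULL) {
  set.seed(seed)
  n_blobs <- sample(1:4, 1)
  # one plaque per pullback segment: distinct lesions at distinct positions
  seg_w <- W / n_blobs
  blobs <- lapply(seq_len(n_blobs), function(i) {
    list(row = sample(H, 1),
         col = round((i - 1) * seg_w + runif(1, 0.35, 0.65) * seg_w),
         r_row = runif(1, H / 14, H / 7),
         r_col = runif(1, W / 25, min(W / 10, seg_w / 2.6)),
         peak = runif(1, 0.85, 1))
  })
  gw_height <- round(runif(1, 15, 30) / (360 / H))   # 15-30 degrees tall
  gw_start <- sample(H, 1)
  bands <- list(list(row_start = gw_start,
                     row_end = ((gw_start + gw_height - 1L) %% H) + 1L,
                     col_start = 1L, col_end = W, darkness = 25))
  if (is.null(n_calc_shadows)) n_calc_shadows <- sample(0:2, 1)
  for (k in seq_len(min(n_calc_shadows, n_blobs))) {
    # shadow over the blob's upper half, reaching far into the background
    # above it: most of the region is shadow background, not lipid
    b <- blobs[[k]]
    h2 <- round(2.2 * b$r_row); w2 <- max(3L, round(0.8 * b$r_col))
    rs <- ((b$row - 1L - h2) %% H) + 1L
    bands[[length(bands) + 1L]] <-
      list(row_start = rs, row_end = ((b$row - 1L) %% H) + 1L,
           col_start = max(1L, b$col - w2),
           col_end = min(W, b$col + w2), darkness = 25)
  }
  base_prob <- runif(1, 0.08, 0.22)
  scene_spec(H = H, W = W, mm_per_column = mm_per_column, blobs = blobs,
             bands = bands, noise_sd = noise_sd, base_prob = base_prob,
             texture_amp = runif(1, 0.02, min(0.06, base_prob)),
             seed = seed)
}

#' Generate a paired synthetic dataset with a truth metric table
#'
#' Seeded collection of varied scenes plus the table of true LCBI metrics
#' per case, for end-to-end method-agreement testing (e.g. 31 cases,
#' mirroring a typical clinical study size).
#'
#' @param n_cases number of scenes.
#' @param seed master seed; case `i` uses seed `seed * 1000 + i` (keep
#'   `seed` below ~2e6).
#' @param ... passed to [random_scene_spec()].
#' @return List with `scenes` (list of [generate_chemogram()] results) and
#'   `truth_table`: `data.frame` of `case`, `lcbi_total`, `max_lcbi_2mm`,
#'   `max_lcbi_4mm`, all in `[0, 1000]`.
#' @export
generate_paired_dataset <- function(n_cases = 31L, seed = 1L, ...) {
  stopifnot(n_cases >= 1L)
  scenes <- lapply(seq_len(n_cases), function(i) {
    generate_chemogram(random_scene_spec(seed = seed * 1000L + i, ...))
  })
  truth_table <- data.frame(
    case = seq_len(n_cases),
    lcbi_total = vapply(scenes, function(s) s$truth$lcbi_total, numeric(1)),
    max_lcbi_2mm = vapply(scenes, function(s) s$truth$max_lcbi_2mm$value,
                          numeric(1)),
    max_lcbi_4mm = vapply(scenes, function(s) s$truth$max_lcbi_4mm$value,
                          numeric(1)))
  list(scenes = scenes, truth_table = truth_table)
}
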