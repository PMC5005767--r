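#' Pipeline configuration
#'
#' Collects every tunable parameter of the detection pipeline with its
#' default. Defaults: 1% intensity saturation at both ends, minimum artifact
#' area 8 px, hidden-lipid analysis on the green channel with a 25 gray-level
#' difference threshold, sliding maxLCBI windows with a one-column stride,
#' 2 mm blocks, linear-interpolation percentiles, and valid pixels = ROI
#' minus artifact plus artifact pixels reclaimed as hidden lipid.
#'
#' @param low_frac,high_frac saturated intensity fractions
#'   ([adjust_intensity()]).
#' @param min_artifact_area_px minimum artifact component area
#'   ([detect_artifacts()]).
#' @param delta_threshold hidden-lipid gray-level difference
#'   ([detect_hidden_lipid()]).
#' @param mode_bandwidth histogram-smoothing half-width for the hidden-lipid
#'   background estimate ([detect_hidden_lipid()]).
#' @param visible_min_contrast minimum lipid/wall class contrast in gray
#'   levels for the visible-lipid Otsu split to be trusted
#'   ([detect_visible_lipid()]); below it the scene is treated as having no
#'   bimodal lipid class.
#' @param lipid_fallback what to do when the contrast guard rejects the
#'   visible-lipid split: `"colormap"` (default) marks pixels whose
#'   approximate inverse-colormap LCP probability exceeds 0.6 — the LCBI
#'   pixel definition — as visible lipid; `"none"` leaves the mask empty.
#' @param hidden_channel channel analysed inside artifact regions:
#'   `"green"` (default), `"red"` or `"blue"`.
#' @param window_mode `"sliding"` (default) or `"blocked"`
#'   ([max_lcbi_window()]).
#' @param stride_mm sliding stride in mm; `NULL` = one pixel column.
#' @param block_mm block length for block chemogram and lipid arc.
#' @param quantile_type percentile convention ([stats::quantile()]).
#' @param valid_convention `"reclaim"` (hidden-lipid pixels count as valid,
#'   default) or `"strict"` (all artifact pixels excluded); both LCBI totals
#'   are reported either way.
#' @param probability_tol colormap-inverse tolerance for the block
#'   chemogram on noisy images ([chemogram_probability()]).
#' @param arc_method lipid-arc definition ([max_lipid_arc()]).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(low_frac = 0.01, high_frac = 0.01,
                            min_artifact_area_px = 8L,
                            delta_threshold = 25,
                            mode_bandwidth = 5,
                            visible_min_contrast = 80,
                            lipid_fallback = c("colormap", "none"),
                            hidden_channel = c("green", "red", "blue"),
                            window_mode = c("sliding", "blocked"),
                            stride_mm = NULL, block_mm = 2,
                            quantile_type = 7,
                            valid_convention = c("reclaim", "strict"),
                            probability_tol = 60,
                            arc_method = c("max_run", "union")) {
  cfg <- list(low_frac = low_frac, high_frac = high_frac,
              min_artifact_area_px = as.integer(min_artifact_area_px),
              delta_threshold = delta_threshold,
              mode_bandwidth = mode_bandwidth,
              visible_min_contrast = visible_min_contrast,
              lipid_fallback = match.arg(lipid_fallback),
              hidden_channel = match.arg(hidden_channel),
              window_mode = match.arg(window_mode),
              stride_mm = stride_mm, block_mm = block_mm,
              quantile_type = quantile_type,
              valid_convention = match.arg(valid_convention),
              probability_tol = probability_tol,
              arc_method = match.arg(arc_method))
  stopifnot(cfg$low_frac >= 0, cfg$high_frac >= 0,
            cfg$low_frac + cfg$high_frac < 1,
            cfg$delta_threshold > 0, cfg$min_artifact_area_px >= 1L,
            cfg$block_mm > 0)
  structure(cfg, class = c("pipeline_config", "list"))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full lipid-pool detection pipeline
#'
#' Executes the four stages in order — per-channel preprocessing
#' (contrast stretch), artifact segmentation (Otsu on the adjusted red
#' channel), lipid segmentation (Otsu on the green channel outside
#' artifacts, plus background-intensity analysis inside artifact regions;
#' both on the unsaturated channel, since saturation can erase the very
#' intensity structure these stages measure) —
#' and computes the LCBI metrics, block chemogram and lipid arcs. Fully
#' deterministic for a fixed input and configuration; any stage error is
#' re-raised with the stage name attached.
#'
#' @param chem a [chemogram()].
#' @param r an [roi()]; default full pullback.
#' @param cfg a [pipeline_config()].
#' @param verbose emit per-stage summaries via [message()].
#' @return List with `report` (LCBI metrics, block chemogram, lipid arcs,
#'   thresholds, ROI and config echo — serializable with [write_report()])
#'   and `masks` (logical matrices: `artifact`, `lipid_visible`,
#'   `lipid_hidden`, `lipid_combined`, `valid`).
#' @export
run_pipeline <- function(chem, r = full_roi(chem), cfg = pipeline_config(),
                         verbose = FALSE) {
  stopifnot(inherits(chem, "chemogram"), inherits(cfg, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  raw_channels <- split_channels(chem)
  channels <- with_stage("preprocess", {
    lapply(raw_channels, adjust_intensity, low_frac = cfg$low_frac,
           high_frac = cfg$high_frac, quantile_type = cfg$quantile_type)
  })

  art <- with_stage("artifacts", {
    detect_artifacts(channels$red, min_area_px = cfg$min_artifact_area_px)
  })
  say("artifacts: threshold %d, %d regions, %d px", art$threshold,
      length(art$regions), sum(art$mask))

  lip <- with_stage("lipid", {
    # the Otsu stages are invariant to the linear part of the contrast
    # stretch, so the adjustment influences them only through its saturation
    # clip; on the green channel that clip can merge a small lipid class
    # into the saturated background tail, so the lipid stages analyse the
    # unsaturated channel
    visible <- detect_visible_lipid(raw_channels$green, art$mask,
                                    min_contrast = cfg$visible_min_contrast)
    if (isTRUE(attr(visible, "low_contrast")) &&
        cfg$lipid_fallback == "colormap") {
      # no bimodal lipid class in the green histogram (little or no visible
      # lipid): fall back to the LCBI pixel definition on the approximate
      # inverse-colormap probability scale
      pmap <- chemogram_probability(chem, tol = cfg$probability_tol)
      visible <- !is.na(pmap) & pmap > 0.6 & !art$mask
    }
    # hidden-lipid analysis also runs on the unsaturated channel: the
    # contrast stretch clips the brightest pixels to 255, and inside a dark
    # shadow the lipid trace is often among them — saturation would collapse
    # the very intensity differences this stage measures
    hidden <- detect_hidden_lipid(raw_channels[[cfg$hidden_channel]],
                                  art$regions,
                                  delta_threshold = cfg$delta_threshold,
                                  mode_bandwidth = cfg$mode_bandwidth)
    comb <- combine_lipid(visible, hidden)
    list(visible = visible, hidden = hidden, combined = comb$mask,
         regions = comb$regions)
  })
  say("lipid: %d visible px, %d hidden px", sum(lip$visible), sum(lip$hidden))

  valid_reclaim <- !art$mask | lip$hidden
  valid_strict <- !art$mask
  valid <- if (cfg$valid_convention == "reclaim") valid_reclaim else
    valid_strict

  report <- with_stage("metrics", {
    cols <- roi_to_columns(r, chem)
    stride <- if (is.null(cfg$stride_mm)) chem$mm_per_column else
      cfg$stride_mm
    m2 <- max_lcbi_window(lip$combined, valid, chem, r, window_mm = 2,
                          mode = cfg$window_mode, stride_mm = stride)
    m4 <- max_lcbi_window(lip$combined, valid, chem, r, window_mm = 4,
                          mode = cfg$window_mode, stride_mm = stride)
    pmap <- chemogram_probability(chem, tol = cfg$probability_tol)
    pmap[art$mask] <- NA_real_
    blocks <- block_chemogram(pmap, chem, r, block_mm = cfg$block_mm,
                              quantile_type = cfg$quantile_type)
    arcs <- max_lipid_arc(lip$combined, chem, r, block_mm = cfg$block_mm,
                          method = cfg$arc_method)
    blocks$arc_deg <- arcs$arc_deg[match(blocks$start_mm, arcs$start_mm)]
    list(
      lcbi_total = lcbi_total(lip$combined, valid, cols),
      lcbi_total_strict = lcbi_total(lip$combined & valid_strict,
                                     valid_strict, cols),
      max_lcbi_2mm = list(value = m2$value, start_mm = m2$start_mm),
      max_lcbi_4mm = list(value = m4$value, start_mm = m4$start_mm),
      mode = cfg$window_mode,
      roi = list(start_mm = r$start_mm, end_mm = r$end_mm),
      otsu_threshold_red = art$threshold,
      n_artifact_regions = length(art$regions),
      blocks = blocks,
      config = unclass(cfg))
  })
  say("metrics: LCBI_total %.1f, maxLCBI_2mm %.1f, maxLCBI_4mm %.1f",
      report$lcbi_total, report$max_lcbi_2mm$value,
      report$max_lcbi_4mm$value)

  list(report = report,
       masks = list(artifact = art$mask, lipid_visible = lip$visible,
                    lipid_hidden = lip$hidden, lipid_combined = lip$combined,
                    valid = valid))
}

#' Compare paired per-case metrics between two methods
#'
#' Builds the full agreement table for each shared metric column of two
#' per-case tables (e.g. pipeline output vs a reference system, or vs
#' generator ground truth): paired Wilcoxon signed-rank p-value, ICC(2,1)
#' with 95% CI, Bland-Altman mean difference and limits of agreement, and
#' median (Q1-Q3) per method.
#'
#' @param table1,table2 `data.frame`s (or CSV paths) with a `case` column of
#'   matching identifiers plus one column per metric.
#' @param metrics metric columns to compare; default all columns shared by
#'   both tables except `case`.
#' @return Named list (one entry per metric) of agreement results.
#' @export
compare_methods <- function(table1, table2, metrics = NULL) {
  read_tab <- function(x) {
    if (is.character(x)) x <- utils::read.csv(x)
    stopifnot(is.data.frame(x), "case" %in% names(x))
    x
  }
  t1 <- read_tab(table1); t2 <- read_tab(table2)
  missing1 <- setdiff(t2$case, t1$case)
  missing2 <- setdiff(t1$case, t2$case)
  if (length(missing1) || length(missing2))
    stop("unmatched case identifiers: ",
         paste(unique(c(missing1, missing2)), collapse = ", "),
         call. = FALSE)
  t2 <- t2[match(t1$case, t2$case), , drop = FALSE]
  if (is.null(metrics))
    metrics <- setdiff(intersect(names(t1), names(t2)), "case")
  out <- lapply(metrics, function(m) {
    a <- t1[[m]]; b <- t2[[m]]
    w <- paired_wilcoxon(a, b)
    ic <- icc(a, b)
    ba <- bland_altman(a, b)
    list(metric = m,
         n = length(a),
         wilcoxon_p = w$p_value,
         icc_estimate = ic$estimate,
         icc_ci_low = ic$ci_low, icc_ci_high = ic$ci_high,
         bland_altman = ba[c("mean_diff", "loa_low", "loa_high", "sd_diff")],
         method1 = summarize_values(a),
         method2 = summarize_values(b))
  })
  names(out) <- metrics
  out
}
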