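no_artifacts <- function(img) matrix(FALSE, nrow(img), ncol(img))

test_that("a yellow blob on red background is segmented as visible lipid", {
  sp <- scene_spec(H = 90, W = 120,
                   blobs = list(list(row = 45, col = 60, r_row = 15,
                                     r_col = 20, peak = 1)),
                   noise_sd = 4, seed = 2)
  sc <- generate_chemogram(sp)
  adj <- adjust_intensity(sc$chemogram$green)
  vis <- detect_visible_lipid(adj, no_artifacts(adj))
  expect_gte(jaccard_brute(vis, sc$truth$lipid), 0.95)
})

test_that("a pure-red chemogram yields no lipid", {
  ch <- chem_from_prob(matrix(0, 20, 30))
  adj <- adjust_intensity(ch$green)
  vis <- detect_visible_lipid(adj, no_artifacts(adj))
  expect_equal(sum(vis), 0)
  expect_true(attr(vis, "degenerate"))
})

test_that("lipid under an artifact is excluded from the visible mask", {
  sp <- scene_spec(H = 90, W = 120,
                   blobs = list(list(row = 45, col = 60, r_row = 18,
                                     r_col = 24, peak = 1)),
                   bands = list(list(row_start = 10, row_end = 45,
                                     col_start = 45, col_end = 75,
                                     darkness = 25)),
                   noise_sd = 4, seed = 3)
  sc <- generate_chemogram(sp)
  adj_r <- adjust_intensity(sc$chemogram$red)
  adj_g <- adjust_intensity(sc$chemogram$green)
  art <- detect_artifacts(adj_r)
  vis <- detect_visible_lipid(adj_g, art$mask)
  expect_equal(sum(vis & art$mask), 0)
  truth_visible <- sc$truth$lipid & !sc$truth$artifact
  expect_gte(jaccard_brute(vis, truth_visible), 0.9)
})

test_that("hidden lipid follows the mode-plus-difference rule per region", {
  img <- matrix(12, 30, 40)
  img[10:14, 10:14] <- 60                     # patch 48 above background
  img[20:22, 30:32] <- 30                     # patch 18 above background
  regions <- list(list(pixels = which(matrix(TRUE, 30, 40)), area = 1200))
  hid <- detect_hidden_lipid(img, regions, delta_threshold = 25)
  expect_true(all(hid[10:14, 10:14]))         # 48 > 25 -> marked
  expect_false(any(hid[20:22, 30:32]))        # 18 <= 25 -> not marked
  expect_equal(sum(hid), 25)

  # uniform region: no intensity change, nothing marked
  expect_equal(sum(detect_hidden_lipid(matrix(10, 5, 5),
    list(list(pixels = 1:25, area = 25)), 25)), 0)

  # single-pixel region: background is that pixel, no hidden lipid possible
  expect_equal(sum(detect_hidden_lipid(matrix(200, 3, 3),
    list(list(pixels = 5L, area = 1L)), 25)), 0)
})

test_that("background mode ties break toward the darker gray level", {
  vals <- c(rep(10, 10), rep(40, 10), rep(70, 5))
  img <- matrix(vals, 5, 5)
  hid <- detect_hidden_lipid(img, list(list(pixels = 1:25, area = 25)),
                             delta_threshold = 25)
  # mode tie 10 vs 40 resolves to 10: pixels above 35 are marked
  expect_equal(sum(hid), sum(vals > 35))
})

test_that("decreasing delta_threshold never removes hidden pixels", {
  set.seed(77)
  img <- matrix(sample(0:120, 600, replace = TRUE), 20, 30)
  regions <- list(list(pixels = which(matrix(TRUE, 20, 30)), area = 600))
  prev <- NULL
  for (delta in c(80, 60, 40, 20, 10)) {
    cur <- detect_hidden_lipid(img, regions, delta_threshold = delta)
    if (!is.null(prev)) expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("hidden lipid never escapes the artifact mask in full scenes", {
  for (s in 301:305) {
    sc <- generate_chemogram(random_scene_spec(seed = s, H = 90, W = 120))
    res <- run_pipeline(sc$chemogram)
    expect_equal(sum(res$masks$lipid_hidden & !res$masks$artifact), 0)
  }
})

test_that("combine_lipid unions masks and reconnects bridged blobs", {
  a <- matrix(FALSE, 10, 10); a[2:4, 2:4] <- TRUE
  b <- matrix(FALSE, 10, 10)
  expect_identical(combine_lipid(a, b)$mask, a)

  b[7:9, 7:9] <- TRUE
  comb <- combine_lipid(a, b)
  expect_equal(sum(comb$mask), sum(a) + sum(b))   # disjoint: areas add
  expect_length(comb$regions, 2)

  # an artifact stripe splits a blob; hidden detection bridges it back
  vis <- matrix(FALSE, 12, 12)
  vis[3:9, 3:5] <- TRUE; vis[3:9, 8:10] <- TRUE   # blob minus stripe
  hid <- matrix(FALSE, 12, 12); hid[3:9, 6:7] <- TRUE
  expect_length(combine_lipid(vis, matrix(FALSE, 12, 12))$regions, 2)
  expect_length(combine_lipid(vis, hid)$regions, 1)

  expect_error(combine_lipid(a, matrix(FALSE, 3, 3)), "dimensions")
})
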