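mask_chem <- function(h, w, mm_per_column = 0.2) {
  m <- matrix(255, h, w)
  chemogram(m, m, m, mm_per_column = mm_per_column)
}

test_that("lcbi_total implements the lipid-fraction-times-1000 definition", {
  all_true <- matrix(TRUE, 10, 12)
  expect_equal(lcbi_total(all_true, all_true), 1000)
  expect_equal(lcbi_total(!all_true, all_true), 0)
  lipid <- matrix(FALSE, 30, 40)
  lipid[1:10, 1:30] <- TRUE                    # 300 of 1200 valid
  expect_equal(lcbi_total(lipid, matrix(TRUE, 30, 40)), 250)
  expect_error(lcbi_total(lipid, matrix(FALSE, 30, 40)), "no valid pixels")
})

test_that("lcbi_total is invariant to row rotation of the masks", {
  set.seed(9)
  lipid <- matrix(runif(800) < 0.3, 20, 40)
  valid <- matrix(runif(800) < 0.9, 20, 40)
  valid <- valid | lipid
  base <- lcbi_total(lipid, valid)
  for (k in c(3, 11)) {
    idx <- c((k + 1):20, 1:k)
    expect_equal(lcbi_total(lipid[idx, ], valid[idx, ]), base)
  }
})

test_that("boundary-straddling lipid separates sliding from blocked maxima", {
  ch <- mask_chem(18, 60, mm_per_column = 0.2)  # 12 mm pullback
  valid <- matrix(TRUE, 18, 60)
  lipid <- matrix(FALSE, 18, 60)
  lipid[, 11:30] <- TRUE   # 4 mm of lipid straddling the 4 mm tile boundary
  sl <- max_lcbi_window(lipid, valid, ch, window_mm = 4, mode = "sliding")
  bl <- max_lcbi_window(lipid, valid, ch, window_mm = 4, mode = "blocked")
  expect_equal(sl$value, 1000)
  expect_equal(sl$start_mm, 2)
  expect_equal(bl$value, 500)
  expect_gte(sl$value, bl$value)
})

test_that("uniform lipid gives equal windows with the tie at the ROI start", {
  ch <- mask_chem(10, 50)
  valid <- matrix(TRUE, 10, 50)
  lipid <- matrix(FALSE, 10, 50)
  lipid[1:4, ] <- TRUE                          # fraction 0.4 in every column
  for (mode in c("sliding", "blocked")) {
    res <- max_lcbi_window(lipid, valid, ch, window_mm = 2, mode = mode)
    expect_equal(res$value, 400)
    expect_equal(res$start_mm, 0)
  }
})

test_that("windows longer than the ROI are rejected", {
  ch <- mask_chem(10, 20, mm_per_column = 0.1)  # 2 mm pullback
  m <- matrix(TRUE, 10, 20)
  expect_error(max_lcbi_window(m, m, ch, window_mm = 4), "longer than")
})

test_that("blocked maxima match a brute-force evaluation of every placement", {
  set.seed(41)
  for (i in 1:10) {
    ch <- mask_chem(12, 55)
    lipid <- matrix(runif(12 * 55) < 0.25, 12, 55)
    valid <- matrix(TRUE, 12, 55)
    res <- max_lcbi_window(lipid, valid, ch, window_mm = 2, mode = "sliding")
    # oracle: evaluate every window of 10 columns directly
    vals <- sapply(1:46, function(s)
      1000 * sum(lipid[, s:(s + 9)]) / (12 * 10))
    expect_equal(res$value, max(vals))
    expect_equal(res$start_mm, (which.max(vals) - 1) * 0.2)
  }
})

test_that("block values are 90th percentiles with partial-tail flagging", {
  ch <- mask_chem(10, 25, mm_per_column = 0.2)  # 5 mm: blocks at 0, 2, 4 mm
  vals <- matrix(runif(250), 10, 25)
  bc <- block_chemogram(vals, ch)
  expect_equal(bc$start_mm, c(0, 2, 4))
  expect_equal(bc$partial, c(FALSE, FALSE, TRUE))
  expect_true(is.na(bc$class[3]))
  # sorted-array oracle on the first block (columns 1..10)
  expect_equal(bc$value[1],
               unname(quantile(as.vector(vals[, 1:10]), 0.9, type = 7)))
  # constant tile -> block value is that constant
  const <- matrix(0.3, 10, 25)
  expect_equal(block_chemogram(const, ch)$value[1], 0.3)
})

test_that("classify_block reproduces the four-colour probability scheme", {
  expect_equal(as.character(classify_block(0.50)), "red")
  expect_equal(as.character(classify_block(0.99)), "yellow")
  expect_equal(as.character(classify_block(0.57)), "orange")
  expect_equal(as.character(classify_block(0.84)), "orange")  # lower class
  expect_equal(as.character(classify_block(0.98)), "tan")     # lower class
  expect_error(classify_block(1.2), "\\[0, 1\\]")
  # monotone across the grid
  grid <- seq(0, 1, by = 0.001)
  cls <- classify_block(grid)
  expect_true(all(diff(as.integer(cls)) >= 0))
})

test_that("lipid arcs measure cyclic angular runs per block", {
  ch <- mask_chem(360, 10, mm_per_column = 0.2)  # 1 degree per row
  lipid <- matrix(FALSE, 360, 10)
  lipid[, 1] <- TRUE                             # full circle
  lipid[100:189, 2] <- TRUE                      # 90 contiguous degrees
  lipid[c(350:360, 1:19), 3] <- TRUE             # 30 degrees over the seam
  arcs <- max_lipid_arc(lipid, ch, block_mm = 0.2)
  expect_equal(arcs$arc_deg[1], 360)
  expect_equal(arcs$arc_deg[2], 90)
  expect_equal(arcs$arc_deg[3], 30)
  expect_equal(arcs$arc_deg[4], 0)
  # block arc is the max over the block's columns
  whole <- max_lipid_arc(lipid, ch, block_mm = 2)
  expect_equal(whole$arc_deg[1], 360)
})

test_that("cyclic run lengths agree with a walk-from-every-start oracle", {
  set.seed(61)
  for (i in 1:50) {
    x <- runif(sample(2:24, 1)) < 0.5
    ch <- mask_chem(length(x), 3)
    arcs <- max_lipid_arc(matrix(x, length(x), 3), ch, block_mm = 0.6)
    expect_equal(arcs$arc_deg[1], cyclic_run_brute(x) * (360 / length(x)))
  }
})
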