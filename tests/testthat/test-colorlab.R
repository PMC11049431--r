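test_that("segmentation is binary, sized, empty on blank input, and accurate on renders", {
  blank <- array(1, dim = c(32, 32, 3))
  m0 <- segment_foreground(blank)
  expect_identical(dim(m0), c(32L, 32L))
  expect_type(m0, "logical")
  expect_false(any(m0))

  co <- small_cohort()
  cfg <- small_render_cfg()
  for (id in c(1L, 5L)) {
    r <- render_fruit_image(co$trajectories[[id]], day = 0, side = "front",
                            cfg = cfg, seed = 2L)
    m <- segment_foreground(r$image)
    iou <- sum(m & r$mask) / sum(m | r$mask)
    expect_gte(iou, 0.95)
  }
})

test_that("identity calibration is recovered with zero residual", {
  pts <- matrix(c(50, 0, 0,  70, 10, 20,  30, -20, 5,  60, 5, -15,
                  40, 25, 25, 80, -5, 40), ncol = 3, byrow = TRUE)
  cal <- fit_color_calibration(pts, pts)
  expect_lt(cal$rmse, 1e-9)
  expect_equal(predict(cal, pts), pts, ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("a known affine distortion is inverted to numerical precision", {
  ref <- withr::with_seed(5, cbind(runif(12, 20, 90), runif(12, -40, 40),
                                   runif(12, -40, 40)))
  A <- matrix(c(0.95, 0.02, -0.01,
                0.03, 1.05, 0.00,
                -0.02, 0.01, 0.98), 3, 3, byrow = TRUE)
  b <- c(2, -1, 0.5)
  device <- ref %*% A + matrix(b, nrow(ref), 3, byrow = TRUE)
  cal <- fit_color_calibration(device, ref, form = "affine")
  expect_lt(cal$rmse, 1e-6)
  expect_equal(predict(cal, device), ref, ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("underdetermined calibrations error", {
  expect_error(fit_color_calibration(matrix(1:6, 2), matrix(1:6, 2)),
               "underdetermined")
  expect_error(fit_color_calibration(matrix(1:24, 8), matrix(1:24, 8),
                                     form = "quadratic"), "underdetermined")
})

test_that("planted five-block palettes are recovered with equal weights", {
  img <- array(0, dim = c(50, 50, 3))
  cols <- matrix(c(0.8, 0.2, 0.2,  0.2, 0.7, 0.3,  0.2, 0.3, 0.8,
                   0.9, 0.9, 0.3,  0.3, 0.3, 0.3), ncol = 3, byrow = TRUE)
  for (b in 1:5) for (ch in 1:3) img[, ((b - 1) * 10 + 1):(b * 10), ch] <- cols[b, ch]
  pal <- extract_palette(img, matrix(TRUE, 50, 50), k = 5, seed = 1L)
  expect_equal(sum(pal$weight), 1)
  expect_true(all(abs(pal$weight - 0.2) < 1e-12))
  truth <- avoripen:::rgb_to_lab(cols)
  for (i in seq_len(5)) {
    d <- sqrt(colSums((t(as.matrix(as.data.frame(pal)[, c("L", "a", "b")])) - truth[i, ])^2))
    expect_lt(min(d), 0.5)
  }
  # deterministic given the seed
  expect_identical(extract_palette(img, matrix(TRUE, 50, 50), k = 5, seed = 1L), pal)
})

test_that("uniform images collapse to a single effective colour", {
  img <- array(0.5, dim = c(20, 20, 3))
  pal <- extract_palette(img, matrix(TRUE, 20, 20), k = 5, seed = 1L)
  expect_identical(nrow(pal), 1L)
  expect_equal(pal$weight, 1)
  expect_error(extract_palette(img, matrix(FALSE, 20, 20)), "empty mask")
})

test_that("palette aggregation recovers planted colour mixtures and orders by weight", {
  anchors <- matrix(c(65, -15, 40,  50, -5, 25,  40, 8, 10,
                      30, 12, -5,  20, 6, -2,  80, 0, 0), ncol = 3, byrow = TRUE)
  share <- c(0.30, 0.25, 0.15, 0.12, 0.10, 0.08)
  pals <- withr::with_seed(11, lapply(1:40, function(i) {
    pick <- sample(1:6, 5, prob = share)
    lab <- anchors[pick, ] + matrix(rnorm(15, 0, 0.1), 5)
    w <- rep(0.2, 5)
    avoripen:::.new_palette(lab, avoripen:::lab_to_rgb(lab), w)
  }))
  agg <- aggregate_palettes(pals, m = 6L, seed = 2L)
  expect_true(all(diff(agg$weight) <= 0))
  expect_equal(sum(agg$weight), 1, tolerance = 1e-9)
  for (i in 1:6) {
    d <- sqrt(colSums((t(as.matrix(as.data.frame(agg)[, c("L", "a", "b")])) - anchors[i, ])^2))
    expect_lt(min(d), 1.0)
  }
  # identical palettes aggregate to themselves
  same <- lapply(1:10, function(i) pals[[1]])
  agg2 <- aggregate_palettes(same, m = 5L, seed = 3L)
  expect_equal(sort(agg2$weight), sort(pals[[1]]$weight), tolerance = 1e-9)
  expect_error(aggregate_palettes(same, m = 6L), "distinct")
})

test_that("stage-1 renders lead with a lighter colour than stage-8 renders", {
  cfg <- small_render_cfg()
  g <- storage_group("T20")
  p <- sample_fruit_params(g, seed = 12L, blemish_prob = 0, base_dwell = 2,
                           dwell_cv = 0, speed_sd = 0)
  p$start_stage10 <- 1L
  p$phase <- 0
  tl <- stage_timeline(p)
  pal_at <- function(stage) {
    d <- tl$day[tl$ri10 == stage][1]
    pals <- lapply(1:6, function(s) {
      r <- render_fruit_image(tl, day = d, side = "front", cfg = cfg, seed = s)
      extract_palette(r$image, segment_foreground(r$image), k = 5, seed = s)
    })
    aggregate_palettes(pals, m = 3L, seed = 1L)
  }
  expect_gt(pal_at(1L)$L[1], pal_at(8L)$L[1])
})

test_that("palettes export to CSV and swatch files", {
  img <- array(0.5, dim = c(20, 20, 3))
  img[, 1:10, 1] <- 0.9
  pal <- extract_palette(img, matrix(TRUE, 20, 20), k = 2, seed = 1L)
  csv <- withr::local_tempfile(fileext = ".csv")
  sw <- withr::local_tempfile(fileext = ".png")
  write_palette(pal, csv = csv, swatch = sw)
  back <- utils::read.csv(csv)
  expect_equal(back$weight, pal$weight)
  expect_identical(dim(png::readPNG(sw))[3], 3L)
})
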