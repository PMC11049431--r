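test_that("degenerate jitter gives speed factor exactly 1 and params are seed-deterministic", {
  g <- storage_group("T10")
  p0 <- sample_fruit_params(g, seed = 11L, speed_sd = 0, base_dwell = 2)
  expect_identical(p0$speed_factor, 1)
  p1 <- sample_fruit_params(g, seed = 5L, base_dwell = 2)
  p2 <- sample_fruit_params(g, seed = 5L, base_dwell = 2)
  expect_identical(p1, p2)
  p3 <- sample_fruit_params(g, seed = 6L, base_dwell = 2)
  expect_false(identical(p1$phase, p3$phase))
  # blemish on at most one side
  expect_true(p1$blemish_side %in% c("none", "front", "back"))
})

test_that("lognormal speed heterogeneity is mean-one on the log scale", {
  g <- storage_group("T20")
  logs <- vapply(1:10000, function(i)
    log(sample_fruit_params(g, seed = i, speed_sd = 0.2, base_dwell = 2)$speed_factor),
    numeric(1))
  # meanlog = -sd^2/2 makes the factor mean-one; check the sample mean of
  # log(speed) against its own standard error
  expect_lt(abs(mean(logs) + 0.2^2 / 2), 3 * sd(logs) / sqrt(length(logs)))
})

test_that("unit dwell with no noise advances one stage per day", {
  g <- storage_group("T10")
  p <- sample_fruit_params(g, seed = 1L, speed_sd = 0, dwell_cv = 0,
                           base_dwell = 1)
  p$start_stage10 <- 1L
  p$phase <- 0
  tl <- stage_timeline(p)
  expect_identical(tl$ri10[tl$day + 1L], pmin(tl$day + 1L, 10L))
  expect_identical(tl$endpoint_day9, 8L)
  expect_identical(tl$end_day10, 9L)
  # Days Left at the endpoint day is zero by definition
  expect_identical(tl$endpoint_day9 - tl$day[tl$ri10 == 9L][1], 0L)
})

test_that("trajectories are monotone with valid stage ranges and endpoints", {
  co <- small_cohort()
  for (tl in co$trajectories) {
    expect_true(all(diff(tl$ri10) >= 0))
    expect_true(all(tl$ri10 >= 1 & tl$ri10 <= 10))
    expect_lte(tl$endpoint_day9, tl$end_day10)
  }
})

test_that("T10 fruits take about twice as long as T20 fruits to reach end of shelf-life", {
  ends <- lapply(c("T10", "T20"), function(gn) {
    sizes <- c(T10 = 0L, T20 = 0L, Tamb = 0L)
    sizes[gn] <- 500L
    co <- simulate_cohort(cohort_config(n_t10 = sizes[["T10"]],
                                        n_t20 = sizes[["T20"]],
                                        n_tamb = sizes[["Tamb"]], seed = 31L))
    vapply(co$trajectories, `[[`, integer(1), "endpoint_day9")
  })
  ratio <- mean(ends[[1]]) / mean(ends[[2]])
  expect_lt(abs(ratio / 2.07 - 1), 0.10)
})

test_that("the default cohort reproduces the study design", {
  co <- simulate_cohort(cohort_config(seed = 2L))
  expect_length(co$trajectories, 478L)
  grp <- vapply(co$params, `[[`, "", "group")
  expect_identical(as.integer(table(grp)[c("T10", "T20", "Tamb")]),
                   c(192L, 143L, 143L))
  # two sides per fruit per observed day
  per_day <- table(co$records$sample_id, co$records$day)
  expect_true(all(per_day %in% c(0L, 2L)))
  # ri5 consistency across every record
  expect_identical(co$records$ri5, stage5_from_stage10(co$records$ri10))
})

test_that("equal seeds reproduce an identical cohort, different seeds do not", {
  cfg <- cohort_config(n_t10 = 6L, n_t20 = 5L, n_tamb = 0L, seed = 77L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$records, b$records)
  c2 <- simulate_cohort(cfg, seed = 78L)
  expect_false(identical(a$records, c2$records))
})

test_that("observation caps censor fruits that have not reached stage 9", {
  co <- simulate_cohort(cohort_config(n_t10 = 12L, n_t20 = 0L, n_tamb = 0L,
                                      max_days = 8, seed = 5L))
  expect_true(all(co$records$day <= 8))
  cens <- unique(co$records$sample_id[co$records$censored])
  if (length(cens)) {
    cens_rec <- co$records[co$records$sample_id %in% cens, ]
    expect_true(all(is.na(cens_rec$days_left9)))
    expect_true(all(cens_rec$ri10 < 9))
  }
  expect_gt(length(cens), 0)  # T10 fruit rarely ripen within 8 days
})

test_that("renders are deterministic, sized, and flat-filled in the degenerate config", {
  co <- small_cohort()
  cfg <- small_render_cfg()
  tl <- co$trajectories[[1]]
  r1 <- render_fruit_image(tl, day = 0, side = "front", cfg = cfg, seed = 4L)
  r2 <- render_fruit_image(tl, day = 0, side = "front", cfg = cfg, seed = 4L)
  expect_identical(r1$image, r2$image)
  expect_identical(dim(r1$image), c(48L, 48L, 3L))
  expect_error(render_fruit_image(tl, day = 999, side = "front", cfg = cfg),
               "out of")

  flat <- render_config(image_size = 32L, patch_density_by_stage = rep(0, 10),
                        noise_sd = 0)
  g <- storage_group("T10")
  p <- sample_fruit_params(g, seed = 2L, blemish_prob = 0, base_dwell = 2)
  tl2 <- stage_timeline(p)
  r <- render_fruit_image(tl2, day = 0, side = "front", cfg = flat, seed = 1L)
  anchor <- avoripen:::lab_to_rgb(flat$stage_palette[tl2$ri10[1], , drop = FALSE])
  anchor_q <- round(anchor * 255) / 255
  for (ch in 1:3)
    expect_true(all(abs(r$image[, , ch][r$mask] - anchor_q[ch]) < 1e-12))
})

test_that("mold spots appear only from stage 9 and patchy stages have higher colour variance", {
  cfg <- small_render_cfg()
  g <- storage_group("T20")
  p <- sample_fruit_params(g, seed = 3L, blemish_prob = 0, base_dwell = 1.5)
  tl <- stage_timeline(p)
  day9 <- tl$day[tl$ri10 >= 9][1]
  day1 <- tl$day[tl$ri10 == tl$ri10[1]][1]
  r9 <- render_fruit_image(tl, day = day9, side = "front", cfg = cfg, seed = 8L)
  r1 <- render_fruit_image(tl, day = day1, side = "front", cfg = cfg, seed = 8L)
  expect_gt(attr(r9$image, "mold_pixels"), 0)
  expect_identical(attr(r1$image, "mold_pixels"), 0L)

  # scattered-purple phase (ri10 = 6) vs homogeneous purple (ri10 = 8):
  # deterministic dwells so both stages are observed on known days
  p2 <- sample_fruit_params(g, seed = 3L, blemish_prob = 0, base_dwell = 2,
                            dwell_cv = 0, speed_sd = 0)
  p2$start_stage10 <- 1L
  p2$phase <- 0
  tl2 <- stage_timeline(p2)
  fruit_var <- function(ri) {
    d <- tl2$day[tl2$ri10 == ri][1]
    r <- render_fruit_image(tl2, day = d, side = "front", cfg = cfg, seed = 21L)
    mean(apply(r$image, 3, function(pl) var(pl[r$mask])))
  }
  expect_gt(fruit_var(6L), fruit_var(8L))
})

test_that("rendered mean lightness decreases from stage 1 to stage 8", {
  cfg <- small_render_cfg()
  g <- storage_group("T20")
  p <- sample_fruit_params(g, seed = 12L, blemish_prob = 0, base_dwell = 2,
                           dwell_cv = 0)
  p$start_stage10 <- 1L
  p$phase <- 0
  tl <- stage_timeline(p)
  L <- vapply(1:8, function(s) {
    d <- tl$day[tl$ri10 == s][1]
    r <- render_fruit_image(tl, day = d, side = "front", cfg = cfg, seed = 2L)
    px <- cbind(r$image[, , 1][r$mask], r$image[, , 2][r$mask], r$image[, , 3][r$mask])
    mean(avoripen:::rgb_to_lab(px)[, 1])
  }, numeric(1))
  expect_true(all(diff(L) < 0))
})

test_that("blemish texture shows only on the blemished side", {
  cfg <- small_render_cfg()
  g <- storage_group("T20")
  p <- sample_fruit_params(g, seed = 14L, blemish_prob = 1, base_dwell = 2)
  expect_true(p$blemish_side %in% c("front", "back"))
  tl <- stage_timeline(p)
  r_b <- render_fruit_image(tl, day = 0, side = p$blemish_side, cfg = cfg, seed = 3L)
  other <- setdiff(c("front", "back"), p$blemish_side)
  r_o <- render_fruit_image(tl, day = 0, side = other, cfg = cfg, seed = 3L)
  v_b <- mean(apply(r_b$image, 3, function(pl) var(pl[r_b$mask])))
  v_o <- mean(apply(r_o$image, 3, function(pl) var(pl[r_o$mask])))
  expect_gt(v_b, v_o)
})
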