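test_that("the exact-fit worked example gives alpha -2 with unit R-squared", {
  fit <- shelf_life_fit(y ~ ri, data.frame(ri = c(4, 3), y = c(2, 4)),
                        endpoint = 5)
  expect_equal(coef(fit)[["alpha"]], -2)
  expect_equal(fit$r.squared, 1)
  expect_equal(fit$se, 0)
  expect_equal(unname(residuals(fit)), c(0, 0))
})

test_that("degenerate input at the endpoint stage errors", {
  expect_error(shelf_life_fit(y ~ ri, data.frame(ri = c(5, 5), y = c(0, 0)),
                              endpoint = 5),
               "away from the endpoint")
})

test_that("the through-origin estimator matches a grid search over alpha", {
  dat <- withr::with_seed(13, {
    ri <- sample(1:9, 50, replace = TRUE)
    data.frame(ri = ri, y = -1.8 * (ri - 9) + rnorm(50, 0, 1.2))
  })
  fit <- shelf_life_fit(y ~ ri, dat, endpoint = 9)
  grid <- seq(-8, 0, by = 1e-4)
  x <- dat$ri - 9
  sse <- vapply(grid, function(a) sum((dat$y - a * x)^2), numeric(1))
  expect_lt(abs(coef(fit)[["alpha"]] - grid[which.min(sse)]), 1e-3)
  # the same slope as lm through the origin, with matching standard error
  lmfit <- lm(y ~ 0 + x, data = data.frame(x = x, y = dat$y))
  expect_equal(coef(fit)[["alpha"]], unname(coef(lmfit)), tolerance = 1e-12)
  expect_equal(fit$se, unname(sqrt(diag(vcov(lmfit)))), tolerance = 1e-12)
  expect_gte(fit$r.squared, 0)
  expect_lte(fit$r.squared, 1)
})

test_that("shelf-life estimates are zero at and beyond the endpoint", {
  fit5 <- shelf_life_fit(y ~ ri, data.frame(ri = c(1, 2, 3, 4), y = c(17.6, 13.2, 8.8, 4.4)),
                         endpoint = 5)
  expect_equal(estimate_days_left(fit5, 5), 0)
  expect_equal(estimate_days_left(fit5, 1), -coef(fit5)[["alpha"]] * 4)
  fit9 <- shelf_life_fit(y ~ ri, data.frame(ri = c(5, 7), y = c(4.18, 2.09)),
                         endpoint = 9)
  expect_equal(estimate_days_left(fit9, 9), 0)
  expect_equal(estimate_days_left(fit9, 10), 0)  # past end of shelf-life, clipped
  expect_lt(predict(fit9, 10, clip = FALSE), 0)
  expect_error(predict(fit9, 11), "index range")
  expect_error(predict(fit5, 6), "index range")
})

test_that("model methods are coherent (summary, confint, simulate, fitted)", {
  dat <- withr::with_seed(5, {
    ri <- rep(1:9, 6)
    data.frame(ri = ri, y = -1.2 * (ri - 9) + rnorm(54, 0, 0.8))
  })
  fit <- shelf_life_fit(y ~ ri, dat, endpoint = 9)
  s <- summary(fit)
  expect_equal(s$coefficients["alpha", "estimate"], coef(fit)[["alpha"]])
  ci <- confint(fit)
  expect_equal(unname(ci[1, 2] - ci[1, 1]) / 2, fit$ci95, tolerance = 1e-12)
  expect_equal(fitted(fit) + residuals(fit), dat$y)
  sims <- simulate(fit, nsim = 3, seed = 1L)
  expect_identical(dim(sims), c(54L, 3L))
  expect_identical(simulate(fit, nsim = 3, seed = 1L), sims)
})

test_that("censored records are excluded and estimates convert stages to days", {
  co <- small_cohort()
  rec <- co$records[co$records$group == "T20", ]
  fit <- shelf_life_fit(days_left9 ~ ri10, rec, endpoint = 9)
  expect_identical(fit$n, sum(!is.na(rec$days_left9)))
  expect_lt(coef(fit)[["alpha"]], 0)
})

test_that("loss tables follow the signed definition, best-side rule and equal group weights", {
  fitA <- shelf_life_fit(y ~ ri, data.frame(ri = c(4, 3), y = c(2, 4)), endpoint = 5)

  # estimates equal to actual give all-zero losses
  preds0 <- data.frame(sample_id = 1:4, side = "front", day = 0L, group = "T20",
                       pred_stage = c(1L, 2L, 3L, 4L),
                       days_left9 = estimate_days_left(fitA, 1:4))
  lt0 <- loss_table(preds0, list(T20 = fitA))
  expect_true(all(lt0$records$loss == 0))
  expect_equal(lt0$overall, 0)

  # single record: estimated 3, actual 2 -> loss +1
  one <- data.frame(sample_id = 1L, side = "front", day = 0L, group = "T20",
                    pred_stage = 3.5, days_left9 = 2)
  # use a model estimating exactly 3 at stage 3.5
  fitB <- shelf_life_fit(y ~ ri, data.frame(ri = c(3.5, 4.25), y = c(3, 1.5)),
                         endpoint = 5)
  lt1 <- loss_table(one, list(T20 = fitB))
  expect_equal(lt1$records$loss, 1)
  expect_equal(lt1$overall, 1)

  # best side: losses (+2, -1) keep the -1 side in sample aggregation
  two <- data.frame(sample_id = 1L, side = c("front", "back"), day = 0L,
                    group = "T20", pred_stage = c(2, 3.5),
                    days_left9 = c(4, 4))
  # fitB estimates: stage 2 -> 6, stage 3.5 -> 3  => losses +2 and -1
  lt2p <- loss_table(two, list(T20 = fitB), by = "picture")
  expect_equal(sort(lt2p$records$loss), c(-1, 2))
  lt2s <- loss_table(two, list(T20 = fitB), by = "sample")
  expect_equal(lt2s$records$loss, -1)
  expect_equal(lt2s$overall, 1)

  # random set: group averages match an enumeration oracle, equal weights
  preds <- random_preds(40, k = 5L, seed = 12L)
  preds$days_left9 <- withr::with_seed(6, runif(nrow(preds), 0, 12))
  models <- list(T10 = fitA, T20 = fitA, Tamb = fitA)
  lt <- loss_table(preds, models, by = "picture")
  oracle <- vapply(c("T10", "T20", "Tamb"), function(g) {
    sel <- preds$group == g
    est <- estimate_days_left(fitA, preds$pred_stage[sel])
    mean(abs(est - preds$days_left9[sel]))
  }, numeric(1))
  expect_equal(sort(lt$by_group$mean_abs_loss), sort(unname(oracle)))
  expect_equal(lt$overall, mean(oracle))

  # sample-mode absolute loss never exceeds picture-mode on identical input
  lts <- loss_table(preds, models, by = "sample")
  expect_lte(lts$overall, lt$overall)
  expect_error(loss_table(preds, list(T10 = fitA)), "missing shelf-life model")
})

test_that("loss KDE integrates to one, is symmetric for symmetric input, and matches the Gaussian at a point mass", {
  k1 <- kde_loss(0)
  at0 <- k1$density[which.min(abs(k1$loss))]
  expect_lt(abs(at0 - 1 / sqrt(2 * pi)), 1e-4)

  sym <- c(-3, -1, 1, 3)
  ks <- kde_loss(sym, n_grid = 1001L)
  expect_lt(abs(sum(ks$density * diff(ks$loss)[1]) - 1), 1e-3)
  left <- approx(ks$loss, ks$density, xout = -seq(0, 3, 0.25))$y
  right <- approx(ks$loss, ks$density, xout = seq(0, 3, 0.25))$y
  expect_equal(left, right, tolerance = 1e-6)
  expect_error(kde_loss(numeric(0)), "no losses")
})

test_that("fitting simulated cohorts recovers every group preset slope within 3 MC standard errors", {
  presets <- expand.grid(g = c("T10", "T20", "Tamb"), idx = c(5L, 10L),
                         stringsAsFactors = FALSE)
  for (r in seq_len(nrow(presets))) {
    gname <- presets$g[r]; idx <- presets$idx[r]
    grp <- storage_group(gname)
    alpha <- if (idx == 10L) grp$alpha9 else grp$alpha5
    slopes <- vapply(1:12, function(s) {
      sizes <- c(T10 = 0L, T20 = 0L, Tamb = 0L)
      sizes[gname] <- 220L
      co <- simulate_cohort(cohort_config(n_t10 = sizes[["T10"]],
                                          n_t20 = sizes[["T20"]],
                                          n_tamb = sizes[["Tamb"]],
                                          index_target = idx,
                                          seed = 2000L + 77L * r + s))
      rec <- co$records[!co$records$censored, ]
      if (idx == 10L)
        coef(shelf_life_fit(days_left9 ~ ri10, rec, endpoint = 9))[["alpha"]]
      else
        coef(shelf_life_fit(days_left5 ~ ri5, rec, endpoint = 5))[["alpha"]]
    }, numeric(1))
    expect_lt(abs(mean(slopes) - alpha), 3 * sd(slopes) / sqrt(length(slopes)))
  }
})
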