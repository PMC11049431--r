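# Forced-endpoint shelf-life regression, shelf-life estimation, loss
# analysis and kernel density estimation of the losses.
#
# The model: Days Left = alpha * (RI - E), a through-origin ordinary
# least-squares line in x = RI - E, forced to estimate zero at the
# end-of-shelf-life stage E (5 of the 5-stage index, 9 of the 10-stage).

#' Fit the forced-endpoint shelf-life regression
#'
#' Through-origin OLS of Days Left on (Ripening Index - E):
#' `alpha = sum(x*y) / sum(x^2)` with `x = ri - E`. The standard error is
#' `sqrt(RSS / ((n - 1) * sum(x^2)))` (one fitted parameter, n - 1 residual
#' degrees of freedom), the 95% confidence half-width uses the Student-t
#' quantile, and R-squared is the uncentered definition
#' `1 - RSS / sum(y^2)`.
#'
#' @param formula model formula `days_left ~ ri` naming the Days Left and
#'   Ripening Index columns of `data`.
#' @param data data frame of image records; rows with undefined (NA) Days
#'   Left — censored samples — are dropped.
#' @param endpoint end-of-shelf-life stage E (5 or 9); default inferred from
#'   the stage range.
#' @return object of class `shelf_life_fit` with methods `print`, `summary`,
#'   `coef`, `confint`, `predict`, `fitted`, `residuals`, `simulate` and
#'   `plot`.
#' @examples
#' fit <- shelf_life_fit(y ~ ri, data.frame(ri = c(4, 3), y = c(2, 4)),
#'                       endpoint = 5)
#' coef(fit)  # alpha = -2
#' @export
shelf_life_fit <- function(formula, data, endpoint = NULL) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- mf[[1]]
  ri <- mf[[2]]
  if (is.null(endpoint)) endpoint <- if (max(ri) > 5) 9L else 5L
  stopifnot(endpoint %in% c(5L, 9L))
  x <- ri - endpoint
  n <- length(y)
  if (sum(x != 0) < 2L)
    stop("need at least 2 observations away from the endpoint stage",
         call. = FALSE)
  sxx <- sum(x^2)
  alpha <- sum(x * y) / sxx
  res <- y - alpha * x
  rss <- sum(res^2)
  se <- sqrt(rss / ((n - 1) * sxx))
  ci95 <- stats::qt(0.975, n - 1) * se
  tss <- sum(y^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  structure(list(coefficients = c(alpha = alpha), endpoint = endpoint,
                 se = se, ci95 = ci95, r.squared = r2,
                 sigma = sqrt(rss / (n - 1)), df.residual = n - 1L, n = n,
                 index_max = if (endpoint == 5L) 5L else 10L,
                 fitted.values = alpha * x, residuals = res,
                 x = x, y = y, call = match.call()),
            class = "shelf_life_fit")
}

#' @export
print.shelf_life_fit <- function(x, ...) {
  cat(sprintf("forced-endpoint shelf-life regression (endpoint stage %d)\n",
              x$endpoint))
  cat(sprintf("  alpha = %.3f +/- %.3f days/stage (95%% CI), R2 = %.3f, n = %d\n",
              x$coefficients[["alpha"]], x$ci95, x$r.squared, x$n))
  invisible(x)
}

#' @export
summary.shelf_life_fit <- function(object, ...) {
  a <- object$coefficients[["alpha"]]
  tval <- if (object$se > 0) a / object$se else NA_real_
  tab <- data.frame(estimate = a, std.error = object$se, t.value = tval,
                    p.value = if (is.na(tval)) NA_real_ else
                      2 * stats::pt(-abs(tval), object$df.residual),
                    ci95.halfwidth = object$ci95, row.names = "alpha")
  out <- list(coefficients = tab, endpoint = object$endpoint,
              r.squared = object$r.squared, sigma = object$sigma,
              n = object$n, df.residual = object$df.residual)
  class(out) <- "summary.shelf_life_fit"
  out
}

#' @export
print.summary.shelf_life_fit <- function(x, ...) {
  cat(sprintf("Days Left = alpha * (RI - %d), through-origin OLS\n", x$endpoint))
  print(round(x$coefficients, 4))
  cat(sprintf("uncentered R-squared %.3f, residual sd %.3f days, n = %d\n",
              x$r.squared, x$sigma, x$n))
  invisible(x)
}

#' @export
coef.shelf_life_fit <- function(object, ...) object$coefficients

#' @export
confint.shelf_life_fit <- function(object, parm = "alpha", level = 0.95, ...) {
  a <- object$coefficients[["alpha"]]
  hw <- stats::qt(1 - (1 - level) / 2, object$df.residual) * object$se
  out <- matrix(c(a - hw, a + hw), 1,
                dimnames = list("alpha", sprintf("%g %%", c((1 - level) / 2,
                                                            1 - (1 - level) / 2) * 100)))
  out
}

#' @export
fitted.shelf_life_fit <- function(object, ...) object$fitted.values

#' @export
residuals.shelf_life_fit <- function(object, ...) object$residuals

#' Estimated Days Left at given Ripening Index values
#'
#' `alpha * (ri - E)`, clipped at 0 beyond the endpoint stage (a fruit past
#' the end of its shelf-life has no days left).
#'
#' @param object a [shelf_life_fit()].
#' @param ri Ripening Index values within the model's index range.
#' @param clip clip estimates past the endpoint at zero.
#' @param ... unused.
#' @return estimated Days Left (days).
#' @export
predict.shelf_life_fit <- function(object, ri, clip = TRUE, ...) {
  if (any(ri < 1 | ri > object$index_max))
    stop(sprintf("ri out of the model's index range 1..%d", object$index_max),
         call. = FALSE)
  est <- object$coefficients[["alpha"]] * (ri - object$endpoint)
  if (clip) est[ri > object$endpoint] <- 0
  unname(est)
}

#' @rdname predict.shelf_life_fit
#' @param model a [shelf_life_fit()].
#' @export
estimate_days_left <- function(model, ri, clip = TRUE) {
  predict(model, ri = ri, clip = clip)
}

#' @export
simulate.shelf_life_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) return(withr::with_seed(seed, simulate(object, nsim)))
  as.data.frame(replicate(nsim, object$fitted.values +
                            stats::rnorm(object$n, 0, object$sigma)))
}

#' @export
plot.shelf_life_fit <- function(x, ...) {
  ri <- x$x + x$endpoint
  graphics::plot(jitter(ri, 0.3), x$y, xlab = "Ripening Index",
                 ylab = "Days Left", col = "grey40", pch = 16, cex = 0.5, ...)
  graphics::abline(a = -x$coefficients[["alpha"]] * x$endpoint,
                   b = x$coefficients[["alpha"]], col = "red3", lwd = 2)
  graphics::points(x$endpoint, 0, pch = 4, col = "red3", cex = 1.4)
  invisible(x)
}

#' Shelf-life estimation losses
#'
#' Converts stage classifications into shelf-life estimates with the group's
#' forced-endpoint model and computes the signed loss
#' `estimated - actual` per record. In sample aggregation only the
#' best-performing side (minimal absolute loss) of each (sample, day) pair
#' is kept. Reported averages are means of the absolute loss per storage
#' group plus an overall average giving each group equal weight.
#'
#' @param preds records carrying `sample_id`, `side`, `day`, `group`, a
#'   stage column and the actual Days Left: predictions joined to truth, or
#'   attributed records.
#' @param models named list of [shelf_life_fit()] per storage group (or one
#'   model used for every group).
#' @param stage_col column holding the classification to convert
#'   (e.g. `"pred_stage"` or `"ri10"`).
#' @param actual_col column holding the actual Days Left; NA rows
#'   (censored) are dropped.
#' @param by `"picture"` (every record) or `"sample"` (best side per
#'   sample-day).
#' @return list of class `loss_table`: `records` (with `estimated`,
#'   `actual`, `loss`), `by_group` (mean absolute loss and n per group) and
#'   `overall` (equal-weight mean of the group averages).
#' @export
loss_table <- function(preds, models, stage_col = "pred_stage",
                       actual_col = "days_left9", by = c("picture", "sample")) {
  by <- match.arg(by)
  stopifnot(all(c("sample_id", "day", "group", stage_col, actual_col) %in%
                  names(preds)))
  if (inherits(models, "shelf_life_fit"))
    models <- stats::setNames(rep(list(models), length(unique(preds$group))),
                              unique(preds$group))
  rec <- preds[!is.na(preds[[actual_col]]), , drop = FALSE]
  if (!nrow(rec)) stop("no records with defined Days Left", call. = FALSE)
  miss <- setdiff(unique(rec$group), names(models))
  if (length(miss))
    stop("missing shelf-life model for group: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rec$estimated <- NA_real_
  for (g in unique(rec$group)) {
    sel <- rec$group == g
    rec$estimated[sel] <- estimate_days_left(models[[g]], rec[[stage_col]][sel])
  }
  rec$actual <- rec[[actual_col]]
  rec$loss <- rec$estimated - rec$actual
  if (by == "sample") {
    key <- paste(rec$sample_id, rec$day)
    keep <- unlist(tapply(seq_len(nrow(rec)), key, function(i)
      i[which.min(abs(rec$loss[i]))]), use.names = FALSE)
    rec <- rec[sort(keep), , drop = FALSE]
  }
  by_group <- do.call(rbind, lapply(split(rec, rec$group), function(d)
    data.frame(group = d$group[1], mean_abs_loss = mean(abs(d$loss)),
               mean_loss = mean(d$loss), n = nrow(d))))
  rownames(by_group) <- NULL
  structure(list(records = rec, by_group = by_group,
                 overall = mean(by_group$mean_abs_loss), by = by),
            class = "loss_table")
}

#' @export
print.loss_table <- function(x, ...) {
  cat(sprintf("shelf-life estimation loss (by %s):\n", x$by))
  print(transform(x$by_group, mean_abs_loss = round(mean_abs_loss, 3),
                  mean_loss = round(mean_loss, 3)), row.names = FALSE)
  cat(sprintf("overall (equal group weights): %.3f days\n", x$overall))
  invisible(x)
}

#' Kernel density estimate of shelf-life losses
#'
#' Gaussian-kernel KDE of the signed losses with a fixed 1-day bandwidth
#' (the kernel standard deviation), evaluated on a regular grid; the curve
#' integrates to 1.
#'
#' @param losses signed losses in days (non-empty).
#' @param bandwidth kernel sd in days.
#' @param n_grid grid size.
#' @return data frame (loss, density) of class `loss_kde`.
#' @export
kde_loss <- function(losses, bandwidth = 1, n_grid = 512L) {
  losses <- losses[!is.na(losses)]
  if (!length(losses)) stop("no losses to smooth", call. = FALSE)
  d <- stats::density(losses, bw = bandwidth, kernel = "gaussian", n = n_grid,
                      cut = 4)
  structure(data.frame(loss = d$x, density = d$y),
            class = c("loss_kde", "data.frame"))
}
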