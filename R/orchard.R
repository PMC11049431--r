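# Synthetic orchard: fruit ripening trajectories and cohort simulation.
#
# The generative model: a fruit enters its starting 10-stage index partway
# through that stage (uniform phase) and advances one stage at a time, each
# stage's dwell drawn from a gamma distribution with a common per-fruit mean
# (group dwell scale x a lognormal per-fruit speed factor) and fixed CV.
# Photographs are taken once per integer day, from day 0 until the day the
# fruit first shows stage 10. Days Left counts to the first day classified
# stage 9 (end of shelf-life).

.calib_cache <- new.env(parent = emptyenv())
.CALIB_REF_SEED <- 20220314L   # internal reference-cohort seed, fixed

# Stage occupancy for one fruit given its dwell times.
# Returns integer stages for days 0..end_day10 plus the two endpoint days.
timeline_from_dwells <- function(start_stage10, phase, dwells) {
  stopifnot(start_stage10 >= 1L, start_stage10 <= 8L,
            phase >= 0, phase < 1, all(dwells > 0), length(dwells) == 10L)
  t0 <- -phase * dwells[start_stage10]
  trans <- t0 + cumsum(dwells[start_stage10:9])   # times of s -> s+1
  end9 <- ceiling(trans[length(trans) - 1L])      # first day at stage >= 9
  end10 <- ceiling(trans[length(trans)])          # first day at stage 10
  days <- 0:end10
  ri10 <- start_stage10 + findInterval(days, trans)
  list(day = days, ri10 = as.integer(ri10),
       endpoint_day9 = as.integer(max(end9, 0L)),
       end_day10 = as.integer(end10))
}

# Through-origin Days-Left slope of a reference cohort simulated with mean
# dwell D, using pre-drawn standardized randomness (common random numbers, so
# the slope is a smooth deterministic function of D).
.reference_slope <- function(D, draws, endpoint_stage) {
  n <- length(draws$s0)
  xs <- vector("list", n)
  ys <- vector("list", n)
  for (i in seq_len(n)) {
    tl <- timeline_from_dwells(draws$s0[i], draws$phase[i],
                               D * draws$speed[i] * draws$gamma[i, ])
    keep <- tl$day <= tl$endpoint_day9
    ri <- tl$ri10[keep]
    if (endpoint_stage == 5L) ri <- ceiling(ri / 2)
    xs[[i]] <- ri - endpoint_stage
    ys[[i]] <- tl$endpoint_day9 - tl$day[keep]
  }
  x <- unlist(xs); y <- unlist(ys)
  sum(x * y) / sum(x * x)
}

#' Calibrated mean dwell time per 10-stage step
#'
#' Solves for the mean per-stage dwell (days per 10-stage step) such that the
#' forced-endpoint through-origin regression of annotated Days Left on the
#' Ripening Index, applied to a large fixed-seed reference cohort drawn from
#' the generative model, recovers the storage group's slope preset exactly.
#' This is what makes the simulator's Days-Left law carry the preset slope:
#' because Days Left counts to the *first* day classified at the endpoint
#' stage while photographs are spread across each stage's dwell window, the
#' naive choice dwell = |alpha| would bias the recovered slope.
#'
#' @param group a [storage_group()].
#' @param index_target which index system's slope preset to calibrate
#'   against: 10 (uses `alpha9`, endpoint stage 9) or 5 (uses `alpha5`,
#'   endpoint stage 5).
#' @param dwell_cv coefficient of variation of the per-stage gamma dwells.
#' @param speed_sd sdlog of the mean-one lognormal per-fruit speed factor.
#' @param start_probs probabilities of starting at 10-stage index 1, 2, 3.
#' @param n_ref reference-cohort size used by the solver; large enough that
#'   the reference draw's own sampling error is small against the
#'   Monte-Carlo spread of study-scale cohorts.
#' @return mean dwell in days per 10-stage step (positive scalar).
#' @export
calibrate_dwell <- function(group, index_target = 10L, dwell_cv = 0.25,
                            speed_sd = 0.15, start_probs = c(0.55, 0.30, 0.15),
                            n_ref = 30000L) {
  stopifnot(inherits(group, "storage_group"), index_target %in% c(5L, 10L),
            dwell_cv >= 0, speed_sd >= 0, length(start_probs) == 3L,
            all(start_probs >= 0), sum(start_probs) > 0)
  key <- paste(group$name, index_target, dwell_cv, speed_sd,
               paste(signif(start_probs, 8), collapse = ","), n_ref, sep = "|")
  hit <- .calib_cache[[key]]
  if (!is.null(hit)) return(hit)

  alpha <- if (index_target == 10L) group$alpha9 else group$alpha5
  endpoint <- if (index_target == 10L) 9L else 5L
  draws <- withr::with_seed(.CALIB_REF_SEED, {
    shape <- if (dwell_cv > 0) 1 / dwell_cv^2 else NA_real_
    g <- if (dwell_cv > 0) {
      matrix(stats::rgamma(n_ref * 10L, shape = shape, rate = shape), n_ref, 10L)
    } else matrix(1, n_ref, 10L)
    list(
      s0 = sample(1:3, n_ref, replace = TRUE, prob = start_probs / sum(start_probs)),
      phase = stats::runif(n_ref),
      speed = if (speed_sd > 0)
        stats::rlnorm(n_ref, meanlog = -speed_sd^2 / 2, sdlog = speed_sd)
      else rep(1, n_ref),
      gamma = g
    )
  })
  f <- function(D) .reference_slope(D, draws, endpoint) - alpha
  sol <- stats::uniroot(f, interval = c(0.2 * abs(alpha), 1.6 * abs(alpha) + 2),
                        tol = 5e-4)
  .calib_cache[[key]] <- sol$root
  sol$root
}

#' Draw the parameters of one simulated fruit
#'
#' Per-fruit heterogeneity: a mean-one lognormal ripening-speed factor, a
#' starting 10-stage index (fruit arrive mature but mostly unripe), a uniform
#' phase within the starting stage, and a possible one-sided skin blemish
#' (wind rub / sunburn).
#'
#' @param group a [storage_group()].
#' @param seed integer seed; draws are deterministic given the seed.
#' @param sample_id integer fruit identifier carried into all records.
#' @param speed_sd sdlog of the lognormal speed factor (0 gives exactly 1).
#' @param dwell_cv CV of per-stage dwell times (0 gives deterministic dwells).
#' @param start_probs probabilities of starting at 10-stage index 1..3.
#' @param blemish_prob probability that one side carries a blemish.
#' @param index_target index system whose slope preset calibrates the dwell.
#' @param base_dwell mean days per 10-stage step before the speed factor;
#'   defaults to [calibrate_dwell()] for the group.
#' @return An object of class `fruit_params`.
#' @export
sample_fruit_params <- function(group, seed, sample_id = 1L,
                                speed_sd = 0.15, dwell_cv = 0.25,
                                start_probs = c(0.55, 0.30, 0.15),
                                blemish_prob = 0.35,
                                index_target = 10L, base_dwell = NULL) {
  stopifnot(inherits(group, "storage_group"))
  if (is.null(base_dwell))
    base_dwell <- calibrate_dwell(group, index_target, dwell_cv, speed_sd, start_probs)
  p <- withr::with_seed(derive_seed(seed, "params", sample_id), {
    speed <- if (speed_sd > 0)
      stats::rlnorm(1, meanlog = -speed_sd^2 / 2, sdlog = speed_sd) else 1
    s0 <- sample(1:3, 1L, prob = start_probs / sum(start_probs))
    phase <- stats::runif(1)
    blem <- if (stats::runif(1) < blemish_prob)
      sample(c("front", "back"), 1L) else "none"
    list(speed_factor = speed, start_stage10 = s0, phase = phase,
         blemish_side = blem,
         blemish_intensity = if (blem == "none") 0 else stats::runif(1, 0.3, 1))
  })
  structure(
    c(list(sample_id = as.integer(sample_id), group = group$name,
           base_dwell = base_dwell, dwell_cv = dwell_cv, seed = seed),
      p),
    class = "fruit_params")
}

#' Ripening trajectory of one fruit
#'
#' Draws per-stage dwell times (gamma, mean `base_dwell * speed_factor`, CV
#' `dwell_cv`; deterministic at CV 0) and converts them to the sequence of
#' 10-stage indices observed on integer days, from day 0 up to the first day
#' at stage 10.
#'
#' @param params a [sample_fruit_params()] object.
#' @return An object of class `fruit_trajectory`: fields `params`, `day`
#'   (0-based), `ri10`, `endpoint_day9` (first day classified >= 9) and
#'   `end_day10`.
#' @export
stage_timeline <- function(params) {
  stopifnot(inherits(params, "fruit_params"))
  D <- params$base_dwell * params$speed_factor
  dwells <- withr::with_seed(derive_seed(params$seed, "timeline", params$sample_id), {
    if (params$dwell_cv > 0) {
      shape <- 1 / params$dwell_cv^2
      stats::rgamma(10L, shape = shape, rate = shape / D)
    } else rep(D, 10L)
  })
  tl <- timeline_from_dwells(params$start_stage10, params$phase, dwells)
  structure(c(list(params = params), tl), class = "fruit_trajectory")
}

#' @export
print.fruit_trajectory <- function(x, ...) {
  cat(sprintf("fruit %d (%s): stages %d..%d over days 0..%d, end of shelf-life day %d\n",
              x$params$sample_id, x$params$group, x$ri10[1],
              x$ri10[length(x$ri10)], x$end_day10, x$endpoint_day9))
  invisible(x)
}

#' Cohort configuration for the simulator
#'
#' Defaults reproduce the study design: 192 fruits at 10 C, 143 at 20 C and
#' 143 at fluctuating room temperature (478 in total), photographed from two
#' sides daily until the first day at stage 10, uncapped observation.
#'
#' @param n_t10,n_t20,n_tamb group sizes.
#' @param index_target index system (10 or 5) whose slope preset the dwell
#'   scale is calibrated against.
#' @param dwell_cv,speed_sd,start_probs,blemish_prob heterogeneity settings,
#'   see [sample_fruit_params()].
#' @param max_days observation cap in days; records beyond the cap are absent
#'   and fruits that have not reached stage 9 by the cap are censored.
#' @param start_date ISO date of day 0 for date stamps.
#' @param seed default master seed used by [simulate_cohort()].
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_t10 = 192L, n_t20 = 143L, n_tamb = 143L,
                          index_target = 10L, dwell_cv = 0.25, speed_sd = 0.15,
                          start_probs = c(0.55, 0.30, 0.15), blemish_prob = 0.35,
                          max_days = Inf, start_date = "2022-03-20", seed = 1L) {
  stopifnot(n_t10 >= 0, n_t20 >= 0, n_tamb >= 0, index_target %in% c(5L, 10L))
  structure(list(n_t10 = as.integer(n_t10), n_t20 = as.integer(n_t20),
                 n_tamb = as.integer(n_tamb), index_target = as.integer(index_target),
                 dwell_cv = dwell_cv, speed_sd = speed_sd,
                 start_probs = start_probs, blemish_prob = blemish_prob,
                 max_days = max_days, start_date = start_date,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a labelled ripening cohort
#'
#' Generates fruit trajectories for the three storage groups and the metadata
#' of every photograph: two sides per fruit per observed day, 5- and 10-stage
#' indices, Days Left annotations to both shelf-life endpoints, and censoring
#' flags. Images themselves are rendered lazily (see
#' [cohort_image_provider()] / [render_fruit_image()]).
#'
#' @param config a [cohort_config()].
#' @param seed master seed; defaults to `config$seed`. Equal seeds give
#'   byte-identical cohorts.
#' @return object of class `fruit_cohort`: list with `records` (one row per
#'   photograph: sample_id, side, group, day, date_stamp, ri5, ri10,
#'   days_left5, days_left9, censored), `trajectories`, `params`, `config`,
#'   `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  sizes <- c(T10 = config$n_t10, T20 = config$n_t20, Tamb = config$n_tamb)
  groups <- rep(names(sizes), sizes)
  n <- length(groups)
  dwell <- lapply(storage_groups(), function(g)
    if (sizes[[g]] > 0) calibrate_dwell(storage_group(g), config$index_target,
                                        config$dwell_cv, config$speed_sd,
                                        config$start_probs) else NA_real_)
  names(dwell) <- storage_groups()

  trajectories <- vector("list", n)
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i]
    params <- sample_fruit_params(storage_group(g), seed = seed, sample_id = i,
                                  speed_sd = config$speed_sd,
                                  dwell_cv = config$dwell_cv,
                                  start_probs = config$start_probs,
                                  blemish_prob = config$blemish_prob,
                                  index_target = config$index_target,
                                  base_dwell = dwell[[g]])
    tl <- stage_timeline(params)
    trajectories[[i]] <- tl
    keep <- tl$day <= config$max_days
    day <- tl$day[keep]
    ri10 <- tl$ri10[keep]
    censored <- tl$endpoint_day9 > config$max_days
    dl9 <- if (censored) rep(NA_real_, length(day)) else {
      v <- as.numeric(tl$endpoint_day9 - day); v[day > tl$endpoint_day9] <- NA_real_; v
    }
    rec[[i]] <- data.frame(
      sample_id = i,
      side = rep(c("front", "back"), each = length(day)),
      group = g,
      day = rep(day, 2L),
      ri10 = rep(ri10, 2L),
      days_left9 = rep(dl9, 2L),
      censored = censored,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rec)
  records$ri5 <- stage5_from_stage10(records$ri10)
  records$days_left5 <- records$days_left9   # both endpoints fall on the same first stage-9 day
  records$date_stamp <- as.character(as.Date(config$start_date) + records$day)
  records <- records[order(records$sample_id, records$day, records$side),
                     c("sample_id", "side", "group", "day", "date_stamp",
                       "ri5", "ri10", "days_left5", "days_left9", "censored")]
  rownames(records) <- NULL
  structure(list(records = records, trajectories = trajectories,
                 params = lapply(trajectories, `[[`, "params"),
                 config = config, seed = seed),
            class = "fruit_cohort")
}

#' @export
print.fruit_cohort <- function(x, ...) {
  cat(sprintf("fruit cohort: %d fruits (%s), %d image records, seed %d\n",
              length(x$trajectories),
              paste(sprintf("%s=%d", names(table(x$records$group[!duplicated(x$records$sample_id)])),
                            table(x$records$group[!duplicated(x$records$sample_id)])),
                    collapse = ", "),
              nrow(x$records), x$seed))
  invisible(x)
}
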