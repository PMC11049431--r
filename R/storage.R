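#' Storage groups of the ripening experiment
#'
#' The study stored fruit in three environments: `T10` (10 degrees C, 85% RH,
#' 192 fruits), `T20` (20 degrees C, 85% RH, 143 fruits) and `Tamb`
#' (fluctuating room temperature, mean 18.7 degrees C, sd 1.2 degrees C,
#' 143 fruits). Each group carries the empirical days-per-stage slopes of the
#' forced-endpoint Days-Left regressions on the 5-stage (`alpha5`) and
#' 10-stage (`alpha9`) Ripening Index, which the simulator uses as its
#' generative targets.
#'
#' @param name one of `"T10"`, `"T20"`, `"Tamb"`.
#' @return An object of class `storage_group`: a list with fields `name`,
#'   `temp_mean`, `temp_sd`, `alpha5`, `alpha9` (both negative, days/stage)
#'   and `n_default` (cohort size in the study design).
#' @examples
#' storage_group("T10")$alpha9
#' @export
storage_group <- function(name = c("T10", "T20", "Tamb")) {
  name <- match.arg(name)
  g <- .storage_presets[[name]]
  stopifnot(g$alpha5 < 0, g$alpha9 < 0)
  # one 5-stage step spans two 10-stage steps
  ratio <- abs(g$alpha5) / (2 * abs(g$alpha9))
  stopifnot(abs(ratio - 1) < 0.10)
  structure(g, class = "storage_group")
}

.storage_presets <- list(
  T10  = list(name = "T10",  temp_mean = 10,   temp_sd = 0,
              alpha5 = -4.390, alpha9 = -2.392, n_default = 192L),
  T20  = list(name = "T20",  temp_mean = 20,   temp_sd = 0,
              alpha5 = -2.116, alpha9 = -1.156, n_default = 143L),
  Tamb = list(name = "Tamb", temp_mean = 18.7, temp_sd = 1.2,
              alpha5 = -1.929, alpha9 = -1.045, n_default = 143L)
)

#' @rdname storage_group
#' @export
storage_groups <- function() names(.storage_presets)

#' @export
print.storage_group <- function(x, ...) {
  cat(sprintf("storage group %s: %.1f C (sd %.1f), alpha5 = %.3f, alpha9 = %.3f d/stage\n",
              x$name, x$temp_mean, x$temp_sd, x$alpha5, x$alpha9))
  invisible(x)
}

#' Daily temperature profile of a storage group
#'
#' Constant for the controlled rooms; a seeded daily oscillation around the
#' recorded mean for the room-temperature group. Cosmetic metadata only: the
#' simulator's ripening speed is governed by the slope presets, not by
#' temperature.
#'
#' @param group a [storage_group()].
#' @param days number of days to emit.
#' @param seed integer seed for the oscillation.
#' @return numeric vector of daily temperatures (degrees C).
#' @export
temperature_profile <- function(group, days, seed = 1L) {
  stopifnot(inherits(group, "storage_group"), is_count(days))
  if (group$temp_sd == 0) return(rep(group$temp_mean, days))
  withr::with_seed(derive_seed(seed, "temp", group$name), {
    drift <- stats::rnorm(days, 0, group$temp_sd)
    group$temp_mean + drift
  })
}
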