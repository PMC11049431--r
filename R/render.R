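# Rendering of synthetic fruit images.
#
# A fruit is an ellipse on a near-white backdrop. Its base skin colour is the
# stage palette anchor for the current 10-stage index; scattered purple
# patches appear with a stage-dependent density (peaking while purple shades
# spread, vanishing once the skin is a homogeneous purple); dark mold spots
# appear only from stage 9; a one-sided blemish emulates wind rub / sunburn.

# CIELAB anchors per 10-stage index: yellowish green -> olive/brown ->
# scattered purple -> homogeneous purple -> senescent dark. L* strictly
# decreases from stage 1 to stage 8 (the skin darkens through ripening).
.default_stage_palette <- function() {
  m <- matrix(c(
    62, -14, 38,
    58, -12, 34,
    50,  -6, 26,
    45,  -2, 20,
    40,   4, 12,
    34,   8,  6,
    28,  10,  0,
    22,   8, -2,
    20,   6, -2,
    18,   4,  0), ncol = 3, byrow = TRUE)
  colnames(m) <- c("L", "a", "b")
  m
}

#' Rendering configuration
#'
#' @param image_size side length of the square image in pixels.
#' @param stage_palette 10 x 3 matrix of CIELAB anchors per 10-stage index;
#'   `L*` must be nonincreasing over stages 1..8.
#' @param patch_density_by_stage target fraction of fruit pixels covered by
#'   scattered purple patches, per 10-stage index.
#' @param mold_spot_rate expected mold spots per image at stage >= 9 (at
#'   least one is always drawn once senescent).
#' @param background backdrop grey level in [0, 1].
#' @param noise_sd per-channel Gaussian pixel noise sd.
#' @return list of class `render_config`.
#' @export
render_config <- function(image_size = 64L,
                          stage_palette = .default_stage_palette(),
                          patch_density_by_stage =
                            c(0, 0, 0.02, 0.05, 0.18, 0.30, 0.10, 0.03, 0.03, 0.03),
                          mold_spot_rate = 12,
                          background = 0.96,
                          noise_sd = 0.012) {
  stopifnot(is_count(image_size), image_size >= 16,
            is.matrix(stage_palette), nrow(stage_palette) == 10L,
            length(patch_density_by_stage) == 10L,
            all(patch_density_by_stage >= 0 & patch_density_by_stage <= 1),
            background >= 0, background <= 1, noise_sd >= 0)
  L <- stage_palette[1:8, 1]
  if (any(diff(L) > 0))
    stop("stage palette L* must be nonincreasing over stages 1..8", call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 stage_palette = stage_palette,
                 patch_density_by_stage = patch_density_by_stage,
                 mold_spot_rate = mold_spot_rate,
                 background = background, noise_sd = noise_sd),
            class = "render_config")
}

# paint solid disks into a logical canvas
.paint_disks <- function(mask_dim, centers_r, centers_c, radius) {
  out <- matrix(FALSE, mask_dim[1], mask_dim[2])
  rr <- matrix(seq_len(mask_dim[1]), mask_dim[1], mask_dim[2])
  cc <- matrix(seq_len(mask_dim[2]), mask_dim[1], mask_dim[2], byrow = TRUE)
  for (i in seq_along(centers_r)) {
    out <- out | ((rr - centers_r[i])^2 + (cc - centers_c[i])^2 <= radius[i]^2)
  }
  out
}

#' Render one synthetic fruit photograph
#'
#' @param trajectory a [stage_timeline()] object.
#' @param day 0-based observation day; must lie within the trajectory.
#' @param side `"front"` or `"back"`; the blemish, if any, appears only on
#'   the fruit's blemished side.
#' @param cfg a [render_config()].
#' @param seed integer seed; renders are deterministic given the seed.
#' @return list with `image` (H x W x 3 array in [0, 1], sRGB, quantized to
#'   8 bits), `mask` (logical ground-truth fruit mask) and `record` (the
#'   metadata row: sample_id, side, day, group, ri5, ri10).
#' @export
render_fruit_image <- function(trajectory, day, side = c("front", "back"),
                               cfg = render_config(), seed = 1L) {
  stopifnot(inherits(trajectory, "fruit_trajectory"), inherits(cfg, "render_config"))
  side <- match.arg(side)
  if (!(day %in% trajectory$day)) stop("day out of trajectory range", call. = FALSE)
  ri10 <- trajectory$ri10[match(day, trajectory$day)]
  p <- trajectory$params
  n <- cfg$image_size

  withr::with_seed(derive_seed(seed, "render", p$sample_id, side, day), {
    # geometry: ellipse with slight per-render jitter
    cy <- n * (0.5 + stats::runif(1, -0.02, 0.02))
    cx <- n * (0.5 + stats::runif(1, -0.02, 0.02))
    ay <- n * 0.38 * (1 + stats::runif(1, -0.04, 0.04))
    ax <- n * 0.30 * (1 + stats::runif(1, -0.04, 0.04))
    rr <- matrix(seq_len(n), n, n)
    cc <- matrix(seq_len(n), n, n, byrow = TRUE)
    mask <- ((rr - cy) / ay)^2 + ((cc - cx) / ax)^2 <= 1

    base_rgb <- lab_to_rgb(cfg$stage_palette[ri10, , drop = FALSE])
    img <- array(cfg$background, dim = c(n, n, 3))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- base_rgb[ch]
      img[, , ch] <- plane
    }

    # scattered purple ripening patches
    dens <- cfg$patch_density_by_stage[ri10]
    if (dens > 0) {
      r_patch <- max(2, n * 0.045)
      n_patch <- max(1L, round(dens * sum(mask) / (pi * r_patch^2)))
      ctr_r <- stats::runif(n_patch, cy - ay, cy + ay)
      ctr_c <- stats::runif(n_patch, cx - ax, cx + ax)
      rad <- r_patch * stats::runif(n_patch, 0.7, 1.3)
      patch <- .paint_disks(c(n, n), ctr_r, ctr_c, rad) & mask
      patch_rgb <- lab_to_rgb(matrix(c(30, 18, -8), 1))
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[patch] <- 0.25 * plane[patch] + 0.75 * patch_rgb[ch]
        img[, , ch] <- plane
      }
    }

    # dark mold spots, only once senescent (stage >= 9)
    if (ri10 >= 9L) {
      n_spot <- max(1L, stats::rpois(1, cfg$mold_spot_rate * (1 + (ri10 == 10L))))
      ctr_r <- stats::runif(n_spot, cy - 0.9 * ay, cy + 0.9 * ay)
      ctr_c <- stats::runif(n_spot, cx - 0.9 * ax, cx + 0.9 * ax)
      rad <- pmax(1, n * 0.018 * stats::runif(n_spot, 0.6, 1.6))
      spot <- .paint_disks(c(n, n), ctr_r, ctr_c, rad) & mask
      spot_rgb <- lab_to_rgb(matrix(c(12, 2, 2), 1))
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[spot] <- spot_rgb[ch]
        img[, , ch] <- plane
      }
      attr(img, "mold_pixels") <- sum(spot)
    } else attr(img, "mold_pixels") <- 0L

    # one-sided blemish (wind rub / sunburn): cluster of brown smudges
    if (p$blemish_side == side && p$blemish_intensity > 0) {
      k <- sample(3:6, 1)
      br <- stats::runif(1, cy - 0.5 * ay, cy + 0.5 * ay)
      bc <- stats::runif(1, cx - 0.5 * ax, cx + 0.5 * ax)
      ctr_r <- br + stats::rnorm(k, 0, n * 0.04)
      ctr_c <- bc + stats::rnorm(k, 0, n * 0.04)
      rad <- pmax(1.5, n * 0.05 * stats::runif(k, 0.5, 1.2) * p$blemish_intensity)
      blem <- .paint_disks(c(n, n), ctr_r, ctr_c, rad) & mask
      blem_rgb <- lab_to_rgb(matrix(c(35, 12, 22), 1))
      w <- 0.8 * p$blemish_intensity
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[blem] <- (1 - w) * plane[blem] + w * blem_rgb[ch]
        img[, , ch] <- plane
      }
    }

    if (cfg$noise_sd > 0)
      img <- clip01(img + array(stats::rnorm(length(img), 0, cfg$noise_sd), dim = dim(img)))
    img_q <- round(img * 255) / 255
    attr(img_q, "mold_pixels") <- attr(img, "mold_pixels")

    list(image = img_q, mask = mask,
         record = data.frame(sample_id = p$sample_id, side = side, day = day,
                             group = p$group, ri5 = stage5_from_stage10(ri10),
                             ri10 = ri10, stringsAsFactors = FALSE))
  })
}

#' Image provider for a simulated cohort
#'
#' Returns a function mapping a metadata record (one row of
#' `cohort$records`, or a list with `sample_id`, `side`, `day`) to its
#' rendered image. Renders are deterministic: the per-record seed is derived
#' from the cohort seed, so repeated calls return identical pixels.
#'
#' @param cohort a [simulate_cohort()] object.
#' @param cfg a [render_config()].
#' @return function(record) -> image array.
#' @export
cohort_image_provider <- function(cohort, cfg = render_config()) {
  stopifnot(inherits(cohort, "fruit_cohort"))
  force(cfg)
  function(record) {
    id <- as.integer(record$sample_id)
    img <- render_fruit_image(cohort$trajectories[[id]],
                              day = as.integer(record$day),
                              side = as.character(record$side), cfg = cfg,
                              seed = cohort$seed)$image
    attr(img, "mold_pixels") <- NULL
    img
  }
}
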