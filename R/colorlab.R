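# Initial colour characterization: background segmentation, colorimeter-style
# calibration of CIELAB values, per-image 5-colour k-means palettes and the
# cohort-level 6-colour predominance palette.

#' Segment the fruit from a near-white backdrop
#'
#' Luminance/chroma thresholding (a pixel is foreground if it is clearly
#' darker than the backdrop or clearly chromatic), followed by largest
#' connected component and hole filling. An image with no foreground returns
#' an empty mask rather than failing.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param luma_max luminance threshold below which a pixel is foreground.
#' @param chroma_min channel-spread threshold above which a pixel is
#'   foreground.
#' @return logical H x W mask marking fruit pixels.
#' @export
segment_foreground <- function(image, luma_max = 0.88, chroma_min = 0.10) {
  stopifnot_image(image)
  luma <- 0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
  spread <- pmax(image[, , 1], image[, , 2], image[, , 3]) -
    pmin(image[, , 1], image[, , 2], image[, , 3])
  cand <- luma < luma_max | spread > chroma_min
  if (!any(cand)) return(matrix(FALSE, nrow(luma), ncol(luma)))
  lab <- EBImage::bwlabel(cand * 1)
  sizes <- tabulate(as.integer(lab[lab > 0]))
  keep <- which.max(sizes)
  mask <- lab == keep
  mask <- EBImage::fillHull(mask * 1) > 0
  matrix(as.logical(mask), nrow(luma), ncol(luma))
}

#' Fit a colour calibration against reference CIELAB patches
#'
#' Least-squares map from device-derived Lab coordinates to colorimeter
#' reference Lab, emulating the study's calibration-kit correction. The map
#' is affine (default) or full degree-2 polynomial in (L, a, b),
#' fitted per output channel.
#'
#' @param device_patches n x 3 matrix of device Lab values.
#' @param reference_patches n x 3 matrix of reference Lab values.
#' @param form `"affine"` (4 parameters per channel) or `"quadratic"`
#'   (10 per channel).
#' @return object of class `color_calibration` with `coefficients`, `form`,
#'   `residuals` and `rmse`; apply with `predict()`.
#' @export
fit_color_calibration <- function(device_patches, reference_patches,
                                  form = c("affine", "quadratic")) {
  form <- match.arg(form)
  X <- as.matrix(device_patches)
  Y <- as.matrix(reference_patches)
  stopifnot(ncol(X) == 3L, ncol(Y) == 3L, nrow(X) == nrow(Y))
  B <- .calibration_basis(X, form)
  if (nrow(B) < ncol(B))
    stop(sprintf("underdetermined fit: %d patches for %d parameters per channel",
                 nrow(B), ncol(B)), call. = FALSE)
  fit <- stats::lm.fit(B, Y)
  res <- Y - B %*% fit$coefficients
  structure(list(coefficients = fit$coefficients, form = form,
                 residuals = res, rmse = sqrt(mean(res^2))),
            class = "color_calibration")
}

.calibration_basis <- function(X, form) {
  L <- X[, 1]; a <- X[, 2]; b <- X[, 3]
  if (form == "affine") cbind(1, L, a, b)
  else cbind(1, L, a, b, L^2, a^2, b^2, L * a, L * b, a * b)
}

#' @param object a `color_calibration`.
#' @param newdata n x 3 matrix of device Lab values to correct.
#' @param ... unused.
#' @rdname fit_color_calibration
#' @export
predict.color_calibration <- function(object, newdata, ...) {
  B <- .calibration_basis(as.matrix(newdata), object$form)
  out <- B %*% object$coefficients
  colnames(out) <- c("L", "a", "b")
  out
}

#' @export
print.color_calibration <- function(x, ...) {
  cat(sprintf("colour calibration (%s): fit RMSE %.4g on %d patches\n",
              x$form, x$rmse, nrow(x$residuals)))
  invisible(x)
}

.new_palette <- function(lab, rgb, weight) {
  ord <- order(weight, decreasing = TRUE)
  out <- data.frame(rank = seq_along(ord),
                    L = lab[ord, 1], a = lab[ord, 2], b = lab[ord, 3],
                    R = rgb[ord, 1], G = rgb[ord, 2], B = rgb[ord, 3],
                    weight = weight[ord])
  rownames(out) <- NULL
  class(out) <- c("fruit_palette", "data.frame")
  out
}

#' Extract a k-colour palette from a segmented image
#'
#' k-means clustering of the (optionally calibration-corrected) CIELAB values
#' of the masked pixels; the palette holds cluster-mean colours with
#' pixel-fraction weights, ordered by predominance. If the mask holds fewer
#' distinct colours than `k`, those distinct colours are returned with merged
#' weights.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param mask logical mask (see [segment_foreground()]); must be non-empty.
#' @param k number of clusters.
#' @param seed integer seed (k-means is deterministic given the seed).
#' @param calibration optional [fit_color_calibration()] model applied to
#'   the Lab pixels before clustering.
#' @return object of class `fruit_palette`: data frame with rank, L, a, b,
#'   companion sRGB, and weights summing to 1.
#' @export
extract_palette <- function(image, mask, k = 5L, seed = 1L, calibration = NULL) {
  stopifnot_image(image)
  stopifnot(is.logical(mask), all(dim(mask) == dim(image)[1:2]))
  if (!any(mask)) stop("empty mask", call. = FALSE)
  px <- cbind(image[, , 1][mask], image[, , 2][mask], image[, , 3][mask])
  lab <- rgb_to_lab(px)
  if (!is.null(calibration)) lab <- predict(calibration, lab)
  distinct <- unique(round(lab, 6))
  if (nrow(distinct) <= k) {
    grp <- match(apply(round(lab, 6), 1, paste, collapse = ","),
                 apply(distinct, 1, paste, collapse = ","))
    w <- tabulate(grp, nbins = nrow(distinct)) / nrow(lab)
    rgb <- lab_to_rgb(distinct)
    return(.new_palette(distinct, rgb, w))
  }
  km <- withr::with_seed(derive_seed(seed, "palette"),
                         stats::kmeans(lab, centers = k, nstart = 5, iter.max = 50))
  w <- as.numeric(km$size) / sum(km$size)
  .new_palette(km$centers, lab_to_rgb(km$centers), w)
}

#' Aggregate per-image palettes into a predominance palette
#'
#' Pools the entries of many per-image palettes and clusters them into `m`
#' groups by weighted k-means in CIELAB (weights are the entries' pixel
#' fractions), giving the cohort-level most-predominant colours ordered by
#' total weight, with companion weighted-average sRGB values.
#'
#' @param palettes list of [extract_palette()] objects.
#' @param m number of output colours.
#' @param seed integer seed.
#' @return object of class `fruit_palette` with weights normalized to sum 1.
#' @export
aggregate_palettes <- function(palettes, m = 6L, seed = 1L) {
  stopifnot(length(palettes) > 0)
  entries <- do.call(rbind, lapply(palettes, function(p)
    as.data.frame(p)[, c("L", "a", "b", "R", "G", "B", "weight")]))
  lab <- as.matrix(entries[, c("L", "a", "b")])
  w <- entries$weight / sum(entries$weight)
  distinct <- unique(round(lab, 6))
  if (nrow(distinct) < m)
    stop(sprintf("only %d distinct palette entries for m = %d", nrow(distinct), m),
         call. = FALSE)
  fit <- withr::with_seed(derive_seed(seed, "aggregate"),
                          .weighted_kmeans(lab, w, m))
  rgb <- vapply(1:3, function(ch)
    vapply(seq_len(m), function(g) {
      sel <- fit$cluster == g
      sum(entries[sel, c("R", "G", "B")[ch]] * w[sel]) / sum(w[sel])
    }, numeric(1)), numeric(m))
  .new_palette(fit$centers, matrix(rgb, ncol = 3), fit$weight)
}

# weighted Lloyd iterations with k-means++ style seeding
.weighted_kmeans <- function(X, w, k, iter_max = 100L, n_start = 5L) {
  best <- NULL
  for (s in seq_len(n_start)) {
    centers <- X[.kmeanspp_init(X, w, k), , drop = FALSE]
    cluster <- rep(1L, nrow(X))
    for (it in seq_len(iter_max)) {
      d2 <- .sqdist(X, centers)
      new_cluster <- max.col(-d2, ties.method = "first")
      if (identical(new_cluster, cluster) && it > 1L) break
      cluster <- new_cluster
      for (g in seq_len(k)) {
        sel <- cluster == g
        if (any(sel)) centers[g, ] <- colSums(X[sel, , drop = FALSE] * w[sel]) / sum(w[sel])
      }
    }
    wss <- sum(w * d2[cbind(seq_len(nrow(X)), cluster)])
    if (is.null(best) || wss < best$wss)
      best <- list(centers = centers, cluster = cluster, wss = wss,
                   weight = vapply(seq_len(k), function(g) sum(w[cluster == g]), numeric(1)))
  }
  best
}

.kmeanspp_init <- function(X, w, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L, prob = w)
  for (j in 2:k) {
    d2 <- apply(.sqdist(X, X[idx[1:(j - 1)], , drop = FALSE]), 1, min)
    p <- w * d2
    if (sum(p) <= 0) p <- rep(1, n)
    idx[j] <- sample.int(n, 1L, prob = p)
  }
  idx
}

.sqdist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  d2[d2 < 0] <- 0   # numerical guard
  d2
}

#' @export
print.fruit_palette <- function(x, ...) {
  cat(sprintf("colour palette, %d entries (by predominance):\n", nrow(x)))
  print.data.frame(cbind(round(as.data.frame(x)[, c("L", "a", "b")], 1),
                         weight = round(x$weight, 3)))
  invisible(x)
}

#' Write a palette as CSV and a horizontal swatch image
#'
#' @param palette a `fruit_palette`.
#' @param csv path for the CSV (rank, L, a, b, R, G, B, weight);
#'   `NULL` to skip.
#' @param swatch path for a PNG swatch of the colours left-to-right by
#'   predominance; `NULL` to skip.
#' @param swatch_height,swatch_width swatch dimensions in pixels.
#' @return invisibly, the palette.
#' @export
write_palette <- function(palette, csv = NULL, swatch = NULL,
                          swatch_height = 40L, swatch_width = 240L) {
  stopifnot(inherits(palette, "fruit_palette"))
  if (!is.null(csv))
    utils::write.csv(as.data.frame(palette), csv, row.names = FALSE)
  if (!is.null(swatch)) {
    m <- nrow(palette)
    widths <- diff(round(seq(0, swatch_width, length.out = m + 1)))
    img <- array(0, dim = c(swatch_height, swatch_width, 3))
    at <- 0L
    for (i in seq_len(m)) {
      cols <- (at + 1L):(at + widths[i])
      for (ch in 1:3)
        img[, cols, ch] <- as.numeric(palette[i, c("R", "G", "B")[ch]])
      at <- at + widths[i]
    }
    png::writePNG(clip01(img), swatch)
  }
  invisible(palette)
}
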