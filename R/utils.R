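# Internal helpers shared across modules.

# Deterministic 32-bit sub-seed derived from a master seed and a label path,
# so every stochastic component gets its own reproducible stream.
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- 5381
  for (ch in utf8ToInt(key)) h <- (h * 33 + ch) %% 2147483629
  as.integer(h)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' @importFrom grDevices convertColor
rgb_to_lab <- function(rgb) {
  rgb <- matrix(rgb, ncol = 3)
  convertColor(rgb, from = "sRGB", to = "Lab", to.ref.white = "D65")
}

lab_to_rgb <- function(lab) {
  lab <- matrix(lab, ncol = 3)
  clip01(convertColor(lab, from = "Lab", to = "sRGB", from.ref.white = "D65"))
}

# image arrays are H x W x 3 in [0, 1]
stopifnot_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("expected an H x W x 3 numeric image array", call. = FALSE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
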