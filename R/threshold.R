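# Threshold computation with the user-controlled multiplier and minimum
# permitted threshold, and strict binarization.

#' Compute an intensity threshold
#'
#' Raw threshold `t0` by method:
#' \describe{
#'   \item{otsu}{argmax of between-class variance over a 256-bin histogram
#'     spanning \[min, max\] of the image; ties broken toward the lowest bin;
#'     returned as the upper-edge intensity of the chosen bin. Constant
#'     images are degenerate (error).}
#'   \item{mean}{mean intensity.}
#'   \item{fixed}{the supplied value `t`.}
#' }
#' The returned threshold is `max(k * t0, t_min)`: the multiplier is applied
#' first, then the minimum permitted threshold clamps it (guards against
#' segmenting background in low-signal images).
#'
#' @param img numeric array/matrix of intensities (non-empty).
#' @param method `"otsu"`, `"mean"` or `"fixed"`.
#' @param k positive threshold multiplier (default 1).
#' @param t_min minimum permitted threshold (default 0). Interpreted as an
#'   absolute intensity, or as a fraction of the image's \[min, max\] range
#'   when `t_min_fractional = TRUE`.
#' @param t fixed threshold (required for `method = "fixed"`).
#' @param t_min_fractional interpret `t_min` as a fraction of the range.
#' @return threshold intensity (scalar). Foreground is strictly above it.
#' @export
compute_threshold <- function(img, method = c("otsu", "mean", "fixed"),
                              k = 1, t_min = 0, t = NULL,
                              t_min_fractional = FALSE) {
  method <- match.arg(method)
  if (inherits(img, "ImageStack")) img <- img$data
  if (length(img) == 0L) validation_error("cannot threshold an empty image")
  check_number(k, "k", min = 0, strict_min = TRUE)
  check_number(t_min, "t_min")
  check_flag(t_min_fractional, "t_min_fractional")
  t0 <- switch(method,
    otsu = otsu_threshold(img),
    mean = mean(img),
    fixed = {
      if (is.null(t)) validation_error("method 'fixed' requires t")
      check_number(t, "t")
      t
    })
  if (t_min_fractional) {
    rng <- range(img)
    t_min <- rng[1] + t_min * (rng[2] - rng[1])
  }
  max(k * t0, t_min)
}

# 256-bin Otsu. Bin b (0-based) covers [min + b*w, min + (b+1)*w); the
# threshold after bin b is the bin's upper edge. Vectorized via cumulative
# sums; the test suite checks it against an exhaustive 255-candidate search.
otsu_threshold <- function(img) {
  rng <- range(img)
  if (rng[1] == rng[2])
    degenerate_histogram_error("constant image: Otsu threshold undefined")
  nb <- 256L
  b <- pmin(floor((as.numeric(img) - rng[1]) / (rng[2] - rng[1]) * nb), nb - 1L)
  h <- tabulate(b + 1L, nbins = nb)
  p <- h / sum(h)
  idx <- seq_len(nb) - 1L                  # bin indices as surrogate intensities
  w0 <- cumsum(p)[-nb]                     # class 0 = bins 0..b
  mu <- cumsum(p * idx)
  mu_t <- mu[nb]
  mu0 <- mu[-nb]
  w1 <- 1 - w0
  between <- ifelse(w0 > 0 & w1 > 0, (mu_t * w0 - mu0)^2 / (w0 * w1), -Inf)
  bstar <- which.max(between) - 1L         # which.max takes the first (lowest) tie
  rng[1] + (bstar + 1) * (rng[2] - rng[1]) / nb
}

#' Binarize an image at a threshold
#'
#' Foreground iff intensity is strictly greater than `t`, so a threshold at
#' the image maximum yields an empty mask.
#'
#' @param img numeric array/matrix or [image_stack()] (single channel).
#' @param t threshold intensity.
#' @return a [mask()] of the same shape.
#' @export
binarize <- function(img, t) {
  if (inherits(img, "ImageStack")) img <- img$data
  check_number(t, "t")
  mask(array(img > t, dim = dim(img) %||% length(img)))
}
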