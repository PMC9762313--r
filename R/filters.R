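# Pre-filters and background subtraction.
#
# All window filters use nearest-replication edge handling and operate on 2D
# planes; for stacks/movies they are applied to every yx plane independently
# (per z-slice / frame / channel).

# apply f(matrix)->matrix over every yx plane of an ImageStack or array
map_planes <- function(x, f) {
  if (inherits(x, "ImageStack")) {
    out <- x
    out$data <- map_planes(x$data, f)
    return(out)
  }
  d <- dim(x)
  nd <- length(d)
  if (nd == 2L) return(f(x))
  nplanes <- prod(d[seq_len(nd - 2L)])
  per <- aperm(x, c(nd - 1L, nd, seq_len(nd - 2L)))
  dim(per) <- c(d[nd - 1L], d[nd], nplanes)
  for (i in seq_len(nplanes)) per[, , i] <- f(per[, , i, drop = TRUE])
  dim(per) <- c(d[nd - 1L], d[nd], d[seq_len(nd - 2L)])
  aperm(per, c(seq_len(nd - 2L) + 2L, 1L, 2L))
}

# clamped-index shifted copy of a matrix (nearest replication)
shift_clamp <- function(m, dy, dx) {
  d <- dim(m)
  m[pmin(pmax(seq_len(d[1]) + dy, 1L), d[1]),
    pmin(pmax(seq_len(d[2]) + dx, 1L), d[2]), drop = FALSE]
}

window_offsets <- function(radius) {
  expand.grid(dy = -radius:radius, dx = -radius:radius)
}

#' 2D median filter
#'
#' Replaces each pixel by the median of its (2r+1)² neighborhood, per yx
#' plane, with nearest-replication edges. The optional noise-removal
#' pre-filter of the uptake and section workflows.
#'
#' @param stack [image_stack()], matrix or array.
#' @param radius window radius in pixels (>= 1).
#' @return filtered object of the same type/shape.
#' @export
median_filter_2d <- function(stack, radius) {
  check_number(radius, "radius", min = 1, integer = TRUE)
  map_planes(stack, function(m) {
    off <- window_offsets(radius)
    w <- matrix(0, length(m), nrow(off))
    for (i in seq_len(nrow(off))) w[, i] <- shift_clamp(m, off$dy[i], off$dx[i])
    out <- apply(w, 1L, stats::median)
    dim(out) <- dim(m)
    out
  })
}

#' Gaussian smoothing filter
#'
#' Separable Gaussian convolution (kernel truncated at 3σ, normalized to unit
#' sum), nearest-replication edges, per yx plane. `sigma = 0` is the
#' identity. The noise-reduction pre-filter of the immune-cell workflow.
#'
#' @param stack [image_stack()], matrix or array.
#' @param sigma standard deviation in pixels (>= 0).
#' @return filtered object of the same type/shape.
#' @export
gaussian_filter <- function(stack, sigma) {
  check_number(sigma, "sigma", min = 0)
  if (sigma == 0) return(stack)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  map_planes(stack, function(m) {
    d <- dim(m)
    out <- matrix(0, d[1], d[2])
    for (i in seq_along(k)) out <- out + k[i] * shift_clamp(m, i - r - 1L, 0L)
    out2 <- matrix(0, d[1], d[2])
    for (i in seq_along(k)) out2 <- out2 + k[i] * shift_clamp(out, 0L, i - r - 1L)
    out2
  })
}

#' Variance filter
#'
#' Replaces each pixel by the population variance of its (2r+1)²
#' neighborhood; highlights textured regions (used to find tissue sections
#' against a flat background).
#'
#' @param stack [image_stack()], matrix or array.
#' @param radius window radius in pixels (>= 1).
#' @return filtered object of the same type/shape.
#' @export
variance_filter <- function(stack, radius) {
  check_number(radius, "radius", min = 1, integer = TRUE)
  map_planes(stack, function(m) {
    off <- window_offsets(radius)
    s <- 0; s2 <- 0
    for (i in seq_len(nrow(off))) {
      v <- shift_clamp(m, off$dy[i], off$dx[i])
      s <- s + v; s2 <- s2 + v * v
    }
    n <- nrow(off)
    pmax(s2 / n - (s / n)^2, 0)
  })
}

# non-flat ball structuring element: height profile over a disc support
ball_element <- function(radius) {
  off <- window_offsets(radius)
  keep <- off$dy^2 + off$dx^2 <= radius^2
  off <- off[keep, , drop = FALSE]
  off$h <- sqrt(radius^2 - off$dy^2 - off$dx^2) - radius  # <= 0, 0 at center
  off
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image with a ball
#' structuring element of the given radius (erosion then dilation with the
#' ball's height profile) and subtracts it, clipping at zero. Structures
#' narrower than the ball survive; broad plateaus are removed.
#'
#' @param stack [image_stack()], matrix or array.
#' @param radius ball radius in pixels (>= 1).
#' @return background-subtracted object of the same type/shape.
#' @export
rolling_ball_subtract <- function(stack, radius) {
  check_number(radius, "radius", min = 1, integer = TRUE)
  ball <- ball_element(radius)
  map_planes(stack, function(m) {
    ero <- matrix(Inf, nrow(m), ncol(m))
    for (i in seq_len(nrow(ball)))
      ero <- pmin(ero, shift_clamp(m, ball$dy[i], ball$dx[i]) - ball$h[i])
    dil <- matrix(-Inf, nrow(m), ncol(m))
    for (i in seq_len(nrow(ball)))
      dil <- pmax(dil, shift_clamp(ero, ball$dy[i], ball$dx[i]) + ball$h[i])
    pmax(m - dil, 0)
  })
}
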