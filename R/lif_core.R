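# Local Image Fitting (LIF) machinery: regularised Heaviside/Dirac pair,
# windowed local region means m1/m2, the local fitted image, the LIF
# energy and its data force.
#
# Sign convention (fixed package-wide): "inside" the contour is the
# region {phi > 0}, i.e. where H(phi) = 1; m1 is the local mean of the
# inside region, m2 of the outside.

#' Regularised Heaviside function
#'
#' Arctangent regularisation
#' \eqn{H_\epsilon(z) = \tfrac12 (1 + \tfrac{2}{\pi} \arctan(z/\epsilon))}:
#' smooth, strictly increasing, \eqn{H(0) = 1/2}, with derivative
#' [dirac()].
#'
#' @param z Numeric vector/matrix (level-set values).
#' @param eps Regularisation width in pixel units (> 0).
#' @return Values in (0, 1), same shape as \code{z}.
#' @export
heaviside <- function(z, eps = 1) {
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    stop("`eps` must be a positive scalar", call. = FALSE)
  0.5 * (1 + (2 / pi) * atan(z / eps))
}

#' Regularised Dirac delta
#'
#' \eqn{\delta_\epsilon(z) = \epsilon / (\pi (\epsilon^2 + z^2))},
#' the derivative of [heaviside()].
#'
#' @inheritParams heaviside
#' @return Non-negative values, same shape as \code{z}.
#' @export
dirac <- function(z, eps = 1) {
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    stop("`eps` must be a positive scalar", call. = FALSE)
  (eps / pi) / (eps^2 + z^2)
}

# k x k box-window sums with replicate padding (compiled kernel).
box_sum <- function(m, k) {
  .box_sum_c(m, as.integer(k))
}

#' Windowed local region means and the local fitted image
#'
#' For each pixel, computes the mean intensity of the inside region
#' (\code{m1}) and outside region (\code{m2}) over a square window
#' centred on the pixel, weighting membership by the regularised
#' Heaviside of \code{phi}:
#' \deqn{m_1(x) = \frac{\sum_W H(\phi) I}{\sum_W H(\phi)}, \quad
#'       m_2(x) = \frac{\sum_W (1 - H(\phi)) I}{\sum_W (1 - H(\phi))}}
#' with edge-replicating padding. Where a window is entirely one-sided
#' (denominator below 1e-10) the corresponding mean falls back to the
#' global region mean, which keeps the force finite when the contour is
#' far away. The local fitted image is
#' \eqn{I^{LFI} = m_1 H(\phi) + m_2 (1 - H(\phi))}.
#'
#' @param image Numeric matrix.
#' @param phi Level-set matrix, congruent with \code{image}; inside is
#'   \code{phi > 0}.
#' @param window Odd window side length (>= 3), in pixels.
#' @param eps Heaviside regularisation width.
#' @return List with matrices \code{m1}, \code{m2}, \code{lfi}.
#' @export
local_fit <- function(image, phi, window = 11, eps = 1) {
  stopifnot(is.matrix(image), is.matrix(phi))
  if (!all(dim(image) == dim(phi)))
    stop("`image` and `phi` must have the same shape", call. = FALSE)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  H <- heaviside(phi, eps)
  Hc <- 1 - H
  num1 <- box_sum(H * image, window)
  den1 <- box_sum(H, window)
  num2 <- box_sum(Hc * image, window)
  den2 <- box_sum(Hc, window)
  g1 <- if (sum(H) > 1e-10) sum(H * image) / sum(H) else mean(image)
  g2 <- if (sum(Hc) > 1e-10) sum(Hc * image) / sum(Hc) else mean(image)
  m1 <- num1 / pmax(den1, 1e-10)
  m2 <- num2 / pmax(den2, 1e-10)
  bad1 <- den1 < 1e-10
  if (any(bad1)) m1[bad1] <- g1
  bad2 <- den2 < 1e-10
  if (any(bad2)) m2[bad2] <- g2
  lfi <- m1 * H + m2 * Hc
  list(m1 = m1, m2 = m2, lfi = lfi)
}

#' LIF data energy
#'
#' \eqn{E^{LIF} = \tfrac12 \sum_\Omega (I - I^{LFI})^2}: the squared
#' residual between the image and its two-phase locally fitted
#' approximation.
#'
#' @param image Numeric matrix.
#' @param fit A decomposition from [local_fit()].
#' @return Non-negative scalar.
#' @export
lif_energy <- function(image, fit) {
  stopifnot(is.matrix(image), all(dim(image) == dim(fit$lfi)))
  0.5 * sum((image - fit$lfi)^2)
}

#' LIF data force
#'
#' The field \eqn{(I - I^{LFI})(m_1 - m_2)} multiplying
#' \eqn{\delta_\epsilon(\phi)} in the gradient-descent evolution of the
#' LIF energy (local means held fixed during the variation). Positive
#' values expand the inside region.
#'
#' @inheritParams lif_energy
#' @return Matrix congruent with \code{image}.
#' @export
lif_force <- function(image, fit) {
  stopifnot(is.matrix(image), all(dim(image) == dim(fit$lfi)))
  (image - fit$lfi) * (fit$m1 - fit$m2)
}
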