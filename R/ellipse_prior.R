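# Elliptical shape prior: the ellipse-shaped level set phi_e, the prior
# energy (arc-length smoothing + Heaviside-footprint mismatch), analytic
# gradients of the mismatch term with respect to the five ellipse
# parameters, and their gradient-descent fitting loop.

#' Ellipse parameters
#'
#' Centre \code{(x_e, y_e)} in 0-based pixel coordinates, rotation
#' \code{theta_e} in radians (wrapped to \eqn{(-\pi/2, \pi/2]}), and
#' semi-axis scales \code{a_e} (major direction) and \code{b_e} (minor),
#' in pixels. Axes are clamped above 0.5 px to guard against collapse.
#'
#' @param x_e,y_e Centre coordinates (px).
#' @param theta_e Rotation (radians).
#' @param a_e,b_e Semi-axis lengths (px, > 0.5).
#' @return An \code{ellipse_params} list.
#' @export
ellipse_params <- function(x_e, y_e, theta_e = 0, a_e, b_e) {
  if (!all(is.finite(c(x_e, y_e, theta_e, a_e, b_e))))
    stop("ellipse parameters must be finite", call. = FALSE)
  if (a_e <= 0 || b_e <= 0)
    stop("semi-axes must be positive", call. = FALSE)
  structure(list(x_e = unname(x_e), y_e = unname(y_e),
                 theta_e = wrap_angle(unname(theta_e)),
                 a_e = max(unname(a_e), 0.5 + 1e-9),
                 b_e = max(unname(b_e), 0.5 + 1e-9)),
            class = "ellipse_params")
}

# wrap to (-pi/2, pi/2] (an ellipse has half-turn symmetry)
wrap_angle <- function(theta) {
  t <- (theta + pi / 2) %% pi
  if (t == 0) t <- pi
  t - pi / 2
}

# cache of 0-based coordinate grids, keyed by grid shape; these are
# rebuilt constantly during evolution otherwise
.grid_cache <- new.env(parent = emptyenv())

coord_grids <- function(dim) {
  key <- paste(dim[1L], dim[2L])
  g <- .grid_cache[[key]]
  if (is.null(g)) {
    nr <- dim[1L]; nc <- dim[2L]
    g <- list(x = matrix(rep(0:(nc - 1L), each = nr), nr, nc),
              y = matrix(rep(0:(nr - 1L), times = nc), nr, nc))
    .grid_cache[[key]] <- g
  }
  g
}

# rotated coordinates (u along the a-axis, v along the b-axis) of every
# pixel, 0-based grid coords x = col - 1, y = row - 1
ellipse_uv <- function(params, dim) {
  g <- coord_grids(dim)
  ct <- cos(params$theta_e); st <- sin(params$theta_e)
  dx <- g$x - params$x_e; dy <- g$y - params$y_e
  list(u = dx * ct + dy * st, v = -dx * st + dy * ct)
}

#' Ellipse-shaped level set
#'
#' \deqn{\phi_e(x, y) = 1 - \frac{((x - x_e)\cos\theta_e + (y - y_e)\sin\theta_e)^2}{a_e^2}
#'   - \frac{(-(x - x_e)\sin\theta_e + (y - y_e)\cos\theta_e)^2}{b_e^2}}
#' Positive strictly inside the ellipse, zero on it, negative outside;
#' the maximum value 1 is attained exactly at the centre. This is a
#' quadratic level set, not a signed distance function; the prior energy
#' only compares Heaviside footprints, so no renormalisation is applied.
#'
#' @param params An [ellipse_params()].
#' @param dim Grid dimensions \code{c(nrow, ncol)} = (height, width).
#' @return Numeric matrix of \eqn{\phi_e} values.
#' @export
ellipse_levelset <- function(params, dim) {
  stopifnot(inherits(params, "ellipse_params"), length(dim) >= 2L)
  uv <- ellipse_uv(params, dim)
  1 - uv$u^2 / params$a_e^2 - uv$v^2 / params$b_e^2
}

# central-difference gradient magnitude with replicated edges
grad_mag <- function(phi) {
  nr <- nrow(phi); nc <- ncol(phi)
  jp <- pmin(seq_len(nc) + 1L, nc); jm <- pmax(seq_len(nc) - 1L, 1L)
  ip <- pmin(seq_len(nr) + 1L, nr); im <- pmax(seq_len(nr) - 1L, 1L)
  gx <- (phi[, jp, drop = FALSE] - phi[, jm, drop = FALSE]) / 2
  gy <- (phi[ip, , drop = FALSE] - phi[im, , drop = FALSE]) / 2
  sqrt(gx^2 + gy^2)
}

# the footprint-mismatch term (alpha/2) * sum (H(phi) - H(phi_e))^2.
# phi is in pixel units but phi_e is the dimensionless quadratic of
# ellipse_levelset() (maximum 1), so the two Heavisides carry separate
# regularisation widths: eps for phi, eps_e for phi_e.
ellipse_energy <- function(phi, params, alpha = 1, eps = 1, eps_e = 0.05) {
  phi_e <- ellipse_levelset(params, dim(phi))
  (alpha / 2) * sum((heaviside(phi, eps) - heaviside(phi_e, eps_e))^2)
}

#' Shape-prior energy
#'
#' \eqn{E_{prior} = E_{smooth} + E_{ellipse}} with
#' \eqn{E_{smooth} = \nu \sum \delta_\epsilon(\phi) |\nabla\phi|}
#' (arc length of the zero level contour) and
#' \eqn{E_{ellipse} = \tfrac{\alpha}{2} \sum (H_\epsilon(\phi) - H_\epsilon(\phi_e))^2}
#' (footprint mismatch with the prior ellipse). Gradients by central
#' differences.
#'
#' @param phi Level-set matrix.
#' @param params An [ellipse_params()].
#' @param nu Non-negative arc-length weight.
#' @param alpha Non-negative ellipse-constraint weight.
#' @param eps Heaviside/Dirac regularisation width for \code{phi}
#'   (pixel units).
#' @param eps_e Regularisation width for the dimensionless ellipse
#'   level set \eqn{\phi_e}; much smaller than \code{eps} because
#'   \eqn{\phi_e} peaks at 1.
#' @return Non-negative scalar.
#' @export
prior_energy <- function(phi, params, nu = 6.50025, alpha = 1, eps = 1,
                         eps_e = 0.05) {
  stopifnot(is.matrix(phi), nu >= 0, alpha >= 0)
  nu * sum(dirac(phi, eps) * grad_mag(phi)) +
    ellipse_energy(phi, params, alpha, eps, eps_e)
}

#' Analytic gradients of the ellipse-mismatch energy
#'
#' Partial derivatives of
#' \eqn{E_{ellipse} = \tfrac{\alpha}{2}\sum (H(\phi) - H(\phi_e))^2}
#' with respect to \eqn{(x_e, y_e, \theta_e, a_e, b_e)}, by the chain
#' rule:
#' \deqn{\partial E / \partial p = -\alpha \sum (H(\phi) - H(\phi_e))\,
#'   \delta(\phi_e)\, \partial\phi_e/\partial p}
#' with the analytic partials of the quadratic ellipse level set.
#'
#' @inheritParams prior_energy
#' @return Named numeric 5-vector
#'   \code{(x_e, y_e, theta_e, a_e, b_e)}.
#' @export
ellipse_gradients <- function(phi, params, eps = 1, alpha = 1, eps_e = 0.05) {
  stopifnot(is.matrix(phi), inherits(params, "ellipse_params"))
  uv <- ellipse_uv(params, dim(phi))
  a2 <- params$a_e^2; b2 <- params$b_e^2
  ct <- cos(params$theta_e); st <- sin(params$theta_e)
  phi_e <- 1 - uv$u^2 / a2 - uv$v^2 / b2
  w <- -alpha * (heaviside(phi, eps) - heaviside(phi_e, eps_e)) * dirac(phi_e, eps_e)
  d_xe <- 2 * uv$u * ct / a2 - 2 * uv$v * st / b2
  d_ye <- 2 * uv$u * st / a2 + 2 * uv$v * ct / b2
  d_th <- 2 * uv$u * uv$v * (1 / b2 - 1 / a2)
  d_a <- 2 * uv$u^2 / params$a_e^3
  d_b <- 2 * uv$v^2 / params$b_e^3
  c(x_e = sum(w * d_xe), y_e = sum(w * d_ye), theta_e = sum(w * d_th),
    a_e = sum(w * d_a), b_e = sum(w * d_b))
}

#' Fit an ellipse to a level-set footprint by gradient descent
#'
#' Evolves the five ellipse parameters to minimise the footprint
#' mismatch \eqn{E_{ellipse}} between \eqn{H(\phi)} and
#' \eqn{H(\phi_e)}. Per-parameter step sizes accommodate the
#' heterogeneous scales (pixels for centre/axes, radians for the
#' angle); a joint backtracking factor halves any step that would
#' increase the energy, so the energy is non-increasing across accepted
#' iterations. Rotation updates are frozen when \eqn{|a_e - b_e| <
#' 0.5} px, where the angle is unidentifiable. Stops when the maximum
#' relative parameter change in a sweep falls below \code{tol}.
#'
#' @param phi Level-set matrix whose footprint \eqn{\{\phi > 0\}} is the
#'   fitting target.
#' @param init Starting [ellipse_params()].
#' @param alpha Ellipse-constraint weight (scales the energy, not the
#'   optimum).
#' @param eps Regularisation width.
#' @param step_sizes Steps for \code{(x_e, y_e, theta_e, a_e, b_e)}.
#' @param max_iter Iteration cap.
#' @param tol Relative-change stationarity tolerance.
#' @return Fitted [ellipse_params()] with attributes \code{iterations}
#'   and \code{energy}.
#' @export
fit_ellipse_to_levelset <- function(phi, init, alpha = 1, eps = 1,
                                    eps_e = 0.05,
                                    step_sizes = c(0.1, 0.1, 1e-3, 0.05, 0.05),
                                    max_iter = 200, tol = 1e-4) {
  stopifnot(is.matrix(phi), inherits(init, "ellipse_params"),
            length(step_sizes) == 5L, max_iter >= 1, tol > 0)
  p <- c(init$x_e, init$y_e, init$theta_e, init$a_e, init$b_e)
  Hphi <- heaviside(phi, eps)
  e_of <- function(p) {
    pe <- ellipse_params(p[1], p[2], p[3], p[4], p[5])
    phi_e <- ellipse_levelset(pe, dim(phi))
    (alpha / 2) * sum((Hphi - heaviside(phi_e, eps_e))^2)
  }
  e_cur <- e_of(p)
  iters <- 0L
  for (it in seq_len(max_iter)) {
    pe <- ellipse_params(p[1], p[2], p[3], p[4], p[5])
    g <- ellipse_gradients(phi, pe, eps, alpha, eps_e)
    if (any(!is.finite(g)))
      stop("ellipse fit diverged (non-finite gradient); step sizes: ",
           paste(step_sizes, collapse = ", "), call. = FALSE)
    if (abs(p[4] - p[5]) < 0.5) g[3] <- 0  # angle unidentifiable near circle
    fac <- 1
    repeat {
      trial <- p - fac * step_sizes * g
      trial[3] <- wrap_angle(trial[3])
      trial[4:5] <- pmax(trial[4:5], 0.5 + 1e-9)
      if (any(!is.finite(trial)))
        stop("ellipse fit diverged (non-finite parameters); step sizes: ",
             paste(step_sizes, collapse = ", "), call. = FALSE)
      e_new <- e_of(trial)
      if (e_new <= e_cur || fac < 1e-8) break
      fac <- fac / 2
    }
    if (e_new > e_cur) break  # no descent direction at the smallest step
    rel <- abs(trial - p) / pmax(abs(p), 1)
    p <- trial
    e_cur <- e_new
    iters <- it
    if (max(rel) < tol) break
  }
  out <- ellipse_params(p[1], p[2], p[3], p[4], p[5])
  attr(out, "iterations") <- iters
  attr(out, "energy") <- e_cur
  out
}
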