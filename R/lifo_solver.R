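# The outer LIFO evolution: alternate local-mean refresh, ellipse
# re-fit, elliptical level-set rebuild and explicit-Euler level-set
# update until the binarised footprint is stationary.

#' Solver configuration
#'
#' All hyperparameters of the LIFO pipeline. The defaults are the
#' model's stated operating point: \eqn{\nu = 0.0001 \cdot 255 \cdot
#' 255 = 6.50025} (arc-length weight), \eqn{\alpha = 1} (ellipse
#' constraint), with image intensities brought to unit scale inside the
#' solver (\code{intensity_scale = 255}) so the three energy terms are
#' commensurate.
#'
#' @param nu Arc-length (smoothing) weight.
#' @param alpha Ellipse-constraint weight; \code{alpha = 0} disables
#'   the shape prior (plain LIF evolution).
#' @param eps Heaviside/Dirac regularisation width for \code{phi} (px).
#' @param eps_e Regularisation width for the dimensionless ellipse
#'   level set \eqn{\phi_e} (which peaks at 1), used wherever
#'   \eqn{H(\phi_e)} or \eqn{\delta(\phi_e)} appears.
#' @param window Odd side length of the local-mean window (px).
#' @param dt Time-step upper bound; each step is additionally clamped
#'   so that \eqn{dt \cdot \max|\delta_\epsilon(\phi) F| \le 0.5},
#'   i.e. the level set moves at most half a pixel-unit per iteration.
#' @param max_outer_iter Cap on outer evolution iterations.
#' @param phi_tol Stationarity tolerance: stop when the mean fraction
#'   of pixels whose binarised classification changed per iteration,
#'   averaged over the trailing \code{stationary_iters} iterations,
#'   falls below this.
#' @param stationary_iters Length of the trailing window over which
#'   footprint changes are averaged for the stopping rule. A single
#'   iteration can flip no pixels while the boundary is still moving
#'   coherently at sub-pixel speed, so stationarity is judged on a
#'   window, not on one step.
#' @param intensity_scale Divisor applied to the input image before
#'   evolution (the energy weights are calibrated for unit-scale
#'   intensities).
#' @param ellipse_step_sizes,ellipse_max_iter,ellipse_tol Inner
#'   ellipse-fit settings (see [fit_ellipse_to_levelset()]).
#' @param n_segments,ca_steps,mean_kernel Saliency-initialisation
#'   settings (see [make_initial_contour()]).
#' @param morph_kernel Odd diameter (px) of the disk structuring
#'   element used to close the binarised saliency map before component
#'   extraction; sized to bridge gaps cut by retinal vessels
#'   (about twice the expected vessel width).
#' @param seed Recorded seed (the pipeline itself uses no randomness).
#' @return A \code{lifo_config} list.
#' @export
lifo_config <- function(nu = 0.0001 * 255 * 255, alpha = 1, eps = 1,
                        eps_e = 0.05, window = 11, dt = 1,
                        max_outer_iter = 300, phi_tol = 1e-4,
                        stationary_iters = 10, intensity_scale = 255,
                        ellipse_step_sizes = c(0.1, 0.1, 1e-3, 0.05, 0.05),
                        ellipse_max_iter = 200, ellipse_tol = 1e-4,
                        n_segments = 200, ca_steps = 20, mean_kernel = 5,
                        morph_kernel = 9, seed = 0L) {
  stopifnot(nu >= 0, alpha >= 0, eps > 0, eps_e > 0, dt >= 0,
            max_outer_iter >= 1, phi_tol > 0, stationary_iters >= 1,
            intensity_scale > 0, window >= 3,
            window %% 2 == 1, length(ellipse_step_sizes) == 5L)
  structure(list(nu = nu, alpha = alpha, eps = eps, eps_e = eps_e,
                 window = as.integer(window),
                 dt = dt, max_outer_iter = as.integer(max_outer_iter),
                 phi_tol = phi_tol,
                 stationary_iters = as.integer(stationary_iters),
                 intensity_scale = intensity_scale,
                 ellipse_step_sizes = ellipse_step_sizes,
                 ellipse_max_iter = as.integer(ellipse_max_iter),
                 ellipse_tol = ellipse_tol,
                 n_segments = as.integer(n_segments),
                 ca_steps = as.integer(ca_steps),
                 mean_kernel = as.integer(mean_kernel),
                 morph_kernel = as.integer(morph_kernel),
                 seed = as.integer(seed)),
            class = "lifo_config")
}

#' Energy terms of the LIFO functional
#'
#' \deqn{E = \tfrac12 \sum (I - I^{LFI})^2
#'   + \nu \sum \delta_\epsilon(\phi)|\nabla\phi|
#'   + \tfrac{\alpha}{2} \sum (H_\epsilon(\phi) - H_\epsilon(\phi_e))^2}
#' evaluated at the supplied state. The image is used at the scale it
#' is passed in; [lifo_segment()] evaluates the trace at unit intensity
#' scale.
#'
#' @param image Numeric matrix.
#' @param phi Level-set matrix.
#' @param ellipse An [ellipse_params()] (may be NULL when
#'   \code{alpha = 0}).
#' @param config A [lifo_config()].
#' @return Named vector \code{(e_lif, e_smooth, e_ellipse, e_total)}.
#' @export
total_energy <- function(image, phi, ellipse, config = lifo_config()) {
  fit <- local_fit(image, phi, config$window, config$eps)
  e_lif <- lif_energy(image, fit)
  e_smooth <- config$nu * sum(dirac(phi, config$eps) * grad_mag(phi))
  e_ell <- if (config$alpha > 0 && !is.null(ellipse)) {
    ellipse_energy(phi, ellipse, config$alpha, config$eps, config$eps_e)
  } else 0
  c(e_lif = e_lif, e_smooth = e_smooth, e_ellipse = e_ell,
    e_total = e_lif + e_smooth + e_ell)
}

#' One explicit-Euler evolution step
#'
#' Recomputes the local means and fitted image from the incoming
#' \eqn{\phi}, then updates
#' \deqn{\phi \leftarrow \phi + dt\, \delta_\epsilon(\phi)\,
#'   [(I - I^{LFI})(m_1 - m_2) + \nu\, \mathrm{div}(\nabla\phi/|\nabla\phi|)
#'   - \alpha (H_\epsilon(\phi) - H_\epsilon(\phi_e))]}
#' with curvature by central differences (\eqn{|\nabla\phi|} floored at
#' 1e-8) and the time step clamped so the update magnitude never
#' exceeds 0.5.
#'
#' @param image Numeric matrix (at the scale the energies are
#'   calibrated for).
#' @param phi Level-set matrix.
#' @param ellipse An [ellipse_params()] or NULL when \code{alpha = 0}.
#' @param config A [lifo_config()].
#' @return List with \code{phi} (updated), \code{fit} (the
#'   decomposition used) and \code{dt} (the clamped step actually
#'   taken).
#' @export
evolve_step <- function(image, phi, ellipse, config = lifo_config()) {
  stopifnot(is.matrix(image), is.matrix(phi), all(dim(image) == dim(phi)))
  fit <- local_fit(image, phi, config$window, config$eps)
  force <- lif_force(image, fit) + config$nu * .curvature_c(phi, 1e-8)
  if (config$alpha > 0 && !is.null(ellipse)) {
    phi_e <- ellipse_levelset(ellipse, dim(phi))
    force <- force - config$alpha *
      (heaviside(phi, config$eps) - heaviside(phi_e, config$eps_e))
  }
  dphi <- dirac(phi, config$eps) * force
  mx <- max(abs(dphi))
  dt_eff <- if (mx > 0) min(config$dt, 0.5 / mx) else config$dt
  phi_new <- phi + dt_eff * dphi
  if (!all(is.finite(phi_new)))
    stop("level-set evolution diverged (non-finite phi) at dt = ",
         format(dt_eff), call. = FALSE)
  list(phi = phi_new, fit = fit, dt = dt_eff)
}

#' Segment the optic disc with the LIFO model
#'
#' Runs the full alternation: refresh the local means and fitted image
#' from the current \eqn{\phi}, re-fit the prior ellipse parameters by
#' gradient descent (warm-started from the previous iteration), rebuild
#' \eqn{\phi_e}, and take one explicit-Euler level-set step; repeats
#' until the fraction of pixels whose binarised classification changed
#' drops below \code{phi_tol} or \code{max_outer_iter} is reached.
#'
#' Initialisation follows the model's stated constants: ellipse centred
#' at \code{(width/2, height/2)}, \eqn{\theta_e = 0},
#' \eqn{a_e = b_e = \sqrt{width^2 + height^2}/8}; \eqn{\phi^0} comes
#' from the adaptive saliency contour unless \code{initial} supplies a
#' mask.
#'
#' @param image Numeric matrix in [0, 255].
#' @param config A [lifo_config()].
#' @param initial Optional {0,1} initial mask; when omitted the
#'   adaptive saliency initialisation is used.
#' @param init_ellipse Optional [ellipse_params()] overriding the
#'   default prior initialisation.
#' @return A \code{lifo_result}: \code{mask} (final {0,1}
#'   segmentation, \eqn{H(\phi) \ge 0.5}), \code{phi}, \code{ellipse},
#'   \code{n_iterations}, \code{energy_trace} (one row per iteration:
#'   \code{e_lif}, \code{e_smooth}, \code{e_ellipse}, \code{e_total},
#'   \code{changed}), \code{converged}, \code{initial_mask}.
#' @export
lifo_segment <- function(image, config = lifo_config(), initial = NULL,
                         init_ellipse = NULL) {
  check_gray_image(image)
  I <- image / config$intensity_scale
  nr <- nrow(image); nc <- ncol(image)

  if (is.null(initial)) {
    init <- make_initial_contour(image, config)
    mask0 <- init$mask
    phi <- init$phi
  } else {
    check_binary_mask(initial, "initial")
    if (!all(dim(initial) == dim(image)))
      stop("`initial` mask must match the image shape", call. = FALSE)
    if (sum(initial) == 0)
      stop("`initial` mask is empty", call. = FALSE)
    mask0 <- initial
    phi <- mask_to_levelset(initial)
  }

  ellipse <- if (!is.null(init_ellipse)) {
    stopifnot(inherits(init_ellipse, "ellipse_params"))
    init_ellipse
  } else {
    r0 <- sqrt(nc^2 + nr^2) / 8
    ellipse_params(x_e = nc / 2, y_e = nr / 2, theta_e = 0,
                   a_e = r0, b_e = r0)
  }

  trace <- matrix(NA_real_, config$max_outer_iter, 5,
                  dimnames = list(NULL, c("e_lif", "e_smooth", "e_ellipse",
                                          "e_total", "changed")))
  n_it <- 0L
  converged <- FALSE
  for (l in seq_len(config$max_outer_iter)) {
    if (config$alpha > 0) {
      ellipse <- fit_ellipse_to_levelset(
        phi, ellipse, alpha = config$alpha, eps = config$eps,
        eps_e = config$eps_e,
        step_sizes = config$ellipse_step_sizes,
        max_iter = config$ellipse_max_iter, tol = config$ellipse_tol)
    }
    step <- evolve_step(I, phi, ellipse, config)
    changed <- mean((step$phi >= 0) != (phi >= 0))
    # energy of the state entering this iteration, from the same
    # decomposition the step used
    e_lif <- lif_energy(I, step$fit)
    e_smooth <- config$nu * sum(dirac(phi, config$eps) * grad_mag(phi))
    e_ell <- if (config$alpha > 0)
      ellipse_energy(phi, ellipse, config$alpha, config$eps, config$eps_e) else 0
    trace[l, ] <- c(e_lif, e_smooth, e_ell, e_lif + e_smooth + e_ell, changed)
    phi <- step$phi
    n_it <- l
    if (sum(phi >= 0) == 0)
      stop("contour collapsed to an empty region; try a larger initial ",
           "contour or a smaller nu", call. = FALSE)
    W <- config$stationary_iters
    if (l >= W && mean(trace[(l - W + 1L):l, "changed"]) < config$phi_tol) {
      converged <- TRUE
      break
    }
  }

  mask <- (phi >= 0) + 0
  structure(list(mask = mask, phi = phi, ellipse = ellipse,
                 n_iterations = n_it,
                 energy_trace = trace[seq_len(n_it), , drop = FALSE],
                 converged = converged, initial_mask = mask0,
                 config = config),
            class = "lifo_result")
}

#' @export
print.lifo_result <- function(x, ...) {
  cat("LIFO segmentation result\n")
  cat(sprintf("  grid: %d x %d px, area: %d px\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  cat(sprintf("  iterations: %d (%s)\n", x$n_iterations,
              if (x$converged) "stationary" else "iteration cap reached"))
  e <- x$ellipse
  cat(sprintf("  prior ellipse: center (%.1f, %.1f), axes (%.1f, %.1f), theta %.3f rad\n",
              e$x_e, e$y_e, e$a_e, e$b_e, e$theta_e))
  invisible(x)
}
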