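# Deterministic generator of fundus-like test images with known ground
# truth. The fixtures emulate the structures that make optic-disc
# segmentation hard: a bright, approximately elliptical disc on a
# darker background, dark curvilinear vessels crossing the disc
# boundary, smooth multiplicative intensity inhomogeneity, an optional
# bright peripapillary-atrophy-like ring abutting the disc, blur and
# noise. The ground-truth mask is the rasterisation of the same
# quadratic ellipse level set the shape prior uses, so metrics are
# consistent across modules.

#' Specify a synthetic fundus-like fixture
#'
#' @param shape Grid dimensions \code{c(height, width)}.
#' @param disc True disc geometry, an [ellipse_params()].
#' @param disc_intensity,background_intensity Intensities in [0, 255];
#'   the disc must be brighter.
#' @param n_vessels Number of dark vessel tracks crossing the disc.
#' @param vessel_width Vessel thickness (px).
#' @param vessel_intensity Vessel intensity (darker than the disc).
#' @param inhomogeneity_amplitude Relative amplitude in [0, 1) of the
#'   smooth multiplicative illumination field.
#' @param ppa_ring \code{NULL}, or a list with \code{outer_scale}
#'   (> 1, mean outer boundary of the ring as a scale of the disc
#'   axes), \code{intensity} (between background and disc) and
#'   optional \code{arc} (angular extent in radians, length 2,
#'   relative to the disc orientation; default a temporal crescent).
#'   Real peripapillary atrophy is ragged and mottled, so the rendered
#'   ring has an angularly varying outer border (random low-order
#'   harmonics, up to 20\% of \code{outer_scale}) and smooth
#'   multiplicative texture.
#' @param blur_sigma Gaussian blur sigma (px; 0 disables).
#' @param noise_sigma Additive Gaussian noise sd (intensity units).
#' @param seed Integer seed; generation is deterministic per seed.
#' @return A \code{fixture_spec} list.
#' @export
fixture_spec <- function(shape = c(200, 200),
                         disc = ellipse_params(99.5, 99.5, 0, 30, 24),
                         disc_intensity = 200, background_intensity = 80,
                         n_vessels = 0, vessel_width = 4,
                         vessel_intensity = 40,
                         inhomogeneity_amplitude = 0,
                         ppa_ring = NULL, blur_sigma = 0, noise_sigma = 0,
                         seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 32),
            inherits(disc, "ellipse_params"))
  if (disc_intensity <= background_intensity)
    stop("disc must be brighter than the background", call. = FALSE)
  if (n_vessels > 0 && vessel_intensity >= disc_intensity)
    stop("vessels must be darker than the disc", call. = FALSE)
  if (inhomogeneity_amplitude < 0 || inhomogeneity_amplitude >= 1)
    stop("`inhomogeneity_amplitude` must be in [0, 1)", call. = FALSE)
  outer <- if (is.null(ppa_ring)) 1 else ppa_ring$outer_scale * 1.25
  a <- disc$a_e * outer; b <- disc$b_e * outer
  ext <- max(a, b)
  if (disc$x_e - ext < 0 || disc$x_e + ext > shape[2L] - 1 ||
      disc$y_e - ext < 0 || disc$y_e + ext > shape[1L] - 1)
    stop("disc (and ring) geometry must lie inside the grid", call. = FALSE)
  if (!is.null(ppa_ring)) {
    stopifnot(ppa_ring$outer_scale > 1,
              ppa_ring$intensity > background_intensity,
              ppa_ring$intensity < disc_intensity)
    if (is.null(ppa_ring$arc)) ppa_ring$arc <- c(-0.45 * pi, 0.45 * pi)
  }
  structure(list(shape = as.integer(shape), disc = disc,
                 disc_intensity = disc_intensity,
                 background_intensity = background_intensity,
                 n_vessels = as.integer(n_vessels),
                 vessel_width = vessel_width,
                 vessel_intensity = vessel_intensity,
                 inhomogeneity_amplitude = inhomogeneity_amplitude,
                 ppa_ring = ppa_ring, blur_sigma = blur_sigma,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "fixture_spec")
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic fixture
#'
#' Renders the image described by a [fixture_spec()] and returns it
#' together with the exact ground truth. The true mask is
#' \eqn{\{\phi_e > 0\}} for the true ellipse, taken before vessels,
#' ring, blur and noise are applied.
#'
#' @param spec A [fixture_spec()].
#' @return List with \code{image} (matrix in [0, 255]), \code{mask}
#'   (true {0,1} disc mask), \code{ellipse} (true [ellipse_params()]),
#'   and \code{spec}.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    nr <- spec$shape[1L]; nc <- spec$shape[2L]
    phi_e <- ellipse_levelset(spec$disc, spec$shape)
    truth <- (phi_e > 0) + 0

    # anti-aliased disc edge: approximate signed distance phi_e/|grad|
    d <- phi_e / pmax(grad_mag(phi_e), 1e-8)
    cov <- pmin(pmax(d + 0.5, 0), 1)
    img <- spec$background_intensity +
      (spec$disc_intensity - spec$background_intensity) * cov

    if (!is.null(spec$ppa_ring)) {
      x <- matrix(rep(0:(nc - 1L), each = nr), nr, nc)
      y <- matrix(rep(0:(nr - 1L), times = nc), nr, nc)
      ct <- cos(spec$disc$theta_e); st <- sin(spec$disc$theta_e)
      dx <- x - spec$disc$x_e; dy <- y - spec$disc$y_e
      u <- dx * ct + dy * st; v <- -dx * st + dy * ct
      rho <- sqrt(u^2 / spec$disc$a_e^2 + v^2 / spec$disc$b_e^2)
      ang <- atan2(v, u)
      # ragged outer border: low-order angular harmonics
      ph <- stats::runif(3, 0, 2 * pi)
      amp <- stats::runif(2, 0.04, 0.1)
      s_out <- spec$ppa_ring$outer_scale *
        (1 + amp[1L] * sin(2 * ang + ph[1L]) + amp[2L] * sin(5 * ang + ph[2L]))
      s_out <- pmin(s_out, spec$ppa_ring$outer_scale * 1.25)
      ring <- rho > 1 & rho < s_out &
        ang >= spec$ppa_ring$arc[1L] & ang <= spec$ppa_ring$arc[2L]
      # mottled texture: smoothed multiplicative noise
      tex <- matrix(stats::rnorm(nr * nc), nr, nc)
      tex <- EBImage::gblur(tex, sigma = 3)
      tex <- tex / max(stats::sd(tex), 1e-8) * 0.2
      lvl <- spec$ppa_ring$intensity * (1 + tex[ring])
      img[ring] <- pmin(pmax(lvl, spec$background_intensity + 20),
                        spec$disc_intensity - 10)
    }

    if (spec$n_vessels > 0) {
      vm <- vessel_mask(spec, nr, nc)
      img[vm] <- spec$vessel_intensity
    }

    if (spec$inhomogeneity_amplitude > 0) {
      x <- matrix(rep(0:(nc - 1L), each = nr), nr, nc)
      y <- matrix(rep(0:(nr - 1L), times = nc), nr, nc)
      phx <- stats::runif(1, 0, pi); phy <- stats::runif(1, 0, pi)
      field <- 1 + spec$inhomogeneity_amplitude *
        sin(pi * x / (nc - 1) + phx) * sin(pi * y / (nr - 1) + phy)
      img <- img * field
    }

    if (spec$blur_sigma > 0) {
      img <- EBImage::gblur(img, sigma = spec$blur_sigma)
      img <- matrix(as.numeric(img), nr, nc)
    }
    if (spec$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sigma), nr, nc)
    }
    img <- pmin(pmax(img, 0), 255)
    list(image = img, mask = truth, ellipse = spec$disc, spec = spec)
  })
}

# dark curvilinear tracks: straight border-to-border chords through the
# disc-centre region, bent by a smoothed random lateral perturbation
vessel_mask <- function(spec, nr, nc) {
  vm <- matrix(FALSE, nr, nc)
  half <- spec$vessel_width / 2
  off <- expand.grid(dr = -ceiling(half):ceiling(half),
                     dc = -ceiling(half):ceiling(half))
  off <- off[off$dr^2 + off$dc^2 <= half^2 + 0.25, ]
  for (v in seq_len(spec$n_vessels)) {
    theta <- stats::runif(1, 0, pi)
    jitter <- stats::runif(2, -0.2, 0.2) * c(spec$disc$a_e, spec$disc$b_e)
    cx <- spec$disc$x_e + jitter[1L]
    cy <- spec$disc$y_e + jitter[2L]
    # chord through (cx, cy) at angle theta, long enough to cross the grid
    L <- sqrt(nr^2 + nc^2)
    t <- seq(-L / 2, L / 2, by = 0.5)
    lat <- stats::rnorm(length(t), 0, 1)
    k <- 25L
    lat <- stats::filter(cumsum(lat), rep(1 / k, k), sides = 2)
    lat[is.na(lat)] <- 0
    lat <- lat / max(abs(lat), 1e-8) * stats::runif(1, 2, 6)
    px <- cx + t * cos(theta) - lat * sin(theta)
    py <- cy + t * sin(theta) + lat * cos(theta)
    keep <- px >= 0 & px <= nc - 1 & py >= 0 & py <= nr - 1
    px <- px[keep]; py <- py[keep]
    if (length(px) == 0L) next
    r <- round(py) + 1L; c <- round(px) + 1L
    rr <- rep(r, each = nrow(off)) + off$dr
    cc <- rep(c, each = nrow(off)) + off$dc
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    vm[cbind(rr[ok], cc[ok])] <- TRUE
  }
  vm
}

#' Generate a reproducible suite of fixtures
#'
#' Draws \code{n} fixtures with randomised disc geometry (semi-axes
#' uniform in [0.12, 0.22] of the smaller grid dimension, axis ratio at
#' most 1.5, rotation uniform, centre jittered around the grid centre)
#' and difficulty-specific overlays. Difficulties are cumulative:
#' \describe{
#'   \item{clean}{mild inhomogeneity, light blur and noise, no
#'     vessels or ring;}
#'   \item{vessels}{adds 3 dark vessels of width 4 px crossing the
#'     disc;}
#'   \item{ppa}{adds a bright crescent abutting the disc;}
#'   \item{blurry}{increases blur and noise.}
#' }
#'
#' @param n Number of fixtures (>= 1).
#' @param difficulty One of \code{"clean"}, \code{"vessels"},
#'   \code{"ppa"}, \code{"blurry"}.
#' @param seed Integer seed; regeneration with the same arguments is
#'   identical.
#' @param shape Grid dimensions.
#' @return List of \code{n} fixtures as returned by
#'   [generate_fixture()].
#' @export
fixture_suite <- function(n, difficulty = c("clean", "vessels", "ppa", "blurry"),
                          seed = 1L, shape = c(200, 200)) {
  stopifnot(n >= 1)
  difficulty <- match.arg(difficulty)
  level <- match(difficulty, c("clean", "vessels", "ppa", "blurry"))
  smin <- min(shape)
  with_seed(seed, {
    seeds <- sample.int(2^31 - 2, n)
    specs <- vector("list", n)
    for (i in seq_len(n)) {
      b <- stats::runif(1, 0.12, 0.22) * smin
      a <- min(b * stats::runif(1, 1, 1.5), 0.22 * smin)
      th <- stats::runif(1, -pi / 2 + 1e-6, pi / 2)
      cx <- (shape[2L] - 1) / 2 + stats::runif(1, -8, 8)
      cy <- (shape[1L] - 1) / 2 + stats::runif(1, -8, 8)
      ring <- if (level >= 3) {
        side <- sample(c(-1, 1), 1)
        list(outer_scale = stats::runif(1, 1.3, 1.5), intensity = 150,
             arc = sort(side * c(0.1 * pi, 0.8 * pi)))
      } else NULL
      specs[[i]] <- fixture_spec(
        shape = shape,
        disc = ellipse_params(cx, cy, th, a, b),
        disc_intensity = 200, background_intensity = 80,
        n_vessels = if (level >= 2) 3L else 0L,
        vessel_width = 4, vessel_intensity = 40,
        inhomogeneity_amplitude = 0.1,
        ppa_ring = ring,
        blur_sigma = if (level >= 4) 2.5 else 1,
        noise_sigma = if (level >= 4) 5 else 2,
        seed = seeds[i])
    }
    lapply(specs, generate_fixture)
  })
}
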