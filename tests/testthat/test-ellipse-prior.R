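test_that("the ellipse level set has its stated analytic structure", {
  e <- ellipse_params(12.25, 9.5, 0.4, 7, 5)
  # value 1 exactly at the centre (evaluate off-grid analytically)
  phi_at <- function(x, y, p) {
    u <- (x - p$x_e) * cos(p$theta_e) + (y - p$y_e) * sin(p$theta_e)
    v <- -(x - p$x_e) * sin(p$theta_e) + (y - p$y_e) * cos(p$theta_e)
    1 - u^2 / p$a_e^2 - v^2 / p$b_e^2
  }
  expect_equal(phi_at(e$x_e, e$y_e, e), 1)
  # zero on the boundary point centre + a_e along the major axis
  expect_equal(phi_at(e$x_e + e$a_e * cos(e$theta_e),
                      e$y_e + e$a_e * sin(e$theta_e), e), 0,
               tolerance = 1e-12)
  # grid maximum at most 1, attained near the centre
  phi <- ellipse_levelset(e, c(24, 24))
  expect_lte(max(phi), 1)
  expect_error(ellipse_params(5, 5, 0, -1, 2), "positive")
})

test_that("quarter-turn with swapped axes reproduces the same level set", {
  dim <- c(30, 30)
  a <- ellipse_levelset(ellipse_params(14, 15, pi / 2, 8, 5), dim)
  b <- ellipse_levelset(ellipse_params(14, 15, 0, 5, 8), dim)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("the positive set of phi_e is exactly the open ellipse interior", {
  e <- ellipse_params(15, 16, 0.7, 9, 6)
  g <- lifoseg:::coord_grids(c(32, 32))
  u <- (g$x - e$x_e) * cos(e$theta_e) + (g$y - e$y_e) * sin(e$theta_e)
  v <- -(g$x - e$x_e) * sin(e$theta_e) + (g$y - e$y_e) * cos(e$theta_e)
  inside <- u^2 / e$a_e^2 + v^2 / e$b_e^2 < 1
  expect_identical(ellipse_levelset(e, c(32, 32)) > 0, inside)
})

test_that("prior energy: matched shapes, arc-length, and alpha linearity", {
  e <- ellipse_params(20, 20, 0, 9, 9)
  phi_e <- ellipse_levelset(e, c(40, 40))
  # matched footprints with nu = 0 (same regularisation width both sides)
  expect_equal(prior_energy(phi_e, e, nu = 0, alpha = 1,
                            eps = 0.05, eps_e = 0.05), 0)
  # arc-length term on a signed-distance circle approximates nu * 2 pi r
  r <- 14
  phi <- sdf_disc(c(64, 64), 31.5, 31.5, r)
  nu <- 3
  e0 <- ellipse_params(31.5, 31.5, 0, r, r)
  len <- prior_energy(phi, e0, nu = nu, alpha = 0)
  expect_equal(len, nu * 2 * pi * r, tolerance = 0.05 * nu * 2 * pi * r)
  # doubling alpha doubles the mismatch term exactly
  phi2 <- sdf_disc(c(40, 40), 17, 22, 7)
  t1 <- prior_energy(phi2, e, nu = 0, alpha = 1)
  t2 <- prior_energy(phi2, e, nu = 0, alpha = 2)
  expect_equal(t2, 2 * t1)
})

test_that("analytic ellipse gradients vanish at stationary/symmetric points", {
  e <- ellipse_params(16, 15, 0.3, 8, 5)
  phi_e <- ellipse_levelset(e, c(32, 32))
  g <- ellipse_gradients(phi_e, e, eps = 0.05, alpha = 1, eps_e = 0.05)
  expect_equal(unname(g), rep(0, 5))
  # circle: rotation gradient identically zero
  ec <- ellipse_params(16, 16, 0.2, 7, 7)
  phi <- sdf_disc(c(32, 32), 14, 17, 8)
  gc <- ellipse_gradients(phi, ec)
  expect_equal(unname(gc["theta_e"]), 0)
})

test_that("analytic gradients match central differences of the mismatch energy", {
  set.seed(21)
  for (rep in 1:6) {
    n <- sample(24:32, 1)
    phi <- sdf_disc(c(n, n), runif(1, n / 3, 2 * n / 3),
                    runif(1, n / 3, 2 * n / 3), runif(1, n / 6, n / 3))
    e <- ellipse_params(runif(1, n / 3, 2 * n / 3), runif(1, n / 3, 2 * n / 3),
                        runif(1, -1, 1), runif(1, 4, n / 3), runif(1, 3, n / 4))
    g <- ellipse_gradients(phi, e)
    h <- 1e-4
    p0 <- c(e$x_e, e$y_e, e$theta_e, e$a_e, e$b_e)
    for (k in 1:5) {
      en <- function(pp) {
        pe <- ellipse_params(pp[1], pp[2], pp[3], pp[4], pp[5])
        lifoseg:::ellipse_energy(phi, pe, alpha = 1, eps = 1, eps_e = 0.05)
      }
      pp <- p0; pp[k] <- pp[k] + h; up <- en(pp)
      pp <- p0; pp[k] <- pp[k] - h; dn <- en(pp)
      fd <- (up - dn) / (2 * h)
      tol <- 1e-3 * max(abs(g[k]), abs(fd), 1e-6)
      expect_equal(unname(g[k]), fd, tolerance = tol)
    }
  }
})

test_that("gradient descent recovers ellipse parameters from footprints", {
  # already-optimal init stays put
  e <- ellipse_params(20, 22, 0, 9, 7)
  phi_e <- ellipse_levelset(e, c(44, 44))
  fit0 <- fit_ellipse_to_levelset(phi_e, e, eps = 0.05)
  expect_lt(abs(fit0$x_e - e$x_e), 0.05)
  expect_lt(abs(fit0$a_e - e$a_e), 0.05)
  # signed-distance disc radius 20 at (50, 50) from a mis-set circle
  phi <- sdf_disc(c(100, 100), 50, 50, 20)
  fit <- fit_ellipse_to_levelset(phi, ellipse_params(40, 40, 0, 10, 10))
  expect_lt(abs(fit$x_e - 50), 1)
  expect_lt(abs(fit$y_e - 50), 1)
  expect_lt(abs(fit$a_e - 20), 1.5)
  expect_lt(abs(fit$b_e - 20), 1.5)
  # axis-aligned 30 x 20 ellipse: orientation recovered modulo pi
  e2 <- ellipse_params(50, 50, 0, 30, 20)
  phi2 <- lifoseg:::mask_to_levelset(ellipse_mask(e2, c(100, 100)))
  fit2 <- fit_ellipse_to_levelset(phi2, ellipse_params(45, 47, 0.3, 22, 21))
  th <- fit2$theta_e %% pi
  expect_lt(min(th, pi - th), 0.1)
})

test_that("ellipse fitting is translation-equivariant on interior shapes", {
  base <- ellipse_mask(ellipse_params(40, 42, 0.5, 12, 8), c(96, 96))
  shifted <- matrix(0, 96, 96)
  shifted[(1 + 5):96, (1 + 7):96] <- base[1:(96 - 5), 1:(96 - 7)]
  f1 <- fit_ellipse_to_levelset(lifoseg:::mask_to_levelset(base),
                                ellipse_params(37, 40, 0.3, 10, 10))
  f2 <- fit_ellipse_to_levelset(lifoseg:::mask_to_levelset(shifted),
                                ellipse_params(37 + 7, 40 + 5, 0.3, 10, 10))
  # the quadratic level set's regularised delta has polynomial tails, so
  # image-border contributions break exact equivariance; on shapes well
  # inside the grid the recovered centre still shifts with the field to
  # a few hundred-thousandths of a pixel
  expect_equal(f2$x_e - f1$x_e, 7, tolerance = 1e-4)
  expect_equal(f2$y_e - f1$y_e, 5, tolerance = 1e-4)
  expect_equal(f2$a_e, f1$a_e, tolerance = 1e-4)
})

test_that("angle wrapping and axis clamping keep parameters in range", {
  e <- ellipse_params(5, 5, pi / 2 + 0.2, 4, 3)
  expect_true(e$theta_e > -pi / 2 && e$theta_e <= pi / 2)
  e2 <- ellipse_params(5, 5, 0, 0.1, 3)
  expect_gte(e2$a_e, 0.5)
})
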