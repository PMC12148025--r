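test_that("Gaussian disc fraction matches quadrature and is monotone", {
  # independent oracle: midpoint quadrature of the unit 2D Gaussian
  quad_fraction <- function(r) {
    h <- 0.01
    g <- seq(-6 + h / 2, 6 - h / 2, by = h)
    d2 <- outer(g^2, g^2, "+")
    z <- exp(-d2 / 2) / (2 * pi) * h^2
    sum(z[d2 <= r^2])
  }
  for (r in c(0.5, 1, 2, 3)) {
    expect_equal(gaussian_disc_fraction(r), quad_fraction(r), tolerance = 1e-3)
  }
  expect_equal(gaussian_disc_fraction(2), 1 - exp(-2), tolerance = 1e-15)
  expect_equal(gaussian_disc_fraction(0), 0)
  expect_equal(gaussian_disc_fraction(1), 1 - exp(-0.5), tolerance = 1e-12)
  r <- seq(0, 6, by = 0.1)
  expect_true(all(diff(gaussian_disc_fraction(r)) > 0))
  expect_equal(gaussian_disc_fraction(50), 1, tolerance = 1e-12)
  expect_error(gaussian_disc_fraction(-1))
})

test_that("spot fit recovers noiseless ground truth to solver tolerance", {
  sp <- render_single_spot(20.3, 17.8, photons_per_frame = 500 * 2 * pi *
                             psf_sigma_px(confocal_optics())^2)
  sig <- psf_sigma_px(sp$optics)
  ft <- fit_spot(sp$image, c(20, 18), window = 10, psf_sigma = sig,
                 pixel_size = 27)
  expect_equal(ft$status, "ok")
  expect_lt(abs(ft$x0 - 20.3), 0.01)
  expect_lt(abs(ft$y0 - 17.8), 0.01)
  expect_lt(abs(ft$sigma_x / sig - 1), 0.005)
  expect_lt(abs(ft$sigma_y / sig - 1), 0.005)
  expect_lt(abs(ft$amplitude / 500 - 1), 0.005)
  expect_equal(ft$fwhm_nm, 200, tolerance = 0.005)
})

test_that("uniform images are rejected as degenerate, not errors", {
  img <- matrix(120, 41, 41)
  ft <- fit_spot(img, c(20, 20), window = 8)
  expect_equal(ft$status, "rejected_degenerate")
  expect_equal(ft$amplitude, 0)
})

test_that("a constant background shifts only the fitted offset", {
  sp <- render_single_spot(30.4, 29.6)
  sig <- psf_sigma_px(sp$optics)
  f0 <- fit_spot(sp$image, c(30, 30), 10, psf_sigma = sig)
  f1 <- fit_spot(sp$image + 200, c(30, 30), 10, psf_sigma = sig)
  expect_equal(f1$x0, f0$x0, tolerance = 1e-6)
  expect_equal(f1$y0, f0$y0, tolerance = 1e-6)
  expect_equal(f1$sigma_x, f0$sigma_x, tolerance = 1e-6)
  expect_equal(f1$amplitude, f0$amplitude, tolerance = 1e-6)
  expect_equal(f1$offset - f0$offset, 200, tolerance = 1e-6)
})

test_that("least-squares optimum agrees with a dense grid-search oracle", {
  # brute-force oracle: grid over (x0, y0, sigma) at 0.05 px / 0.05 sigma,
  # amplitude and offset solved linearly at each grid point
  set.seed(31)
  optics <- confocal_optics(n_blur_substeps = 1L)
  sig <- psf_sigma_px(optics)
  for (rep in 1:5) {
    x <- 30 + runif(1, -0.5, 0.5)
    y <- 30 + runif(1, -0.5, 0.5)
    sp <- render_single_spot(x, y, optics = optics)
    ft <- fit_spot(sp$image, c(30, 30), 10, psf_sigma = sig)
    ix <- 20:40; iy <- 20:40
    sub <- sp$image[iy + 1, ix + 1]
    sse <- function(x0, y0, s) {
      gx <- (pnorm((ix + 0.5 - x0) / s) - pnorm((ix - 0.5 - x0) / s)) *
        s * sqrt(2 * pi)
      gy <- (pnorm((iy + 0.5 - y0) / s) - pnorm((iy - 0.5 - y0) / s)) *
        s * sqrt(2 * pi)
      shape <- as.vector(outer(gy, gx))
      co <- stats::lm.fit(cbind(1, shape), as.vector(sub))
      sum(co$residuals^2)
    }
    grid_x <- seq(x - 0.25, x + 0.25, by = 0.05)
    grid_y <- seq(y - 0.25, y + 0.25, by = 0.05)
    grid_s <- sig * seq(0.9, 1.1, by = 0.05)
    best <- list(sse = Inf)
    for (gx_ in grid_x) for (gy_ in grid_y) for (gs_ in grid_s) {
      v <- sse(gx_, gy_, gs_)
      if (v < best$sse) best <- list(sse = v, x = gx_, y = gy_, s = gs_)
    }
    # optimizer must be at least as good as the grid and at the same optimum
    expect_lte(sse(ft$x0, ft$y0, sqrt(ft$sigma_x * ft$sigma_y)),
               best$sse + 1e-9)
    expect_lt(abs(ft$x0 - best$x), 0.05)
    expect_lt(abs(ft$y0 - best$y), 0.05)
    expect_lt(abs(sqrt(ft$sigma_x * ft$sigma_y) - best$s), 0.05 * sig)
  }
})

test_that("disc integration captures ~86% and is background-invariant", {
  sp <- render_single_spot(31.7, 30.2)
  sig <- psf_sigma_px(sp$optics)
  ft <- fit_spot(sp$image, c(32, 30), 10, psf_sigma = sig)
  ft <- integrate_cage_intensity(sp$image, ft)
  expect_lt(abs(ft$integrated_intensity / (0.8646647 * sp$photons) - 1), 0.02)
  expect_false(ft$partial_disc)
  # adding a uniform constant and refitting leaves the result unchanged
  f2 <- fit_spot(sp$image + 300, c(32, 30), 10, psf_sigma = sig)
  f2 <- integrate_cage_intensity(sp$image + 300, f2)
  expect_lt(abs(f2$integrated_intensity / ft$integrated_intensity - 1), 0.001)
  # doubling the amplitude doubles the integral
  f3 <- fit_spot(sp$image * 2, c(32, 30), 10, psf_sigma = sig)
  f3 <- integrate_cage_intensity(sp$image * 2, f3)
  expect_equal(f3$integrated_intensity / ft$integrated_intensity, 2,
               tolerance = 1e-6)
})

test_that("disc integration flags partial discs and rejects missing discs", {
  sp <- render_single_spot(4, 30)   # near the left edge
  ft <- fit_spot(sp$image, c(4, 30), 8, psf_sigma = psf_sigma_px(sp$optics))
  ft <- integrate_cage_intensity(sp$image, ft)
  expect_true(ft$partial_disc)
  ft$x0 <- -50
  expect_error(integrate_cage_intensity(sp$image, ft), "outside")
  bad <- ft; bad$status <- "failed"
  expect_error(integrate_cage_intensity(sp$image, bad), "status")
})

test_that("QC keeps in-band spots and rejects blurred or aggregate fits", {
  optics <- confocal_optics()   # expected sigma ~ 3.15 px
  mk <- function(sx, sy) {
    f <- fit_spot(render_single_spot(30, 30)$image, c(30, 30), 10,
                  psf_sigma = psf_sigma_px(optics))
    f$sigma_x <- sx; f$sigma_y <- sy
    f
  }
  expect_equal(qc_filter(mk(3.0, 3.1), optics)$status, "ok")
  expect_equal(qc_filter(mk(3.0, 3.0 * 1.5), optics)$status, "rejected_blur")
  expect_equal(qc_filter(mk(9.4, 9.4), optics)$status, "rejected_blur")
  expect_equal(qc_filter(mk(1.5, 1.5), optics)$status, "rejected_blur")
})

test_that("motion during the exposure elongates the fit beyond the QC gate", {
  # particle translating during a long exposure: rendered with substep
  # stamping, the blur adds variance along x only
  optics <- confocal_optics(n_blur_substeps = 20L)
  cage <- cage_spec(60, 50, Inf)
  tr <- simulate_tracks(motion_spec(0, c(64, 64)), 1L, 1L, optics, seed = 4)
  tr$pos[1, 1, , 1] <- seq(26, 38, length.out = 20)  # 12 px drift
  tr$pos[1, 1, , 2] <- 30
  r <- render_stack(simulation_scene(tr, cage, noiseless_camera()),
                    noise = FALSE)
  ft <- fit_spot(r$stack[, , 1], c(32, 30), 14,
                 psf_sigma = psf_sigma_px(optics))
  expect_gt(ft$sigma_x / ft$sigma_y, 1.3)
  expect_equal(qc_filter(ft, optics)$status, "rejected_blur")
})

test_that("cage count estimate follows the 0.86 disc correction", {
  expect_equal(estimate_cage_count(1000, 10), 86)
  expect_equal(estimate_cage_count(10, 10), 0.86)
  expect_error(estimate_cage_count(1000, 0))
  expect_error(estimate_cage_count(1000, -5))
})

test_that("quantify_spots drives fit, QC and integration over a seed table", {
  optics <- confocal_optics(n_blur_substeps = 1L)
  cage <- cage_spec(60, 50, Inf)
  tr <- simulate_tracks(motion_spec(0, c(96, 96)), 3L, 3L, optics, seed = 8)
  tr$pos[, , , 1] <- array(rep(c(20, 48, 76), 9), dim = c(3, 3, 1))
  tr$pos[, , , 2] <- 48
  r <- render_stack(simulation_scene(tr, cage, noiseless_camera()),
                    noise = FALSE)
  seeds <- data.frame(cell_id = "c1", x_px = c(20, 48, 76), y_px = 48)
  spots <- quantify_spots(r$stack, seeds, optics)
  expect_equal(nrow(spots), 3L)
  expect_true(all(spots$status == "ok"))
  expect_lt(max(abs(spots$intensity_counts / (0.8646647 * 1500) - 1)), 0.02)
  cs <- cell_summary(spots, c(c1 = sum(r$stack[, , 1])))
  expect_equal(cs$n_spots, 3L)
  expect_equal(cs$estimated_cage_count,
               sum(r$stack[, , 1]) / mean(spots$intensity_counts) * 0.86)
})
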