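test_that("core width reduces to the reference width and obeys quadrature", {
  b <- demo_beam()
  expect_equal(sigma_core(b, b$z0_mm), b$sigma0_mm, tolerance = 1e-12)

  # 3-4-5 identity at the end of range with no divergence
  b345 <- beam_spec("345", 100, 200, 20, sigma0_mm = 4, theta0_rad = 0,
                    mcs_scale_mm = 3, mcs_exponent = 1, halo_slope_b = 0.15)
  expect_equal(sigma_core(b345, 200), 5)

  expect_error(sigma_core(b, b$z0_mm - 1), "outside")
  expect_error(sigma_core(b, b$range_r80_mm + 1), "outside")
})

test_that("core width growth is monotone for parametric and anchored beams", {
  withr::with_seed(7, {
    for (i in 1:10) {
      b <- beam_spec("rand", 150, 200, 15, sigma0_mm = runif(1, 2, 9),
                     theta0_rad = runif(1, 0, 0.02),
                     mcs_scale_mm = runif(1, 0, 8),
                     mcs_exponent = runif(1, 0, 2.5), halo_slope_b = 0.15)
      z <- seq(15, 200, length.out = 60)
      expect_true(all(diff(sigma_core(b, z)) >= -1e-12))
    }
  })
  for (b in fixture_beams()) {
    z <- seq(b$z0_mm, b$range_r80_mm, length.out = 60)
    expect_true(all(diff(sigma_core(b, z)) >= -1e-12))
  }
})

test_that("anchored fixtures reproduce their measured widths exactly", {
  beams <- fixture_beams()
  for (b in beams) {
    anchors <- b$sigma_anchors
    if (is.null(anchors)) next
    expect_equal(sigma_core(b, anchors$z_mm), anchors$sigma_mm,
                 tolerance = 0.01 / max(anchors$sigma_mm))
  }
  # deep anchor of the mid-energy anchored beam
  b148 <- beams$open_148
  expect_lt(abs(sigma_core(b148, 0.97 * b148$range_r80_mm) - 5.96), 0.01)
})

test_that("radial dose is CAX-normalized, continuous, and joins at 2.5 sigma", {
  b <- demo_beam()
  z_mid <- 0.5 * b$range_r80_mm  # unit halo amplitude at midrange
  expect_identical(pb_radial_dose(b, z_mid, 0), 1)

  sig <- sigma_core(b, z_mid)
  expect_equal(pb_radial_dose(b, z_mid, 2.5 * sig), exp(-3.125),
               tolerance = 1e-10)

  # continuity in r for amplitudes below and above unity
  for (beam in list(b, demo_beam(halo_peak = 2, halo_floor = 0.8))) {
    r <- seq(0, 12 * sig, by = 0.01)
    d <- pb_radial_dose(beam, z_mid, r)
    expect_true(all(d > 0 & d <= 1))
    expect_lt(max(abs(diff(d))), 0.01)  # no jumps on a 0.01 mm grid
  }
})

test_that("fixture halo reach matches the calibrated 0.1% radii", {
  beams <- fixture_beams()
  for (spec in list(list(beam = beams$open_252, ratio = 10),
                    list(beam = beams$open_148, ratio = 7))) {
    b <- spec$beam
    z_mid <- 0.5 * b$range_r80_mm
    sig <- sigma_core(b, z_mid)
    r001 <- stats::uniroot(function(r) pb_radial_dose(b, z_mid, r) - 0.001,
                           c(2.5 * sig, 30 * sig))$root
    expect_equal(r001 / sig, spec$ratio, tolerance = 0.02)
  }
})

test_that("detector averaging bounds, convergence, and flat-field limit", {
  # near-flat field: gigantic core, halo off
  flat <- gaussian_beam(sigma0 = 1e5)
  det <- detector_spec("Semiflex", 2.75)
  expect_equal(detector_average(flat, 20, c(0, 0), det), 1, tolerance = 1e-8)

  b <- gaussian_beam(sigma0 = 5)
  v <- detector_average(b, 20, c(0, 0), det)
  expect_lt(v, 1)
  expect_gt(v, exp(-2.75^2 / 50))

  # small-disc average converges to the point value
  tiny <- detector_spec("tiny", 0.1, 0.05)
  pt <- point_detector()
  withr::with_seed(11, {
    for (x in runif(10, -15, 15)) {
      expect_equal(detector_average(b, 20, c(x, 0), tiny),
                   detector_average(b, 20, c(x, 0), pt),
                   tolerance = 1e-3)
    }
  })

  expect_equal(detector_average(b, 20, c(0, 0), det,
                                spots = tibble::tibble(x_mm = numeric(),
                                                       y_mm = numeric())),
               0)
})

test_that("scan profiles are deterministic, symmetric, and carry the noise", {
  b <- gaussian_beam(sigma0 = 5)
  pos <- seq(-20, 20, by = 1)
  det <- point_detector()

  p0 <- scan_profile(b, 20, det, pos)
  expect_equal(p0$dose, exp(-pos^2 / 50), tolerance = 1e-12)
  expect_equal(p0$dose, rev(p0$dose))  # symmetry about the axis

  p1 <- scan_profile(b, 20, det, pos, noise_sd_rel = 0.006, seed = 42)
  p2 <- scan_profile(b, 20, det, pos, noise_sd_rel = 0.006, seed = 42)
  expect_identical(p1$dose, p2$dose)
  expect_false(identical(p0$dose, p1$dose))
  expect_error(scan_profile(b, 20, det, pos, noise_sd_rel = -0.1), ">= 0")

  # per-point relative SD over many realizations matches the noise level
  doses <- vapply(1:1000, function(s) {
    scan_profile(b, 20, det, c(-5, 0, 5), noise_sd_rel = 0.006,
                 seed = s)$dose
  }, numeric(3))
  rel_sd <- apply(doses, 1, sd) / apply(doses, 1, mean)
  expect_true(all(abs(rel_sd / 0.006 - 1) < 0.1))
})

test_that("annular scoring matches closed forms and conserves energy", {
  b <- gaussian_beam(sigma0 = 5)
  z <- 20

  # flat dose: every annulus reports the constant
  flat <- gaussian_beam(sigma0 = 1e5)
  pf <- annular_profile(flat, z, seq(0, 20, by = 2.5))
  expect_equal(pf$dose, rep(1, 8), tolerance = 1e-8)

  # Gaussian annulus mean on [0, ro]: (2 sigma^2 / ro^2) (1 - exp(-ro^2/2s^2))
  pg <- annular_profile(b, z, c(0, 2.5))
  closed <- (2 * 25 / 2.5^2) * (1 - exp(-2.5^2 / 50))
  expect_equal(pg$dose[1], closed, tolerance = 1e-3)

  # energy conservation under 4x refinement of every annulus
  edges <- seq(0, 60, by = 2.5)
  fine <- seq(0, 60, by = 0.625)
  for (beam in list(b, demo_beam())) {
    coarse_p <- annular_profile(beam, z, edges)
    fine_p <- annular_profile(beam, z, fine)
    area <- function(e) pi * diff(e^2)
    e_coarse <- sum(coarse_p$dose * area(edges))
    e_fine <- sum(fine_p$dose * area(fine))
    expect_equal(e_coarse, e_fine, tolerance = 1e-4)
  }

  expect_error(annular_profile(b, z, c(0, 5, 5)), "increasing")
})

test_that("profiles round-trip through CSV + JSON sidecar", {
  b <- demo_beam()
  p <- scan_profile(b, 76.6, detector_spec("Semiflex", 2.75),
                    seq(-10, 10, 2), offset_mu_mm = 0.3,
                    noise_sd_rel = 0.006, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile(p, path)
  q <- read_profile(path)
  expect_equal(q$position_mm, p$position_mm)
  expect_equal(q$dose, p$dose)
  expect_identical(attr(q, "geometry"), "linear")
  expect_equal(attr(q, "depth_z_mm"), 76.6)
  expect_equal(attr(q, "offset_true_mm"), 0.3)
  expect_equal(attr(q, "detector")$r_cav_mm, 2.75)
})
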