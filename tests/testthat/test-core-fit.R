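test_that("a noiseless pure Gaussian is recovered to machine precision", {
  t <- seq(-30, 30, by = 0.5)
  p <- lateral_profile(t, exp(-t^2 / 50), depth_z_mm = 20)
  fit <- fit_core(p)
  expect_equal(fit$sigma_c, 5, tolerance = 1e-6 / 5)
  expect_equal(fit$mu, 0, tolerance = 1e-8)
  expect_true(fit$converged)
  expect_gte(fit$n_points_used, 4)
})

test_that("the 2.5 sigma window rejects the halo bias", {
  # generative core width equal to the mid-energy reference-depth value
  p <- core_plus_tail_profile(sigma = 4.53, b = 0.2)
  fit <- fit_core(p)
  expect_equal(fit$sigma_c, 4.53, tolerance = 0.005)

  # tail amplitude at the junction up to 25% of the local Gaussian value:
  # bias stays below 0.5% (single-pass fits would not manage this)
  for (amp in c(0.5, 1, 1.25)) {
    t <- seq(-40, 40, by = 0.5)
    r <- abs(t)
    sig <- 5
    a <- amp * exp(-3.125 + 0.15 * 2.5 * sig)
    dose <- pmax(exp(-r^2 / (2 * sig^2)),
                 (r > 2.5 * sig) * a * exp(-0.15 * r))
    fit <- fit_core(lateral_profile(t, dose, 20))
    expect_lt(abs(fit$sigma_c - sig) / sig, 0.005)
  }
})

test_that("the fit is translation-equivariant and scale-invariant", {
  b <- demo_beam()
  det <- point_detector()
  pos <- seq(-40, 40, by = 0.5)
  p0 <- scan_profile(b, 76.6, det, pos)
  p_shift <- scan_profile(b, 76.6, det, pos, offset_mu_mm = 0.6)
  f0 <- fit_core(p0)
  fs <- fit_core(p_shift)
  expect_equal(fs$mu, 0.6, tolerance = 0.01 / 0.6)
  expect_equal(fs$sigma_c, f0$sigma_c, tolerance = 1e-3)

  p_scaled <- lateral_profile(p0$position_mm, p0$dose * 137, 76.6)
  fsc <- fit_core(p_scaled)
  expect_equal(fsc$sigma_c, f0$sigma_c, tolerance = 1e-9)
  expect_equal(fsc$amplitude, f0$amplitude * 137, tolerance = 1e-6)
})

test_that("annular profiles are fitted with the peak fixed on the axis", {
  b <- demo_beam()
  p <- annular_profile(b, 76.6, seq(0, 40, by = 1))
  fit <- fit_core(p)
  expect_identical(fit$mu, 0)
  expect_equal(fit$sigma_c, sigma_core(b, 76.6), tolerance = 0.02)
})

test_that("too few usable points raise a fit error", {
  p <- lateral_profile(c(-1, 0, 1), c(0.1, 1, 0.1), 20)
  expect_error(fit_core(p), "fewer than 4")
})

test_that("tidy and glance expose the fit as tibbles", {
  t <- seq(-30, 30, by = 0.5)
  fit <- fit_core(lateral_profile(t, exp(-t^2 / 50), depth_z_mm = 42))
  td <- tidy(fit)
  expect_identical(td$term, c("amplitude", "mu", "sigma_c"))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$depth_z_mm, 42)
  expect_true(gl$converged)
})

test_that("sigma_sc implements the quadrature growth transform", {
  expect_identical(sigma_sc(4, 4), 0)
  expect_equal(sigma_sc(5, 4), 3)
  # direct evaluation on the printed mid-energy widths
  expect_equal(sigma_sc(5.96, 4.53), 3.873, tolerance = 1e-3)
  expect_error(sigma_sc(3.9, 4), "radicand")
})

test_that("sigma_sc is independent of the initial beam width", {
  det <- point_detector()
  depths <- c(20, 76.6, 122.56, 148.6)
  curves <- lapply(c(4, 9), function(s0) {
    beam <- demo_beam(sigma0 = s0)
    profiles <- lapply(depths, function(z) {
      scan_profile(beam, z, det, seq(-60, 60, by = 0.5))
    })
    sigma_sc_curve(profiles)
  })
  expect_equal(curves[[1]]$sigma_sc[1], 0)
  ratio <- curves[[2]]$sigma_sc[-1] / curves[[1]]$sigma_sc[-1]
  expect_true(all(abs(ratio - 1) < 0.005))
})

test_that("the fitted growth curve matches the generator closed form", {
  beam <- demo_beam()
  det <- point_detector()
  depths <- c(20, 76.6, 122.56, 148.6)
  profiles <- lapply(depths, function(z) {
    scan_profile(beam, z, det, seq(-45, 45, by = 0.5))
  })
  curve <- sigma_sc_curve(profiles)
  truth <- sqrt(sigma_core(beam, depths)^2 - beam$sigma0_mm^2)
  expect_equal(curve$sigma_sc, truth, tolerance = 0.005)

  single <- sigma_sc_curve(profiles[1])
  expect_identical(nrow(single), 1L)
  expect_equal(single$sigma_sc, 0)
})
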