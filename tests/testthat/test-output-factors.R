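make_meas <- function(dose, unc = NULL) {
  out <- tibble::tibble(frame = 1:9, dose = dose)
  if (!is.null(unc)) out$dose_unc <- unc
  out
}

test_that("frame factors normalize to the 10 cm field", {
  ff <- frame_factors(make_meas(rep(1, 9)))
  expect_equal(ff$ff, rep(1 / 7, 9))

  point <- frame_factors(make_meas(c(1, rep(0, 8))))
  expect_equal(point$ff, c(1, rep(0, 8)))

  withr::with_seed(3, {
    for (i in 1:5) {
      d <- runif(9, 0.01, 5)
      tab <- of_table(make_meas(d))
      expect_equal(sum(tab$ff[1:7]), 1, tolerance = 1e-14)
      expect_identical(tab$fsf[7], 1)  # exact by construction
      expect_equal(diff(tab$fsf), tab$ff[-1], tolerance = 1e-12)
      expect_true(all(diff(tab$fsf) >= 0))
    }
  })
})

test_that("field-size factors cumulate and can exceed unity", {
  tab <- field_size_factors(make_meas(rep(2, 9)))
  expect_equal(tab$fsf, (1:9) / 7)

  closed <- field_size_factors(make_meas(c(runif(7, 1, 2), 0, 0)))
  expect_equal(closed$fsf[8], 1)
  expect_equal(closed$fsf[9], 1)

  halo <- field_size_factors(make_meas(c(5, 1, 0.5, 0.3, 0.2, 0.1, 0.1,
                                         0.05, 0.02)))
  expect_gt(halo$fsf[9], 1)
})

test_that("inputs are validated", {
  expect_error(of_table(make_meas(rep(1, 9))[-3, ]), "nine frames")
  expect_error(of_table(make_meas(c(-1, rep(1, 8)))), ">= 0")
  expect_error(of_table(make_meas(c(rep(0, 7), 1, 1))), "> 0")
})

test_that("FSF uncertainty collapses correctly in analytic limits", {
  zero <- fsf_uncertainty(make_meas(runif(9, 1, 2), unc = rep(0, 9)))
  expect_equal(zero$dfsf, rep(0, 9))

  # only frame 9 uncertain: frame 9 is outside D_N, so dFSF_9 = dD_9 / D_N
  d <- c(2, 1, 1, 1, 1, 1, 1, 0.5, 0.4)
  unc <- c(rep(0, 8), 0.05)
  tab <- fsf_uncertainty(make_meas(d, unc))
  expect_equal(tab$dfsf, c(rep(0, 8), 0.05 / sum(d[1:7])), tolerance = 1e-12)
})

test_that("uncertainty propagation agrees with a resampling oracle", {
  d <- c(60, 12, 6, 4, 3, 2, 2, 1.5, 1)
  unc <- 0.01 * d
  tab <- fsf_uncertainty(make_meas(d, unc))
  n <- 1e5
  sims <- withr::with_seed(123, {
    draws <- matrix(rnorm(9 * n, d, unc), nrow = 9)
    dn <- colSums(draws[1:7, ])
    apply(apply(draws, 2, cumsum) / rep(dn, each = 9), 1, sd)
  })
  # frame 7 FSF is pinned at 1 (fully correlated ratio); the formula ignores
  # that correlation by design, so compare where the numerator is not D_N
  for (i in c(1:4, 8:9)) {
    expect_equal(tab$dfsf[i], sims[i], tolerance = 0.05)
  }
})

test_that("output factors are invariant under common dose rescaling", {
  d <- c(60, 12, 6, 4, 3, 2, 2, 1.5, 1)
  unc <- 0.01 * d
  a <- of_table(make_meas(d, unc))
  b <- of_table(make_meas(d * 17, unc * 17))
  expect_equal(a$ff, b$ff, tolerance = 1e-12)
  expect_equal(a$fsf, b$fsf, tolerance = 1e-12)
  expect_equal(a$dfsf, b$dfsf, tolerance = 1e-12)
  expect_equal(rmsd_fsf(a, b), 0, tolerance = 1e-12)
})

test_that("RMSD matches brute force, is symmetric, and zero iff identical", {
  withr::with_seed(17, {
    fa <- of_table(make_meas(runif(9, 0.5, 5)))
    fb <- of_table(make_meas(runif(9, 0.5, 5)))
  })
  brute <- sqrt(sum((fa$fsf[3:9] - fb$fsf[3:9])^2) / 7)
  expect_equal(rmsd_fsf(fa, fb), brute, tolerance = 1e-12)
  expect_equal(rmsd_fsf(fa, fb), rmsd_fsf(fb, fa))
  expect_identical(rmsd_fsf(fa, fa), 0)

  # constant FSF offset of delta gives RMSD = delta exactly
  shifted <- dplyr::mutate(tibble::as_tibble(fa), fsf = fsf + 0.004)
  expect_equal(rmsd_fsf(fa, shifted), 0.004, tolerance = 1e-12)

  expect_error(rmsd_fsf(fa[fa$frame != 5, ], fb), "missing")
})

test_that("frame-dose tables round-trip through CSV", {
  tab <- make_meas(runif(9, 1, 3), unc = rep(0.01, 9))
  tab$depth_mm <- 76.6
  tab$beam <- "demo"
  path <- withr::local_tempfile(fileext = ".csv")
  write_frame_doses(tab, path)
  back <- read_frame_doses(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
})
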