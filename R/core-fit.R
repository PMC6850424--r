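#' Two-step Gaussian fit of the dose core
#'
#' Fits `A * G(t | mu, sigma^2)` to a lateral profile in two passes designed
#' to keep the non-Gaussian halo out of the core width estimate: the first
#' pass uses only points at or above a dose threshold (default 5% of the
#' profile maximum) to obtain `sigma_init` and the peak offset `mu`; the
#' second pass refits using all points within `window * sigma_init` of `mu`
#' (default 2.5, the radius out to which a proton pencil beam stays
#' Gaussian). Least squares is unweighted; for annular profiles `mu` is fixed
#' at zero and the window is `r <= window * sigma_init`.
#'
#' @param profile A [lateral_profile()].
#' @param threshold First-pass dose threshold relative to the profile maximum
#'   (default 0.05).
#' @param window Second-pass half-width in units of `sigma_init`
#'   (default 2.5).
#' @return An object of class `pb_corefit` with elements `mu`, `sigma_init`,
#'   `sigma_c`, `amplitude`, `window_halfwidth`, `n_points_used`,
#'   `converged`. Use [tidy()][generics::tidy] / [glance()][generics::glance]
#'   for tibble output.
#' @export
#' @examples
#' b <- beam_spec("demo", 148.2, 153.2, 20, 4.53, mcs_scale_mm = 4,
#'                halo_slope_b = 0.17)
#' p <- scan_profile(b, 76.6, detector_spec("point", 0),
#'                   seq(-40, 40, by = 0.5))
#' fit_core(p)
fit_core <- function(profile, threshold = 0.05, window = 2.5) {
  stopifnot(inherits(profile, "pb_profile") || is.data.frame(profile))
  t <- profile$position_mm
  d <- profile$dose
  annular <- profile_geometry(profile) == "annular"
  d_max <- max(d)
  sel <- d >= threshold * d_max
  if (sum(sel) < 4L) {
    stop("fewer than 4 points above the first-pass threshold", call. = FALSE)
  }
  # deterministic initial guesses: peak position (ties broken toward the
  # axis), FWHM / 2.355 by linear interpolation, peak dose
  peak_idx <- which(d == d_max)
  peak_idx <- peak_idx[which.min(abs(t[peak_idx]))]
  mu0 <- if (annular) 0 else t[peak_idx]
  s0 <- interp_fwhm(t, d, annular) / (2 * sqrt(2 * log(2)))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(t[sel])) / 4
  step1 <- gauss_ls(t[sel], d[sel], mu0, s0, d_max, fix_mu = annular)
  sigma_init <- step1$sigma
  win <- window * sigma_init
  sel2 <- if (annular) t <= win else abs(t - step1$mu) <= win
  if (sum(sel2) < 4L) {
    stop("fewer than 4 points inside the refit window", call. = FALSE)
  }
  step2 <- gauss_ls(t[sel2], d[sel2], step1$mu, sigma_init, step1$amplitude,
                    fix_mu = annular)
  structure(
    list(
      mu = step2$mu,
      sigma_init = sigma_init,
      sigma_c = step2$sigma,
      amplitude = step2$amplitude,
      window_halfwidth = win,
      n_points_used = sum(sel2),
      converged = step1$converged && step2$converged,
      geometry = profile_geometry(profile),
      depth_z_mm = attr(profile, "depth_z_mm")
    ),
    class = "pb_corefit"
  )
}

# unweighted Gaussian least squares via Levenberg-Marquardt; robust to a
# zero-residual optimum (noiseless synthetic data)
gauss_ls <- function(t, d, mu0, s0, a0, fix_mu = FALSE) {
  if (fix_mu) {
    fn <- function(p) d - p[1] * exp(-t^2 / (2 * p[2]^2))
    par0 <- c(a0, s0)
  } else {
    fn <- function(p) d - p[1] * exp(-(t - p[2])^2 / (2 * p[3]^2))
    par0 <- c(a0, mu0, s0)
  }
  out <- minpack.lm::nls.lm(par = par0, fn = fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- out$par
  list(
    amplitude = p[1],
    mu = if (fix_mu) 0 else p[2],
    sigma = abs(if (fix_mu) p[2] else p[3]),
    converged = out$info %in% 1:4
  )
}

# FWHM by linear interpolation of the half-maximum crossings
interp_fwhm <- function(t, d, annular = FALSE) {
  half <- max(d) / 2
  cross <- level_crossings(t, d, half)
  if (annular) {
    if (length(cross$right) == 0) return(NA_real_)
    return(2 * max(cross$right))
  }
  if (length(cross$left) == 0 || length(cross$right) == 0) return(NA_real_)
  max(cross$right) - min(cross$left)
}

#' @export
print.pb_corefit <- function(x, ...) {
  cat(sprintf(
    "<pb_corefit> mu = %.3f mm, sigma_init = %.3f mm, sigma_C = %.3f mm\n",
    x$mu, x$sigma_init, x$sigma_c))
  cat(sprintf("  window +/- %.2f mm, %d points, converged: %s\n",
              x$window_halfwidth, x$n_points_used, x$converged))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a two-step core fit
#'
#' @param x A `pb_corefit`.
#' @param ... Unused.
#' @return `tidy()` gives one row per fitted parameter; `glance()` gives a
#'   one-row model summary.
#' @method tidy pb_corefit
#' @export
tidy.pb_corefit <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude", "mu", "sigma_c"),
    estimate = c(x$amplitude, x$mu, x$sigma_c)
  )
}

#' @rdname tidy.pb_corefit
#' @method glance pb_corefit
#' @export
glance.pb_corefit <- function(x, ...) {
  tibble::tibble(
    mu = x$mu, sigma_init = x$sigma_init, sigma_c = x$sigma_c,
    amplitude = x$amplitude, window_halfwidth = x$window_halfwidth,
    n_points_used = x$n_points_used, converged = x$converged,
    depth_z_mm = x$depth_z_mm %||% NA_real_
  )
}

#' Scattering growth of the core width
#'
#' Quadrature growth of the core width relative to the reference depth:
#' \deqn{\sigma_{sc}(z) = \sqrt{\sigma_C^2(z) - \sigma_C^2(z_0)}.}
#' Subtracting the reference width in quadrature removes the initial beam
#' width, isolating the in-phantom scattering and residual divergence.
#'
#' @param sigma_z Core width(s) at depth, mm.
#' @param sigma_z0 Core width at the reference depth, mm (> 0).
#' @return Width growth in mm.
#' @export
#' @examples
#' sigma_sc(5, 4)  # 3
sigma_sc <- function(sigma_z, sigma_z0) {
  stopifnot(length(sigma_z0) == 1L, sigma_z0 > 0)
  if (any(sigma_z < sigma_z0 - 1e-12)) {
    stop("sigma_z < sigma_z0: negative radicand signals a failed fit upstream",
         call. = FALSE)
  }
  sqrt(pmax(sigma_z^2 - sigma_z0^2, 0))
}

#' Scattering-growth curve over depth
#'
#' Fits the core width of each profile with [fit_core()] and transforms the
#' widths to [sigma_sc()] relative to the shallowest profile. The first
#' entry is 0 by construction.
#'
#' @param profiles List of [lateral_profile()]s at increasing depths; the
#'   shallowest is the reference.
#' @param ... Passed to [fit_core()].
#' @return Tibble of class `pb_sc_curve` with columns `depth_z_mm`,
#'   `sigma_c`, `sigma_sc`.
#' @export
sigma_sc_curve <- function(profiles, ...) {
  stopifnot(length(profiles) >= 1)
  fits <- purrr::map(profiles, fit_core, ...)
  out <- tibble::tibble(
    depth_z_mm = purrr::map_dbl(fits, function(f) f$depth_z_mm %||% NA_real_),
    sigma_c = purrr::map_dbl(fits, "sigma_c")
  )
  out <- dplyr::arrange(out, .data$depth_z_mm)
  out$sigma_sc <- sigma_sc(out$sigma_c, out$sigma_c[1])
  class(out) <- c("pb_sc_curve", class(out))
  out
}
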