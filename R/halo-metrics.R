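#' Correct a linear scan for lateral misalignment
#'
#' Shifts the positions of a linear profile by the peak offset `mu` obtained
#' from the two-step Gaussian core fit, so the fitted peak sits at zero.
#' Annular profiles are returned unchanged (their axis is fixed by
#' construction).
#'
#' @param profile A [lateral_profile()].
#' @param ... Passed to [fit_core()].
#' @return The offset-corrected profile.
#' @export
correct_offset <- function(profile, ...) {
  if (profile_geometry(profile) == "annular") return(profile)
  fit <- fit_core(profile, ...)
  out <- profile
  out$position_mm <- profile$position_mm - fit$mu
  attr(out, "offset_applied_mm") <- fit$mu
  out
}

# linearly interpolated crossings of a dose level, split by side of the peak
level_crossings <- function(t, d, level) {
  above <- d >= level
  idx <- which(above[-length(above)] != above[-1])
  if (length(idx) == 0) return(list(left = numeric(), right = numeric()))
  x <- t[idx] + (level - d[idx]) * (t[idx + 1] - t[idx]) / (d[idx + 1] - d[idx])
  rising <- !above[idx]  # crossing upward (left flank)
  list(left = x[rising], right = x[!rising])
}

#' Full width at a fraction of the maximum
#'
#' Extracts the FWxM of an offset-corrected lateral profile. Levels of 1% of
#' the maximum and higher are taken from the outermost linearly interpolated
#' crossings of `x * max(dose)` on each side; lower levels (deep in the halo,
#' where the profile decays exponentially) come from a linear-exponential fit
#' `a * exp(-b |t|)` to all points with dose within +/-50% of the desired
#' level, fitted per side by linear least squares on the log dose and solved
#' for the crossing radius. Annular profiles use a single fit and double the
#' radius.
#'
#' @param profile A [lateral_profile()], offset-corrected for linear scans.
#' @param level Fraction of the maximum in (0, 1), e.g. 0.5 for the FWHM.
#' @return Width in mm. The fitted tail parameters, where used, are attached
#'   as attribute `tail_fit`.
#' @export
#' @examples
#' t <- seq(-30, 30, 0.25)
#' p <- lateral_profile(t, exp(-t^2 / 50), 100)
#' fwxm(p, 0.5)  # 2 sqrt(2 ln 2) * 5
fwxm <- function(profile, level) {
  stopifnot(level > 0, level < 1)
  t <- profile$position_mm
  d <- profile$dose
  annular <- profile_geometry(profile) == "annular"
  target <- level * max(d)
  if (level >= 0.01) {
    cross <- level_crossings(t, d, target)
    if (annular) {
      if (length(cross$right) == 0) {
        stop(sprintf("level %.3g not reached", level), call. = FALSE)
      }
      return(2 * max(cross$right))
    }
    if (length(cross$left) == 0 || length(cross$right) == 0) {
      stop(sprintf("level %.3g not reached on both sides", level),
           call. = FALSE)
    }
    return(max(cross$right) - min(cross$left))
  }
  # tail-fit levels: a exp(-b |t|) on points with dose in [0.5, 1.5] x level
  band <- d >= 0.5 * target & d <= 1.5 * target & d > 0
  solve_side <- function(keep, side) {
    if (sum(keep) < 3L) {
      stop(sprintf("fewer than 3 points in the %s tail band at level %.3g",
                   side, level), call. = FALSE)
    }
    fit <- stats::lm(log(d[keep]) ~ abs(t[keep]))
    b <- -stats::coef(fit)[[2]]
    a <- exp(stats::coef(fit)[[1]])
    if (b <= 0) {
      stop(sprintf("%s tail is not decaying at level %.3g", side, level),
           call. = FALSE)
    }
    list(r = log(a / target) / b, a = a, b = b)
  }
  if (annular) {
    s <- solve_side(band, "annular")
    return(structure(2 * s$r, tail_fit = tibble::tibble(
      side = "annular", a = s$a, b = s$b)))
  }
  left <- solve_side(band & t < 0, "left")
  right <- solve_side(band & t > 0, "right")
  structure(left$r + right$r, tail_fit = tibble::tibble(
    side = c("left", "right"), a = c(left$a, right$a), b = c(left$b, right$b)))
}

#' Halo width set of a profile
#'
#' Maps [fwxm()] over the standard level set (50%, 1%, 0.1%, 0.05% of the
#' maximum) after offset correction, recording which extraction method each
#' level used.
#'
#' @param profile A [lateral_profile()].
#' @param levels Fractions of the maximum (default
#'   `c(0.5, 0.01, 0.001, 0.0005)`).
#' @param correct Apply [correct_offset()] to linear scans first
#'   (default TRUE).
#' @return Tibble with columns `level`, `width_mm`, `method`.
#' @export
halo_widths <- function(profile, levels = c(0.5, 0.01, 0.001, 0.0005),
                        correct = TRUE) {
  if (correct && profile_geometry(profile) == "linear") {
    profile <- correct_offset(profile)
  }
  tibble::tibble(
    level = levels,
    width_mm = purrr::map_dbl(levels, function(x) as.numeric(fwxm(profile, x))),
    method = ifelse(levels >= 0.01, "interpolation", "tail_fit")
  )
}

#' Reproducibility confidence interval of repeated dose readings
#'
#' Combines the relative standard deviation of repeated readings with an
#' assumed day-to-day absolute dose delivery reproducibility (default 0.6%)
#' in quadrature, giving a 1-sigma relative confidence interval.
#'
#' @param rep_doses Numeric vector of repeated dose readings (>= 2).
#' @param day_to_day_rel Relative day-to-day reproducibility (default 0.006).
#' @return Relative 1-sigma confidence interval (dimensionless).
#' @export
#' @examples
#' ci_reproducibility(c(1, 1, 1))  # 0.006: only the day-to-day term remains
ci_reproducibility <- function(rep_doses, day_to_day_rel = 0.006) {
  if (length(rep_doses) < 2L) {
    stop("at least 2 repetitions are required", call. = FALSE)
  }
  rel_sd <- stats::sd(rep_doses) / mean(rep_doses)
  sqrt(rel_sd^2 + day_to_day_rel^2)
}
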