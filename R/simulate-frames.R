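#' Simulate frame-dose measurements of a beam
#'
#' Generates the per-frame central-axis doses of the nine-frame field
#' decomposition by superposing the full pencil-beam dose model (core plus
#' halo) of every spot of each frame over the detector's sensitive disc.
#' Optionally repeats the measurement with multiplicative noise and collapses
#' the repetitions into a mean dose and a reproducibility uncertainty (see
#' [ci_reproducibility()]).
#'
#' @inheritParams detector_average
#' @param frames Frame table (default [standard_frames()]).
#' @param spacing_mm Spot grid spacing in mm (default 2).
#' @param noise_sd_rel Relative SD of multiplicative noise per repetition
#'   (0 = noiseless).
#' @param n_rep Number of repeated readings (default 1; use 3 to emulate
#'   triplicate measurements).
#' @param seed Integer seed for the noise (default 1234).
#' @param averaging_step_mm Sub-grid step for the detector disc when scoring
#'   frames (default 0.5 mm; frame doses vary slowly over the disc, so a
#'   coarser grid than for profile scans suffices).
#' @return Tibble with columns `frame`, `dose`, `dose_unc`, `depth_mm`,
#'   `beam`.
#' @export
simulate_frame_doses <- function(beam, z_mm,
                                 detector = detector_spec("Semiflex", 2.75),
                                 frames = standard_frames(),
                                 spacing_mm = 2,
                                 noise_sd_rel = 0,
                                 n_rep = 1L,
                                 seed = 1234L,
                                 averaging_step_mm = 0.5) {
  step <- if (detector$r_cav_mm > 0) {
    min(averaging_step_mm, detector$r_cav_mm)
  } else {
    averaging_step_mm
  }
  det <- detector_spec(detector$name, detector$r_cav_mm, step)
  bins <- detector_bins(det)
  spots <- frame_spots(frames, spacing_mm)
  dose_of <- function(sx, sy) {
    d <- sqrt(outer(sx, bins[, 1], "-")^2 + outer(sy, bins[, 2], "-")^2)
    sum(pb_radial_dose(beam, z_mm, as.vector(d))) / nrow(bins)
  }
  true <- spots |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(dose = dose_of(.data$x_mm, .data$y_mm)) |>
    dplyr::ungroup()
  if (noise_sd_rel > 0 && n_rep >= 2L) {
    reps <- withr::with_seed(seed, {
      matrix(stats::rnorm(nrow(true) * n_rep, 1, noise_sd_rel),
             nrow = nrow(true))
    })
    reps <- pmax(reps, 0) * true$dose
    true$dose_unc <- apply(reps, 1, ci_reproducibility) * rowMeans(reps)
    true$dose <- rowMeans(reps)
  } else if (noise_sd_rel > 0) {
    eps <- withr::with_seed(seed, stats::rnorm(nrow(true), 0, noise_sd_rel))
    true$dose <- true$dose * pmax(1 + eps, 0)
    true$dose_unc <- 0.006 * true$dose
  } else {
    true$dose_unc <- 0
  }
  true$depth_mm <- z_mm
  true$beam <- beam$label
  true
}
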