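#' Construct a lateral dose profile
#'
#' A lateral profile is a tibble with columns `position_mm` and `dose`
#' carrying metadata attributes: the depth, the scan geometry (`"linear"`
#' signed scans across the axis, `"annular"` radial profiles), the detector,
#' and — for generated profiles — the true misalignment and noise level so
#' tests can check recovery.
#'
#' @param position_mm Strictly increasing lateral positions (signed mm for
#'   linear scans, radii >= 0 for annular profiles).
#' @param dose Non-negative dose values (arbitrary units), same length.
#' @param depth_z_mm Depth of the scan plane in mm.
#' @param geometry `"linear"` or `"annular"`.
#' @param detector Optional [detector_spec()].
#' @param annulus_edges_mm Optional annulus edge radii (annular only).
#' @param offset_true_mm Generator-side lateral misalignment (linear only).
#' @param noise_sd_rel Relative SD of the multiplicative noise applied.
#' @param beam_label Optional label of the generating beam.
#' @return A tibble of class `pb_profile`.
#' @export
lateral_profile <- function(position_mm, dose, depth_z_mm,
                            geometry = c("linear", "annular"),
                            detector = NULL, annulus_edges_mm = NULL,
                            offset_true_mm = 0, noise_sd_rel = 0,
                            beam_label = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(length(position_mm) == length(dose),
            all(dose >= 0), !is.unsorted(position_mm, strictly = TRUE))
  if (geometry == "annular" && any(position_mm < 0)) {
    stop("annular profiles need non-negative radii", call. = FALSE)
  }
  out <- tibble::tibble(position_mm = as.numeric(position_mm),
                        dose = as.numeric(dose))
  structure(
    out,
    class = c("pb_profile", class(out)),
    depth_z_mm = depth_z_mm,
    geometry = geometry,
    detector = detector,
    annulus_edges_mm = annulus_edges_mm,
    offset_true_mm = offset_true_mm,
    noise_sd_rel = noise_sd_rel,
    beam_label = beam_label
  )
}

profile_geometry <- function(profile) attr(profile, "geometry") %||% "linear"

#' @export
print.pb_profile <- function(x, ...) {
  cat(sprintf("<pb_profile> %s scan, depth %.1f mm, %d points%s\n",
              profile_geometry(x), attr(x, "depth_z_mm") %||% NA_real_,
              nrow(x),
              if (!is.null(attr(x, "beam_label"))) {
                paste0(", beam ", attr(x, "beam_label"))
              } else ""))
  NextMethod()
}

# bin centers of the averaging sub-grid inside the detector disc
detector_bins <- function(detector) {
  r <- detector$r_cav_mm
  if (r == 0) return(cbind(x = 0, y = 0))
  step <- detector$averaging_step_mm
  n <- ceiling(r / step)
  k <- seq(-n * step + step / 2, n * step - step / 2, by = step)
  g <- expand.grid(x = k, y = k)
  g <- g[g$x^2 + g$y^2 < r^2, , drop = FALSE]
  as.matrix(g)
}

#' Volume-averaged dose of a superposed field
#'
#' Mean dose over a detector's sensitive disc centered at `center_mm`, for a
#' field composed of pencil beams at the given spot positions. The disc is
#' subdivided into a square sub-grid (default 0.1 mm) and the superposed
#' radial dose model is averaged over the bin centers that fall inside the
#' disc; a zero-radius detector returns the point dose.
#'
#' @inheritParams sigma_core
#' @param center_mm Numeric length-2, detector center (x, y) in mm.
#' @param detector A [detector_spec()].
#' @param spots Data frame of spot coordinates with columns `x_mm`, `y_mm`
#'   (default: a single pencil beam on the axis). An empty spot map gives
#'   zero dose.
#' @return Mean relative dose over the disc.
#' @export
#' @examples
#' b <- beam_spec("demo", 148.2, 153.2, 20, 4.53, mcs_scale_mm = 4,
#'                halo_slope_b = 0.17)
#' detector_average(b, 76.6, c(0, 0), detector_spec("Semiflex", 2.75))
detector_average <- function(beam, z_mm, center_mm, detector,
                             spots = tibble::tibble(x_mm = 0, y_mm = 0)) {
  stopifnot(inherits(detector, "pb_detector"), length(center_mm) == 2L)
  if (nrow(spots) == 0L) return(0)
  bins <- detector_bins(detector)
  bx <- bins[, 1] + center_mm[1]
  by <- bins[, 2] + center_mm[2]
  d <- sqrt(outer(spots$x_mm, bx, "-")^2 + outer(spots$y_mm, by, "-")^2)
  dose <- pb_radial_dose(beam, z_mm, as.vector(d))
  sum(dose) / length(bx)
}

#' Simulate a linear detector scan
#'
#' Emulates moving a detector across a single pencil beam at constant depth:
#' the volume-averaged dose is evaluated at each scan position relative to a
#' (possibly misaligned) beam axis and perturbed by multiplicative Gaussian
#' noise emulating day-to-day dose delivery reproducibility. The noise factor
#' is truncated at zero so doses stay non-negative.
#'
#' @inheritParams detector_average
#' @param positions_mm Scan positions (signed mm), strictly increasing.
#' @param offset_mu_mm True lateral misalignment of the beam axis in mm; the
#'   generated peak appears at `+offset_mu_mm`.
#' @param noise_sd_rel Relative standard deviation of the multiplicative
#'   noise (0.006 emulates 0.6% reproducibility); must be >= 0.
#' @param seed Integer seed making the noise reproducible (default 1234).
#' @return A [lateral_profile()] with geometry `"linear"`; `offset_true_mm`
#'   records the misalignment.
#' @export
scan_profile <- function(beam, z_mm, detector, positions_mm,
                         offset_mu_mm = 0, noise_sd_rel = 0, seed = 1234L) {
  stopifnot(length(positions_mm) > 0)
  if (noise_sd_rel < 0) stop("noise_sd_rel must be >= 0", call. = FALSE)
  dose <- purrr::map_dbl(
    positions_mm,
    function(t) detector_average(beam, z_mm, c(t - offset_mu_mm, 0), detector)
  )
  if (noise_sd_rel > 0) {
    eps <- withr::with_seed(seed, stats::rnorm(length(dose), 0, noise_sd_rel))
    dose <- dose * pmax(1 + eps, 0)
  }
  lateral_profile(positions_mm, dose, depth_z_mm = z_mm, geometry = "linear",
                  detector = detector, offset_true_mm = offset_mu_mm,
                  noise_sd_rel = noise_sd_rel, beam_label = beam$label)
}

#' Score an annular (radial) dose profile
#'
#' Emulates a cylindrical scoring grid: per annulus `[r_i, r_o]` the
#' area-weighted mean dose
#' \deqn{\bar D = \int_{r_i}^{r_o} 2 \pi r D(r)\, dr \; / \; \pi (r_o^2 - r_i^2)}
#' is computed by numerical integration of the radial dose model, and the
#' profile position is reported at the annulus mid-radius. Annuli of 2.5 mm
#' width emulate the side length of a square with the same area as a typical
#' thimble-chamber cross-section.
#'
#' @inheritParams sigma_core
#' @param r_edges_mm Strictly increasing annulus edge radii starting at 0, mm.
#' @return A [lateral_profile()] with geometry `"annular"`.
#' @export
#' @examples
#' b <- beam_spec("demo", 148.2, 153.2, 20, 4.53, mcs_scale_mm = 4,
#'                halo_slope_b = 0.17)
#' annular_profile(b, 76.6, seq(0, 50, by = 2.5))
annular_profile <- function(beam, z_mm, r_edges_mm) {
  if (is.unsorted(r_edges_mm, strictly = TRUE)) {
    stop("r_edges_mm must be strictly increasing", call. = FALSE)
  }
  stopifnot(r_edges_mm[1] == 0, length(r_edges_mm) >= 2)
  ri <- utils::head(r_edges_mm, -1)
  ro <- utils::tail(r_edges_mm, -1)
  mean_dose <- purrr::map2_dbl(ri, ro, function(a, b) {
    stats::integrate(function(r) 2 * pi * r * pb_radial_dose(beam, z_mm, r),
                     a, b, rel.tol = 1e-9, abs.tol = 0)$value /
      (pi * (b^2 - a^2))
  })
  lateral_profile((ri + ro) / 2, mean_dose, depth_z_mm = z_mm,
                  geometry = "annular", annulus_edges_mm = r_edges_mm,
                  beam_label = beam$label)
}

#' Read / write profile files
#'
#' Profiles are stored as a CSV with header `position_mm,dose` next to a JSON
#' sidecar (same path with extension `.json`) holding the metadata: beam
#' label, depth, geometry, detector and noise settings.
#'
#' @param profile A [lateral_profile()].
#' @param path CSV file path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns a `pb_profile`.
#' @export
write_profile <- function(profile, path) {
  readr::write_csv(tibble::as_tibble(profile)[c("position_mm", "dose")], path)
  det <- attr(profile, "detector")
  meta <- list(
    beam_label = attr(profile, "beam_label"),
    depth_z_mm = attr(profile, "depth_z_mm"),
    geometry = profile_geometry(profile),
    detector = if (!is.null(det)) det[c("name", "r_cav_mm", "averaging_step_mm")],
    annulus_edges_mm = attr(profile, "annulus_edges_mm"),
    offset_true_mm = attr(profile, "offset_true_mm"),
    noise_sd_rel = attr(profile, "noise_sd_rel")
  )
  jsonlite::write_json(meta[!purrr::map_lgl(meta, is.null)],
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  meta <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  } else {
    list()
  }
  det <- if (!is.null(meta$detector)) {
    detector_spec(meta$detector$name, meta$detector$r_cav_mm,
                  meta$detector$averaging_step_mm %||% 0.1)
  }
  lateral_profile(
    tab$position_mm, tab$dose,
    depth_z_mm = meta$depth_z_mm %||% NA_real_,
    geometry = meta$geometry %||% "linear",
    detector = det,
    annulus_edges_mm = meta$annulus_edges_mm,
    offset_true_mm = meta$offset_true_mm %||% 0,
    noise_sd_rel = meta$noise_sd_rel %||% 0,
    beam_label = meta$beam_label
  )
}
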