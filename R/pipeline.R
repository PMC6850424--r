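#' Pipeline run configuration
#'
#' Bundles everything an end-to-end characterization run needs: which beams
#' to analyze, at which depths, with which detector, which analyses to run
#' and where to write the artifacts. Depths may be given as the string
#' `"z0"` (the beam's reference depth) or as fractions of the beam range in
#' (0, 1]; absolute depths in mm are also accepted (values > 1).
#'
#' @param beams Named list of [beam_spec()] objects (e.g. a subset of
#'   [beam_library()]).
#' @param depths Vector mixing `"z0"` and numeric relative depths, default
#'   `c("z0", 0.5, 0.8, 0.97)`.
#' @param detector A [detector_spec()] for profile scans.
#' @param analyses Subset of `c("core", "halo", "of", "core_fsf")`.
#' @param seed Integer seed governing all generated noise (default 1234).
#' @param output_dir Directory for the report bundle.
#' @param noise_sd_rel Noise level of the "measured-like" dataset
#'   (default 0.006).
#' @param mc_sigma_scale Relative core-width perturbation of the "MC-like"
#'   dataset used for the RMSD comparison (default 0.95, i.e. a 5%
#'   narrower core emulating an underestimated entrance width).
#' @return An object of class `pb_run_config`.
#' @export
run_config <- function(beams,
                       depths = c("z0", 0.5, 0.8, 0.97),
                       detector = detector_library()$MicroDiamond,
                       analyses = c("core", "halo", "of", "core_fsf"),
                       seed = 1234L,
                       output_dir = tempfile("pbfield-run-"),
                       noise_sd_rel = 0.006,
                       mc_sigma_scale = 0.95) {
  stopifnot(length(beams) >= 1,
            all(purrr::map_lgl(beams, inherits, "pb_beam")),
            inherits(detector, "pb_detector"))
  analyses <- match.arg(analyses, c("core", "halo", "of", "core_fsf"),
                        several.ok = TRUE)
  num <- suppressWarnings(as.numeric(setdiff(depths, "z0")))
  if (anyNA(num) || any(num <= 0)) {
    stop("depths must be \"z0\", fractions of R80 in (0, 1], or mm",
         call. = FALSE)
  }
  if (is.null(names(beams)) || any(names(beams) == "")) {
    names(beams) <- purrr::map_chr(beams, "label")
  }
  structure(
    list(beams = beams, depths = depths, detector = detector,
         analyses = analyses, seed = as.integer(seed),
         output_dir = output_dir, noise_sd_rel = noise_sd_rel,
         mc_sigma_scale = mc_sigma_scale),
    class = "pb_run_config"
  )
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors [run_config()]: `beams` (names from the packaged
#' [beam_library()] or a `beam_file` path), `depths`, `detector` (a name
#' from [detector_library()]), `analyses`, `seed`, `output_dir`,
#' `noise_sd_rel`, `mc_sigma_scale`.
#'
#' @param path YAML file path.
#' @return A `pb_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lib <- beam_library(cfg$beam_file)
  missing <- setdiff(cfg$beams, names(lib))
  if (length(missing) > 0) {
    stop("unknown beams in config: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  det <- detector_library()[[cfg$detector %||% "MicroDiamond"]]
  if (is.null(det)) stop("unknown detector: ", cfg$detector, call. = FALSE)
  run_config(
    beams = lib[cfg$beams],
    depths = cfg$depths %||% c("z0", 0.5, 0.8, 0.97),
    detector = det,
    analyses = cfg$analyses %||% c("core", "halo", "of", "core_fsf"),
    seed = cfg$seed %||% 1234L,
    output_dir = cfg$output_dir %||% tempfile("pbfield-run-"),
    noise_sd_rel = cfg$noise_sd_rel %||% 0.006,
    mc_sigma_scale = cfg$mc_sigma_scale %||% 0.95
  )
}

resolve_depths <- function(beam, depths) {
  purrr::map_dbl(depths, function(d) {
    if (identical(d, "z0")) return(beam$z0_mm)
    d <- as.numeric(d)
    if (d <= 1) d * beam$range_r80_mm else d
  })
}

scan_positions <- function(beam, z_mm, reach_sigma = 11, step_mm = 0.5) {
  half <- ceiling(reach_sigma * sigma_core(beam, z_mm))
  seq(-half, half, by = step_mm)
}

#' Run the end-to-end characterization pipeline
#'
#' For every configured beam, generates the synthetic datasets and runs the
#' requested analyses, writing one CSV per beam and analysis plus a JSON run
#' log (effective configuration, seed, package version, output digest) into
#' the output directory:
#' \describe{
#'   \item{core}{`<beam>_core.csv` — fitted core widths per depth (a
#'     core-width table) and `<beam>_sigma_sc.csv` — the scattering-growth
#'     curve.}
#'   \item{halo}{`<beam>_halo.csv` — FWxM width sets per depth.}
#'   \item{of}{`<beam>_of.csv` — output-factor tables per depth for the
#'     noisy "measured-like" and the width-perturbed noiseless "MC-like"
#'     dataset, and `<beam>_rmsd.csv` — their per-depth RMSD.}
#'   \item{core_fsf}{`<beam>_core_fsf.csv` — analytic core-only FSFs per
#'     depth.}
#' }
#' Any stage failure aborts the run naming the beam and stage.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the effective `config`, per-beam result
#'   tables, and the written `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pb_run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  results <- list()
  emit <- function(tab, name) {
    path <- file.path(config$output_dir, name)
    readr::write_csv(tab, path)
    files[[length(files) + 1]] <<- path
    tab
  }
  stage <- function(beam_name, what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed for beam '%s': %s",
                   what, beam_name, conditionMessage(e)), call. = FALSE)
    })
  }
  for (bn in names(config$beams)) {
    beam <- config$beams[[bn]]
    depths <- resolve_depths(beam, config$depths)
    res <- list()
    profiles <- stage(bn, "profiles", purrr::map(depths, function(z) {
      scan_profile(beam, z, config$detector, scan_positions(beam, z),
                   noise_sd_rel = 0)
    }))
    if ("core" %in% config$analyses) {
      res$core <- stage(bn, "core", {
        fits <- purrr::map(profiles, fit_core)
        tab <- purrr::map_dfr(fits, glance) |>
          dplyr::mutate(beam = beam$label, .before = 1)
        emit(tab, paste0(bn, "_core.csv"))
        curve <- sigma_sc_curve(profiles)
        emit(tibble::as_tibble(curve), paste0(bn, "_sigma_sc.csv"))
        list(widths = tab, sc_curve = curve)
      })
    }
    if ("halo" %in% config$analyses) {
      res$halo <- stage(bn, "halo", {
        tab <- purrr::map2_dfr(profiles, depths, function(p, z) {
          dplyr::mutate(halo_widths(p), depth_mm = z, beam = beam$label)
        })
        emit(tab, paste0(bn, "_halo.csv"))
      })
    }
    if ("of" %in% config$analyses) {
      res$of <- stage(bn, "of", {
        mc_beam <- beam
        mc_beam$sigma0_mm <- beam$sigma0_mm * config$mc_sigma_scale
        if (!is.null(mc_beam$sigma_anchors)) {
          mc_beam$sigma_anchors$sigma_mm <-
            sqrt(pmax(mc_beam$sigma_anchors$sigma_mm^2 +
                        mc_beam$sigma0_mm^2 - beam$sigma0_mm^2, 1e-6))
        }
        per_depth <- purrr::map(depths, function(z) {
          meas <- of_table(simulate_frame_doses(
            beam, z, noise_sd_rel = config$noise_sd_rel, n_rep = 3L,
            seed = config$seed + round(z)))
          mc <- of_table(simulate_frame_doses(mc_beam, z))
          list(meas = meas, mc = mc,
               rmsd = rmsd_fsf(meas, mc))
        })
        tab <- purrr::map_dfr(per_depth, function(x) {
          dplyr::bind_rows(
            dplyr::mutate(tibble::as_tibble(x$meas), dataset = "measured_like"),
            dplyr::mutate(tibble::as_tibble(x$mc), dataset = "mc_like")
          )
        })
        emit(tab, paste0(bn, "_of.csv"))
        rmsd <- tibble::tibble(
          beam = beam$label, depth_mm = depths,
          rmsd = purrr::map_dbl(per_depth, "rmsd")
        )
        emit(rmsd, paste0(bn, "_rmsd.csv"))
        list(tables = tab, rmsd = rmsd)
      })
    }
    if ("core_fsf" %in% config$analyses) {
      res$core_fsf <- stage(bn, "core_fsf", {
        tab <- purrr::map_dfr(depths, function(z) {
          core_only_fsf(core_fsf_config(sigma_core(beam, z))) |>
            dplyr::mutate(depth_mm = z, beam = beam$label)
        })
        emit(tab, paste0(bn, "_core_fsf.csv"))
      })
    }
    results[[bn]] <- res
  }
  log <- list(
    package = "pbfield",
    version = as.character(utils::packageVersion("pbfield")),
    seed = config$seed,
    beams = names(config$beams),
    depths = config$depths,
    detector = config$detector$name,
    analyses = config$analyses,
    noise_sd_rel = config$noise_sd_rel,
    mc_sigma_scale = config$mc_sigma_scale,
    files = basename(unlist(files))
  )
  log_path <- file.path(config$output_dir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA)
  invisible(list(config = config, results = results,
                 files = c(unlist(files), log_path)))
}
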