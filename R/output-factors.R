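#' Frame factors, field-size factors and their uncertainties
#'
#' Output-factor statistics of the nine-frame field decomposition at one
#' depth. With per-frame doses \eqn{D_i} and the 10 cm normalization
#' \eqn{D_N = \sum_{i=1}^{7} D_i}:
#' \deqn{FF_i = D_i / D_N, \qquad FSF_i = \sum_{k \le i} D_k / D_N,}
#' and, for uncorrelated dose uncertainties \eqn{\Delta D_i},
#' \deqn{\Delta FSF_i = \sqrt{\sum_{k \le i} \Delta D_k^2 / D_N^2 +
#'   \left(\sum_{k \le i} D_k\right)^2 \Delta D_N^2 / D_N^4}}
#' with \eqn{\Delta D_N = \sqrt{\sum_{i=1}^{7} \Delta D_i^2}}. Correlations
#' between the cumulative numerator and the normalization are ignored, which
#' is a conservative (slightly widening) simplification for the inner frames.
#'
#' `of_table()` computes all three; `frame_factors()`,
#' `field_size_factors()` and `fsf_uncertainty()` add the respective single
#' column, so they compose in a pipe.
#'
#' @param meas Data frame with columns `frame` (1..9, unique) and `dose`
#'   (>= 0); `dose_unc` (>= 0) is required for the uncertainty. All nine
#'   frames must be present.
#' @return The input tibble with columns `ff`, `fsf` and (when
#'   uncertainties are available) `dfsf` appended; `of_table()` returns it
#'   with class `pb_of_table` and the normalization dose in attribute
#'   `dose_norm`.
#' @export
#' @examples
#' meas <- tibble::tibble(frame = 1:9, dose = c(70, 10, 6, 4, 3, 2, 2, 1, 1),
#'                        dose_unc = 0.01 * dose)
#' of_table(meas)
of_table <- function(meas) {
  meas <- check_of_input(meas)
  out <- field_size_factors(frame_factors(meas))
  if ("dose_unc" %in% names(meas)) out <- fsf_uncertainty(out)
  structure(out,
            class = c("pb_of_table", class(out)),
            dose_norm = dose_norm(meas))
}

check_of_input <- function(meas) {
  stopifnot(is.data.frame(meas), all(c("frame", "dose") %in% names(meas)))
  meas <- dplyr::arrange(tibble::as_tibble(meas), .data$frame)
  if (!identical(as.integer(meas$frame), 1:9)) {
    stop("all nine frames (1..9) must be present exactly once", call. = FALSE)
  }
  if (any(meas$dose < 0)) stop("doses must be >= 0", call. = FALSE)
  if ("dose_unc" %in% names(meas) && any(meas$dose_unc < 0)) {
    stop("dose uncertainties must be >= 0", call. = FALSE)
  }
  meas
}

dose_norm <- function(meas) {
  # cumulative left-to-right sum: keeps FSF_7 = cumsum(dose)[7] / D_N at
  # exactly 1 in floating point
  dn <- cumsum(meas$dose[meas$frame <= 7])[7]
  if (dn <= 0) stop("normalization dose over frames 1..7 must be > 0",
                    call. = FALSE)
  dn
}

#' @rdname of_table
#' @export
frame_factors <- function(meas) {
  meas <- check_of_input(meas)
  dplyr::mutate(meas, ff = .data$dose / dose_norm(meas))
}

#' @rdname of_table
#' @export
field_size_factors <- function(meas) {
  meas <- check_of_input(meas)
  dplyr::mutate(meas, fsf = cumsum(.data$dose) / dose_norm(meas))
}

#' @rdname of_table
#' @export
fsf_uncertainty <- function(meas) {
  meas <- check_of_input(meas)
  stopifnot("dose_unc" %in% names(meas))
  dn <- dose_norm(meas)
  ddn2 <- sum(meas$dose_unc[meas$frame <= 7]^2)
  dplyr::mutate(
    meas,
    dfsf = sqrt(cumsum(.data$dose_unc^2) / dn^2 +
                  cumsum(.data$dose)^2 * ddn2 / dn^4)
  )
}

#' RMSD agreement of two field-size-factor tables
#'
#' Root-mean-square deviation of the field-size factors over frames 3..9
#' (field sizes of 4.4 cm and larger, where the halo dominates), the
#' per-depth agreement statistic between two datasets:
#' \deqn{RMSD = \sqrt{\sum_{i=3}^{9} (FSF_i^{a} - FSF_i^{b})^2 / 7}.}
#'
#' @param fsf_a,fsf_b Data frames with columns `frame` and `fsf` (e.g. from
#'   [of_table()]), or plain numeric vectors indexed by frame. Frames 3..9
#'   must be present in both.
#' @param frames Frame indices entering the statistic (default 3:9).
#' @return RMSD as a fraction.
#' @export
#' @examples
#' a <- of_table(tibble::tibble(frame = 1:9, dose = c(70, 10, 6, 4, 3, 2, 2, 1, 1)))
#' rmsd_fsf(a, a)  # 0
rmsd_fsf <- function(fsf_a, fsf_b, frames = 3:9) {
  va <- fsf_at(fsf_a, frames)
  vb <- fsf_at(fsf_b, frames)
  sqrt(sum((va - vb)^2) / length(frames))
}

fsf_at <- function(x, frames) {
  if (is.data.frame(x)) {
    stopifnot(all(c("frame", "fsf") %in% names(x)))
    idx <- match(frames, x$frame)
    if (anyNA(idx)) {
      stop(sprintf("frames %s missing from FSF table",
                   paste(frames[is.na(idx)], collapse = ", ")), call. = FALSE)
    }
    x$fsf[idx]
  } else {
    if (length(x) < max(frames)) stop("FSF vector too short", call. = FALSE)
    x[frames]
  }
}

#' Read / write frame-dose tables
#'
#' Frame-dose tables are CSVs with columns
#' `frame,dose,dose_unc,depth_mm,beam`.
#'
#' @param path CSV file path.
#' @param meas Frame-dose tibble.
#' @return `read_frame_doses()` returns a tibble; `write_frame_doses()`
#'   returns `path` invisibly.
#' @export
read_frame_doses <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_frame_doses
#' @export
write_frame_doses <- function(meas, path) {
  readr::write_csv(meas, path)
  invisible(path)
}
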