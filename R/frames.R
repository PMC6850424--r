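#' The nine standard frames of the 20 cm field decomposition
#'
#' A 20 cm x 20 cm scanned field is decomposed into nine concentric square
#' frames `[a_inner, a_outer]`; the innermost frame is solid (the in-field
#' 2 cm x 2 cm measurement) and the outer eight are hollow. The outer side of
#' frame 7 (10 cm) is the normalization field boundary.
#'
#' @return Tibble with columns `frame` (1..9), `a_inner_cm`, `a_outer_cm`.
#' @export
#' @examples
#' standard_frames()
standard_frames <- function() {
  tibble::tibble(
    frame = 1:9,
    a_inner_cm = c(0, 2.4, 3.6, 4.8, 6.0, 7.2, 8.4, 10.4, 16.0),
    a_outer_cm = c(2.0, 3.2, 4.4, 5.6, 6.8, 8.0, 10.0, 15.6, 20.0)
  )
}

# spots of one frame: strict at the inner side, inclusive at the outer side;
# grid registered with a spot at the exact origin
frame_spot_grid <- function(a_inner_cm, a_outer_cm, spacing_mm) {
  half_out <- a_outer_cm * 10 / 2
  half_in <- a_inner_cm * 10 / 2
  k <- seq(0, floor(half_out / spacing_mm)) * spacing_mm
  k <- sort(unique(c(-k, k)))
  g <- expand.grid(x_mm = k, y_mm = k)
  m <- pmax(abs(g$x_mm), abs(g$y_mm))
  keep <- if (a_inner_cm == 0) m <= half_out + 1e-9 else
    m > half_in + 1e-9 & m <= half_out + 1e-9
  tibble::as_tibble(g[keep, , drop = FALSE])
}

#' Spot map of one or more frames
#'
#' Enumerates the pencil-beam spot positions of the given frames on the
#' origin-centered scanning grid (default 2 mm spacing). A grid point
#' belongs to a frame when `max(|x|, |y|)` exceeds half the inner side
#' strictly and is at most half the outer side; rings falling exactly on an
#' inner boundary belong to no frame, mirroring the physical gaps between
#' consecutive frames.
#'
#' @param frames Data frame with columns `frame`, `a_inner_cm`, `a_outer_cm`,
#'   e.g. [standard_frames()] or a filtered subset.
#' @param spacing_mm Grid spacing in mm (> 0, default 2).
#' @return Tibble with columns `frame`, `x_mm`, `y_mm`.
#' @export
#' @examples
#' library(dplyr)
#' frame_spots(standard_frames() %>% filter(frame == 1)) %>% nrow()  # 121
frame_spots <- function(frames, spacing_mm = 2) {
  stopifnot(spacing_mm > 0,
            all(c("frame", "a_inner_cm", "a_outer_cm") %in% names(frames)))
  purrr::pmap_dfr(
    frames[c("frame", "a_inner_cm", "a_outer_cm")],
    function(frame, a_inner_cm, a_outer_cm) {
      dplyr::mutate(frame_spot_grid(a_inner_cm, a_outer_cm, spacing_mm),
                    frame = frame, .before = 1)
    }
  )
}

#' Spots per frame
#'
#' @inheritParams frame_spots
#' @return Tibble with columns `frame`, `n_spots`.
#' @export
#' @examples
#' frame_spot_counts(standard_frames())
frame_spot_counts <- function(frames, spacing_mm = 2) {
  frame_spots(frames, spacing_mm) |>
    dplyr::count(.data$frame, name = "n_spots")
}
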