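# shared fixtures: cheap parametric beams and the packaged beam set

# generic mid-energy beam with parametric growth and a unit-amplitude halo
demo_beam <- function(sigma0 = 4.53, halo_peak = 1, halo_floor = 0.2,
                      b = 0.17, theta0 = 0.01) {
  beam_spec("demo", 148.2, range_r80_mm = 153.2, z0_mm = 20,
            sigma0_mm = sigma0, theta0_rad = theta0, mcs_scale_mm = 4,
            mcs_exponent = 0.9, halo_slope_b = b,
            halo_amp_floor = halo_floor, halo_amp_peak = halo_peak)
}

# pure Gaussian beam: zero halo amplitude switches the tail off entirely
gaussian_beam <- function(sigma0 = 5) {
  demo_beam(sigma0 = sigma0, halo_peak = 0, halo_floor = 0)
}

point_detector <- function() detector_spec("point", 0)

# packaged fixtures, loaded once per test run
fixture_beams <- local({
  beams <- NULL
  function() {
    if (is.null(beams)) beams <<- beam_library()
    beams
  }
})

# noiseless linear profile: Gaussian core of width sigma plus a
# linear-exponential tail a * exp(-b r) attached with continuity at
# join * sigma (the construction behind the halo-recovery checks)
core_plus_tail_profile <- function(sigma, b, join = 2.5,
                                   half_range = 40, step = 0.5,
                                   depth = 100) {
  t <- seq(-half_range, half_range, by = step)
  r <- abs(t)
  a <- exp(-join^2 / 2 + b * join * sigma)
  dose <- pmax(exp(-r^2 / (2 * sigma^2)),
               (r > join * sigma) * a * exp(-b * r))
  lateral_profile(t, dose, depth_z_mm = depth)
}
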