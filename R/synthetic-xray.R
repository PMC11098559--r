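#' Simulate a 1D diffraction intensity profile
#'
#' Places Gaussian reflections at the detector radii implied by their
#' d-spacings under the exact Bragg relation (see [detector_to_spacing()]),
#' on top of a smooth monotone-decaying background, with optional Gaussian
#' noise. The peak `intensity` is the integrated area of the Gaussian, which
#' is the quantity [fit_reflection()] estimates.
#'
#' @param peaks Tibble with columns `name`, `d_nm`, `intensity`, `width_mm`
#'   (Gaussian SD on the detector).
#' @param geometry A [beam_geometry()].
#' @param radius_mm Radial grid on the detector, mm (strictly increasing).
#' @param background Function of radius returning background intensity, or a
#'   numeric `c(amplitude, decay_mm, offset)` for
#'   `amplitude * exp(-r/decay_mm) + offset`.
#' @param noise_sd Additive Gaussian noise SD, arbitrary units.
#' @param seed Optional integer seed.
#' @param axis `"equatorial"` or `"meridional"` (label only).
#' @return A tibble `radius_mm`, `intensity` with attributes `geometry`,
#'   `peaks`, `axis`.
#' @examples
#' pk <- tibble::tibble(name = "M6", d_nm = 7.17, intensity = 50, width_mm = 0.4)
#' prof <- simulate_diffraction_profile(pk, seed = 1)
#' @export
simulate_diffraction_profile <- function(peaks,
                                         geometry = beam_geometry(),
                                         radius_mm = seq(2, 80, by = 0.05),
                                         background = c(200, 25, 5),
                                         noise_sd = 0,
                                         seed = NULL,
                                         axis = "meridional") {
  if (nrow(peaks) > 0) {
    assert_columns(peaks, c("name", "d_nm", "intensity", "width_mm"), "`peaks`")
    if (any(peaks$d_nm <= 0)) abort("peak d-spacings must be > 0.")
  }
  if (any(diff(radius_mm) <= 0)) abort("`radius_mm` must be strictly increasing.")
  assert_number(noise_sd, "noise_sd", lower = 0)
  bg_fun <- if (is.function(background)) {
    background
  } else {
    function(r) background[1] * exp(-r / background[2]) + background[3]
  }
  with_seed_or_stream(seed, {
    intensity <- bg_fun(radius_mm)
    centers <- numeric(0)
    if (nrow(peaks) > 0) {
      centers <- spacing_to_detector(peaks$d_nm, geometry)
      for (i in seq_len(nrow(peaks))) {
        r0 <- centers[i]
        if (r0 < min(radius_mm) || r0 > max(radius_mm)) {
          abort(sprintf(
            "peak '%s' (d = %g nm) falls at radius %.2f mm, outside the simulated range [%g, %g].",
            peaks$name[i], peaks$d_nm[i], r0, min(radius_mm), max(radius_mm)))
        }
        amp <- peaks$intensity[i] / (peaks$width_mm[i] * sqrt(2 * pi))
        intensity <- intensity +
          amp * exp(-0.5 * ((radius_mm - r0) / peaks$width_mm[i])^2)
      }
    }
    if (noise_sd > 0) intensity <- intensity + rnorm(length(radius_mm), 0, noise_sd)
    out <- tibble(radius_mm = radius_mm, intensity = intensity)
    attr(out, "geometry") <- geometry
    attr(out, "peaks") <- if (nrow(peaks) > 0) {
      dplyr::mutate(peaks, center_mm = centers)
    } else {
      peaks
    }
    attr(out, "axis") <- axis
    out
  })
}
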