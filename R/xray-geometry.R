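#' Small-angle beamline geometry
#'
#' Wavelength and specimen-to-detector distance used to convert detector
#' radius to lattice/axial spacing via the exact Bragg relation. Defaults
#' match a typical muscle small-angle setup (0.10 nm wavelength, 2.14 m
#' camera length).
#'
#' @param wavelength_nm X-ray wavelength, nm.
#' @param camera_length_m Specimen-to-detector distance, m.
#' @param pixel_size_mm Optional detector pixel size (mm) for pixel-indexed
#'   profiles.
#' @return A `beam_geometry` list.
#' @export
beam_geometry <- function(wavelength_nm = 0.10, camera_length_m = 2.14,
                          pixel_size_mm = NULL) {
  assert_number(wavelength_nm, "wavelength_nm", lower = 0, strict_lower = TRUE)
  assert_number(camera_length_m, "camera_length_m", lower = 0, strict_lower = TRUE)
  if (!is.null(pixel_size_mm)) {
    assert_number(pixel_size_mm, "pixel_size_mm", lower = 0, strict_lower = TRUE)
  }
  structure(list(wavelength_nm = wavelength_nm,
                 camera_length_m = camera_length_m,
                 pixel_size_mm = pixel_size_mm),
            class = "beam_geometry")
}

#' Convert detector radius to d-spacing (and back)
#'
#' Exact Bragg geometry: the scattering angle is
#' \eqn{2\theta = \arctan(r / L)} and the spacing
#' \eqn{d = \lambda / (2 \sin\theta)}. `spacing_to_detector()` is the exact
#' inverse, \eqn{r = L \tan(2 \arcsin(\lambda / 2d))}.
#'
#' @param radius_mm Detector radius from the pattern center, mm (> 0).
#' @param spacing_nm Structural periodicity, nm.
#' @param geometry A [beam_geometry()].
#' @return Spacing in nm (or radius in mm for the inverse).
#' @examples
#' g <- beam_geometry()
#' detector_to_spacing(spacing_to_detector(14.34, g), g)
#' @export
detector_to_spacing <- function(radius_mm, geometry = beam_geometry()) {
  if (any(!is.finite(radius_mm)) || any(radius_mm <= 0)) {
    abort("`radius_mm` must be positive and finite.")
  }
  L_mm <- geometry$camera_length_m * 1000
  theta <- 0.5 * atan(radius_mm / L_mm)
  geometry$wavelength_nm / (2 * sin(theta))
}

#' @rdname detector_to_spacing
#' @export
spacing_to_detector <- function(spacing_nm, geometry = beam_geometry()) {
  if (any(!is.finite(spacing_nm)) || any(spacing_nm <= 0)) {
    abort("`spacing_nm` must be positive and finite.")
  }
  s <- geometry$wavelength_nm / (2 * spacing_nm)
  if (any(s >= 1)) abort("spacing too small for this wavelength (Bragg condition unsatisfiable).")
  L_mm <- geometry$camera_length_m * 1000
  L_mm * tan(2 * asin(s))
}
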