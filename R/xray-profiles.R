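#' Subtract smooth background from a 1D diffraction profile
#'
#' Default method is an iterated polynomial under-fit: a polynomial is fit
#' to the profile, points above the fit are clipped down to it, and the fit
#' is repeated until it settles underneath the peaks — a standard smooth
#' background estimate for 1D reductions. `method = "linear"` is the same
#' procedure with a straight line (linear-under-peak), useful inside a
#' narrow window around one reflection.
#'
#' @param profile Tibble `radius_mm`, `intensity`.
#' @param method `"poly"` (default) or `"linear"`.
#' @param window Optional `c(lo, hi)` radius window to restrict to first.
#' @param degree Polynomial degree for `method = "poly"`.
#' @param iterations Number of clip-and-refit passes.
#' @return Profile tibble with background-subtracted `intensity`; the
#'   estimated background is attached as attribute `"background"`. Negative
#'   residual values are preserved (not clipped); if they are substantial
#'   the attribute `"qc_flags"` contains `NEGATIVE_VALUES`.
#' @export
subtract_background <- function(profile, method = c("poly", "linear"),
                                window = NULL, degree = 4, iterations = 30) {
  assert_columns(profile, c("radius_mm", "intensity"), "`profile`")
  method <- tryCatch(match.arg(method), error = function(e) {
    abort("unknown background method; available: poly, linear.")
  })
  if (!is.null(window)) {
    profile <- filter(profile, .data$radius_mm >= window[1],
                      .data$radius_mm <= window[2])
    if (nrow(profile) < 5L) abort("window leaves too few points.")
  }
  r <- profile$radius_mm
  y <- profile$intensity
  deg <- if (method == "linear") 1L else as.integer(degree)
  work <- y
  bg <- rep(0, length(y))
  for (i in seq_len(iterations)) {
    fit <- lm(work ~ poly(r, deg, raw = TRUE))
    bg <- unname(stats::fitted(fit))
    work <- pmin(work, bg)
  }
  out <- tibble(radius_mm = r, intensity = y - bg)
  attr(out, "background") <- bg
  if (min(out$intensity) < -0.05 * max(abs(y))) {
    attr(out, "qc_flags") <- "NEGATIVE_VALUES"
  }
  for (a in c("geometry", "axis")) attr(out, a) <- attr(profile, a)
  out
}

#' Radius search windows for named reflections
#'
#' Converts d-spacing windows (center +/- a fractional half-width) into
#' detector-radius windows under the beam geometry. Defaults cover the
#' myosin meridional M3 (~14.34 nm) and M6 (~7.17 nm) reflections.
#'
#' @param d_centers_nm Named vector of expected d-spacings, nm.
#' @param half_width Fractional half-width of the search window in d.
#' @param geometry A [beam_geometry()].
#' @return Named list of `c(lo, hi)` radius windows (mm).
#' @export
reflection_windows <- function(d_centers_nm = c(M3 = 14.34, M6 = 7.17),
                               half_width = 0.05,
                               geometry = beam_geometry()) {
  lapply(setNames(nm = names(d_centers_nm)), function(nm) {
    d <- d_centers_nm[[nm]]
    sort(spacing_to_detector(c(d * (1 + half_width), d * (1 - half_width)),
                             geometry))
  })
}

#' Fit one reflection in a radius window
#'
#' Fits a Gaussian plus local linear baseline to the profile inside the
#' window by Levenberg-Marquardt least squares. The reported intensity is
#' the integrated Gaussian area (height x width x sqrt(2 pi)); the peak
#' center is converted to a d-spacing via the exact Bragg relation.
#'
#' @param profile Tibble `radius_mm`, `intensity`.
#' @param window `c(lo, hi)` radius window containing one dominant peak.
#' @param geometry A [beam_geometry()]; taken from the profile attribute if
#'   present.
#' @param name Reflection label carried into the output.
#' @param snr_min Minimum peak height over the local noise scale below which
#'   the window is declared peak-free (error `NOPEAK`).
#' @return One-row tibble: `reflection`, `center_mm`, `spacing_nm`,
#'   `intensity` (integrated area), `height`, `width_mm`, `rss`.
#' @export
fit_reflection <- function(profile, window, geometry = NULL, name = "peak",
                           snr_min = 5) {
  assert_columns(profile, c("radius_mm", "intensity"), "`profile`")
  geometry <- geometry %||% attr(profile, "geometry") %||% beam_geometry()
  sub <- filter(profile, .data$radius_mm >= window[1],
                .data$radius_mm <= window[2])
  if (nrow(sub) < 8L) abort("window contains too few points to fit a peak.")
  r <- sub$radius_mm
  y <- sub$intensity

  # local linear baseline from the window edges
  n_edge <- max(3L, round(0.1 * length(r)))
  edge_idx <- c(seq_len(n_edge), seq(length(r) - n_edge + 1L, length(r)))
  base_fit <- lm(y[edge_idx] ~ r[edge_idx])
  b0 <- coef(base_fit)[1]; b1 <- coef(base_fit)[2]
  resid0 <- y - (b0 + b1 * r)

  noise <- stats::mad(diff(y)) / sqrt(2)
  noise <- max(noise, 1e-12 * max(abs(y)))
  if (max(resid0) < snr_min * noise) {
    abort(sprintf("NOPEAK: no peak above the noise floor in window [%g, %g] mm.",
                  window[1], window[2]))
  }

  i0 <- which.max(resid0)
  start <- list(h = max(resid0), c = r[i0],
                w = max(diff(window) / 10, 2 * mean(diff(r))),
                b0 = unname(b0), b1 = unname(b1))
  fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
    y ~ h * exp(-0.5 * ((r - c) / w)^2) + b0 + b1 * r,
    data = data.frame(r = r, y = y), start = start,
    lower = c(0, window[1], mean(diff(r)) / 2, -Inf, -Inf),
    upper = c(Inf, window[2], diff(window), Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500))),
    error = function(e) NULL)
  if (is.null(fit)) abort("reflection fit failed to converge in this window.")
  cf <- coef(fit)
  tibble(reflection = name,
         center_mm = unname(cf[["c"]]),
         spacing_nm = detector_to_spacing(cf[["c"]], geometry),
         intensity = unname(cf[["h"]] * cf[["w"]] * sqrt(2 * pi)),
         height = unname(cf[["h"]]),
         width_mm = unname(cf[["w"]]),
         rss = sum(stats::resid(fit)^2))
}

#' Measure a set of named reflections on one profile
#'
#' @param profile Tibble `radius_mm`, `intensity`.
#' @param windows Named list of radius windows, e.g. from
#'   [reflection_windows()].
#' @param geometry A [beam_geometry()].
#' @param normalize If `TRUE`, adds `intensity_norm` = integrated area
#'   divided by the total profile intensity (a per-profile normalization
#'   convention for comparing intensities across exposures).
#' @return Tibble with one row per reflection.
#' @export
measure_reflections <- function(profile, windows = reflection_windows(),
                                geometry = NULL, normalize = TRUE) {
  geometry <- geometry %||% attr(profile, "geometry") %||% beam_geometry()
  out <- imap(windows, function(w, nm) {
    fit_reflection(profile, w, geometry = geometry, name = nm)
  }) |> list_rbind()
  if (normalize) {
    total <- sum(profile$intensity) * mean(diff(profile$radius_mm))
    out$intensity_norm <- out$intensity / total
  }
  out
}

#' Equatorial intensity ratio I(1,1) / I(1,0)
#'
#' Ratio of the integrated intensities of the 1,1 and 1,0 equatorial
#' reflections of the hexagonal myofilament lattice; higher values indicate
#' myosin mass shifted from thick toward thin filaments (OFF -> ON).
#'
#' @param m10,m11 One-row measurement tibbles from [fit_reflection()] for
#'   the 1,0 and 1,1 reflections (or numeric integrated intensities).
#' @return The dimensionless ratio.
#' @export
equatorial_ratio <- function(m10, m11) {
  i10 <- if (is.numeric(m10)) m10 else m10$intensity
  i11 <- if (is.numeric(m11)) m11 else m11$intensity
  if (i10 <= 0) abort("I(1,0) intensity must be > 0.")
  i11 / i10
}

#' Plot a diffraction profile with optional measured reflections
#'
#' @param profile Tibble `radius_mm`, `intensity`.
#' @param measurements Optional tibble from [measure_reflections()].
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, measurements = NULL) {
  p <- ggplot(profile, aes(x = .data$radius_mm, y = .data$intensity)) +
    geom_line() +
    labs(x = "Detector radius (mm)", y = "Intensity (a.u.)") +
    theme_bw()
  if (!is.null(measurements)) {
    p <- p + geom_vline(data = measurements,
                        aes(xintercept = .data$center_mm),
                        linetype = "dashed", colour = "firebrick")
  }
  p
}
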