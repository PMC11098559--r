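test_that("Bragg conversion is an exact inverse pair and matches small-angle approx", {
  g <- beam_geometry(wavelength_nm = 0.10, camera_length_m = 2.14)
  for (d in c(14.34, 7.17, 37)) {
    expect_equal(detector_to_spacing(spacing_to_detector(d, g), g), d,
                 tolerance = 1e-12)
  }
  # small-angle approximation d ~ lambda*L/r agrees to < 0.01% at the
  # named reflections (error ~ 0.375*(r/L)^2, under 1e-4 for d >~ 6.2 nm)
  for (d in c(7.17, 14.34, 37)) {
    r <- spacing_to_detector(d, g)
    d_approx <- g$wavelength_nm * g$camera_length_m * 1000 / r
    expect_lt(abs(d_approx - d) / d, 1e-4)
  }
  expect_error(detector_to_spacing(0, g), "positive")
  expect_error(spacing_to_detector(-1, g), "positive")
  expect_error(beam_geometry(wavelength_nm = 0), "wavelength_nm")
})

test_that("background subtraction nulls a pure background and preserves peak area", {
  r <- seq(2, 80, by = 0.05)
  # background inside the polynomial span is removed essentially exactly
  bg <- 100 - 1.5 * r + 0.01 * r^2
  prof <- tibble::tibble(radius_mm = r, intensity = bg)
  out <- subtract_background(prof, method = "poly", degree = 4)
  expect_lt(max(abs(out$intensity)), 1e-6 * max(bg))

  # synthetic peak + linear background, linear method: area preserved within 1%
  g <- beam_geometry()
  pk <- tibble::tibble(name = "M6", d_nm = 7.17, intensity = 80, width_mm = 0.4)
  lin_bg <- function(rr) 50 - 0.3 * rr
  prof2 <- simulate_diffraction_profile(pk, g, background = lin_bg, noise_sd = 0)
  w <- reflection_windows(c(M6 = 7.17))$M6
  sub <- subtract_background(prof2, method = "linear",
                             window = w + c(-5, 5))
  m <- fit_reflection(sub, w, g, name = "M6")
  expect_equal(m$intensity, 80, tolerance = 0.01)

  # negative-going artifacts are preserved, not clipped, and flagged
  prof3 <- tibble::tibble(radius_mm = r, intensity = 0 * r)
  prof3$intensity[500:520] <- -50
  out3 <- subtract_background(prof3, method = "linear")
  expect_lt(min(out3$intensity), 0)
  expect_true("NEGATIVE_VALUES" %in% attr(out3, "qc_flags"))

  expect_error(subtract_background(prof, method = "spline"),
               "poly, linear")
})

test_that("reflection fits recover spacing and intensity ratios from synthetic truth", {
  g <- beam_geometry()
  pk <- tibble::tibble(name = c("eq10", "eq11"), d_nm = c(37, 21.4),
                       intensity = c(100, 40), width_mm = c(0.6, 0.6))
  prof <- simulate_diffraction_profile(pk, g, radius_mm = seq(2, 30, by = 0.02),
                                       background = c(150, 10, 3),
                                       noise_sd = 0, seed = 1)
  wins <- reflection_windows(c(eq10 = 37, eq11 = 21.4), half_width = 0.1)
  m <- measure_reflections(subtract_background(prof), wins, g)
  expect_equal(m$spacing_nm[m$reflection == "eq10"], 37, tolerance = 1e-3)
  expect_equal(m$spacing_nm[m$reflection == "eq11"], 21.4, tolerance = 1e-3)
  ratio <- equatorial_ratio(m[m$reflection == "eq10", ], m[m$reflection == "eq11", ])
  expect_equal(ratio, 0.4, tolerance = 0.02)

  # the intensity ratio is invariant to overall profile scaling
  prof2 <- dplyr::mutate(prof, intensity = intensity * 7.3)
  attr(prof2, "geometry") <- g
  m2 <- measure_reflections(subtract_background(prof2), wins, g)
  expect_equal(equatorial_ratio(m2[m2$reflection == "eq10", ],
                                m2[m2$reflection == "eq11", ]),
               ratio, tolerance = 1e-6)

  # flat profile: no peak above the noise floor
  flat <- tibble::tibble(radius_mm = seq(2, 30, by = 0.02), intensity = 1)
  expect_error(fit_reflection(flat, wins$eq10, g), "NOPEAK")
  expect_error(equatorial_ratio(0, 10), "> 0")
  expect_equal(equatorial_ratio(30, 30), 1)
  expect_equal(equatorial_ratio(30, 60), 2)
})

test_that("spacing recovery stays under 0.1% across random peaks at 1% noise", {
  g <- beam_geometry()
  withr::with_seed(12, {
    errs <- vapply(1:100, function(i) {
      d <- runif(1, 5, 50)
      r0 <- spacing_to_detector(d, g)
      width <- 0.1 + 0.01 * r0  # keep the peak narrow relative to its window
      area <- 60
      pk <- tibble::tibble(name = "p", d_nm = d, intensity = area,
                           width_mm = width)
      peak_height <- area / (width * sqrt(2 * pi))
      prof <- simulate_diffraction_profile(
        pk, g, radius_mm = seq(1, 90, by = 0.05),
        background = c(80, 20, 2), noise_sd = 0.01 * peak_height)
      w <- reflection_windows(stats::setNames(d, "p"), half_width = 0.12)$p
      m <- fit_reflection(subtract_background(prof), w, g, name = "p")
      abs(m$spacing_nm - d) / d
    }, numeric(1))
    expect_lt(max(errs), 1e-3)
  })
})

test_that("background subtraction before fitting matches fitting the bare peak", {
  g <- beam_geometry()
  pk <- tibble::tibble(name = "M3", d_nm = 14.34, intensity = 70, width_mm = 0.5)
  with_bg <- simulate_diffraction_profile(pk, g, background = c(120, 18, 4),
                                          noise_sd = 0)
  bare <- simulate_diffraction_profile(pk, g, background = function(r) 0,
                                       noise_sd = 0)
  w <- reflection_windows(c(M3 = 14.34))$M3
  a1 <- fit_reflection(subtract_background(with_bg), w, g)$intensity
  a2 <- fit_reflection(bare, w, g)$intensity
  expect_equal(a1, a2, tolerance = 0.01)
})
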