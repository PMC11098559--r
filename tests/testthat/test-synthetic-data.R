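test_that("decay model is 1 at t = 0 and tends to the plateau", {
  # no decaying component: constant 1
  tr <- simulate_decay(decay_truth(0, 10, 0, 100), noise_sd = 0)
  expect_equal(normalize_trace(tr)$norm_fluor, rep(1, nrow(tr)))

  expect_identical(mant_decay_model(0, 0.25, 15, 0.5, 200), 1)
  # limit 1 - p1 - p2 evaluated by hand: 1 - 0.25 - 0.50 = 0.25
  expect_equal(mant_decay_model(1e9, 0.25, 15, 0.5, 200), 0.25, tolerance = 1e-12)
})

test_that("invalid decay truths are rejected with the violated invariant named", {
  expect_error(decay_truth(0.7, 15, 0.5, 200), "p1_frac \\+ p2_frac")
  expect_error(decay_truth(0.2, 300, 0.5, 200), "t1_s must be <")
  expect_error(decay_truth(-0.1, 15, 0.5, 200), "p1_frac")
  expect_error(simulate_decay(list(p1 = 0.2), noise_sd = 0), "decay_truth")
  expect_error(simulate_decay(decay_truth(0.2, 15, 0.5, 200), grid = c(5, 10)),
               "start at 0")
  expect_error(simulate_decay(decay_truth(0.2, 15, 0.5, 200), noise_sd = -1),
               "noise_sd")
})

test_that("simulated raw traces encode the normalized curve exactly at zero noise", {
  tr <- simulate_decay(decay_truth(0.25, 15, 0.5, 200), noise_sd = 0,
                       baseline_fluor = 500, background = 50)
  expect_equal(normalize_trace(tr)$norm_fluor, tr$norm_true, tolerance = 1e-12)
  expect_equal(tr$background_fluor, rep(50, nrow(tr)))
})

test_that("study simulation respects design bounds and is seed-deterministic", {
  des <- study_design(conditions = c("SA", "IBA", "torpor"),
                      animals_per_condition = 5,
                      fibers_per_animal = c(8, 12), seed = 42)
  sim <- simulate_study(des)
  n_fibers <- nrow(sim$truth)
  expect_gte(n_fibers, 3 * 5 * 8)
  expect_lte(n_fibers, 3 * 5 * 12)
  expect_setequal(unique(sim$truth$condition), c("SA", "IBA", "torpor"))
  expect_equal(dplyr::n_distinct(sim$truth$animal_id), 15)

  sim2 <- simulate_study(des)
  expect_identical(sim$truth, sim2$truth)
  expect_identical(sim$traces, sim2$traces)
})

test_that("degenerate effects (unit multipliers, zero variance) yield one shared truth", {
  eff <- condition_effects(animal_cv = 0, fiber_cv = 0,
                           animal_p1_sd = 0, fiber_p1_sd = 0, noise_sd = 0)
  des <- study_design(conditions = c("SA", "torpor"), animals_per_condition = 2,
                      fibers_per_animal = c(3, 3), seed = 5)
  sim <- simulate_study(des, eff)
  expect_equal(dplyr::n_distinct(round(sim$truth$t1_s, 12)), 1)
  expect_equal(dplyr::n_distinct(round(sim$truth$p1_frac, 12)), 1)
})

test_that("noiseless refit of generated truths closes the loop to < 1e-6 relative", {
  des <- study_design(conditions = "SA", animals_per_condition = 2,
                      fibers_per_animal = c(2, 2), seed = 9)
  eff <- condition_effects(noise_sd = 0)
  sim <- simulate_study(des, eff)
  fits <- fit_decay_all(sim$traces)
  joined <- dplyr::left_join(fits, sim$truth, by = "fiber_id")
  expect_true(all(abs(joined$t1_s.x - joined$t1_s.y) / joined$t1_s.y < 1e-6))
  expect_true(all(abs(joined$p1_pct / 100 - joined$p1_frac) /
                    pmax(joined$p1_frac, 1e-6) < 1e-6))
})

test_that("between-animal spread of fiber means grows with the animal variance component", {
  des <- study_design(conditions = "SA", animals_per_condition = 6,
                      fibers_per_animal = c(4, 4), duration_s = 10,
                      frame_interval_s = 5, seed = 1)
  spread_at <- function(cv, reps = 100) {
    vals <- vapply(seq_len(reps), function(r) {
      d <- des; d$seed <- r
      eff <- condition_effects(animal_cv = cv, fiber_cv = 0.05, noise_sd = 0)
      truth <- simulate_study(d, eff)$truth
      means <- tapply(truth$t1_s, truth$animal_id, mean)
      stats::var(as.numeric(means))
    }, numeric(1))
    mean(vals)
  }
  v <- c(spread_at(0.01), spread_at(0.1), spread_at(0.3))
  expect_true(v[1] < v[2] && v[2] < v[3])
})

test_that("image stacks reproduce the tabular trace through ROI extraction", {
  tr <- simulate_decay(decay_truth(0.25, 15, 0.5, 200), noise_sd = 0,
                       baseline_fluor = 500, background = 50, seed = 1)
  st <- simulate_image_stack(tr, frame_shape = c(64, 64), pixel_noise_sd = 0)
  expect_identical(dim(st$stack), c(nrow(tr), 64L, 64L))  # 61 x 64 x 64
  ex <- extract_roi_traces(st)
  expect_equal(ex$raw_fluor, tr$raw_fluor, tolerance = 1e-12)
  expect_equal(ex$background_fluor, rep(50, nrow(tr)), tolerance = 1e-12)

  # overlapping ROIs must be rejected
  bad <- st$roi_geometry
  bad$background$bg1 <- bad$fiber$roi1
  expect_error(simulate_image_stack(tr, roi_geometry = bad), "overlap")
})

test_that("diffraction peaks land at the exact Bragg radius", {
  g <- beam_geometry(wavelength_nm = 0.10, camera_length_m = 2.14)
  d <- 7.20
  r_expected <- 2140 * tan(2 * asin(0.10 / (2 * d)))  # hand Bragg geometry, mm
  pk <- tibble::tibble(name = "p", d_nm = d, intensity = 100, width_mm = 0.3)
  prof <- simulate_diffraction_profile(pk, g, background = function(r) 0,
                                       noise_sd = 0)
  # grid resolution is 0.05 mm, so allow half a step
  expect_lt(abs(prof$radius_mm[which.max(prof$intensity)] - r_expected), 0.026)

  # zero peaks: profile equals the background model
  bg <- function(r) 100 * exp(-r / 30) + 2
  prof0 <- simulate_diffraction_profile(pk[0, ], g, background = bg, noise_sd = 0)
  expect_equal(prof0$intensity, bg(prof0$radius_mm), tolerance = 1e-12)

  # a peak outside the radial range is an error naming the peak
  far <- tibble::tibble(name = "far", d_nm = 500, intensity = 1, width_mm = 0.3)
  expect_error(simulate_diffraction_profile(far, g), "far")
})

test_that("two simulated peaks have the constructed area ratio at zero noise", {
  g <- beam_geometry()
  pk <- tibble::tibble(name = c("a", "b"), d_nm = c(14.34, 7.17),
                       intensity = c(100, 50), width_mm = 0.4)
  prof <- simulate_diffraction_profile(pk, g, noise_sd = 0)
  m <- measure_reflections(subtract_background(prof),
                           reflection_windows(c(a = 14.34, b = 7.17)), g)
  ratio <- m$intensity[m$reflection == "b"] / m$intensity[m$reflection == "a"]
  expect_equal(ratio, 0.5, tolerance = 0.01)
})

test_that("abundance simulator honors DE fraction, fold-change and missingness switches", {
  am0 <- simulate_abundance_matrix(n_features = 50, de_fraction = 0, seed = 2)
  expect_false(any(am0$truth$is_de))
  expect_false(any(is.na(am0$mat)))  # missingness off by default

  # with zero sample noise, the group-mean difference of DE features is
  # exactly the configured |log2 fold-change|
  am <- simulate_abundance_matrix(n_features = 200, de_fraction = 0.2,
                                  log2_fc = 2, sample_sd = 0, seed = 2)
  grp <- am$samples$group
  diffs <- rowMeans(am$mat[, grp == "torpor"]) - rowMeans(am$mat[, grp == "SA"])
  expect_equal(abs(diffs[am$truth$is_de]), rep(2, sum(am$truth$is_de)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(diffs[!am$truth$is_de], rep(0, sum(!am$truth$is_de)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # left-censoring: missing cells come from lower abundances than observed
  amm <- simulate_abundance_matrix(n_features = 2000, seed = 4,
                                   missingness = list(censor_quantile = 0.1,
                                                      scale = 0.5))
  expect_gt(sum(is.na(amm$mat)), 0)
  complete <- simulate_abundance_matrix(n_features = 2000, seed = 4,
                                        missingness = NULL)
  expect_lt(mean(complete$mat[is.na(amm$mat)]),
            mean(complete$mat[!is.na(amm$mat)]))
})
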