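#' Describe a hierarchical single-fiber study design
#'
#' Captures the sampling structure of a Mant-ATP chase study: conditions
#' (e.g. summer-active, interbout arousal, torpor), animals per condition,
#' fibers per animal, fiber-type mix, assay temperatures, and the acquisition
#' grid (one frame every `frame_interval_s` seconds for `duration_s` seconds).
#'
#' @param conditions Character vector of condition labels.
#' @param animals_per_condition Number of animals in each condition.
#' @param fibers_per_animal Integer range `c(low, high)`; each animal
#'   contributes a uniformly drawn number of fibers in this range.
#' @param fiber_type_prop Proportion of type II (fast-twitch) fibers.
#' @param temperatures_C Assay temperatures in degrees Celsius.
#' @param frame_interval_s Seconds between frames.
#' @param duration_s Total recording length, seconds; must be an integer
#'   multiple of `frame_interval_s`.
#' @param seed Integer seed; the same seed reproduces the study exactly.
#' @return A `study_design` list.
#' @examples
#' study_design(conditions = c("SA", "torpor"), seed = 1)
#' @export
study_design <- function(conditions = c("SA", "IBA", "torpor"),
                         animals_per_condition = 5,
                         fibers_per_animal = c(8, 12),
                         fiber_type_prop = 0.5,
                         temperatures_C = 20,
                         frame_interval_s = 5,
                         duration_s = 300,
                         seed = 1L) {
  if (!is.character(conditions) || length(conditions) < 1L) {
    abort("`conditions` must be a non-empty character vector.")
  }
  assert_number(animals_per_condition, "animals_per_condition", lower = 1)
  if (length(fibers_per_animal) != 2L || fibers_per_animal[1] > fibers_per_animal[2] ||
      fibers_per_animal[1] < 1) {
    abort("`fibers_per_animal` must be c(low, high) with 1 <= low <= high.")
  }
  assert_number(fiber_type_prop, "fiber_type_prop", lower = 0, upper = 1)
  assert_number(frame_interval_s, "frame_interval_s", lower = 0, strict_lower = TRUE)
  assert_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  if (abs(duration_s / frame_interval_s - round(duration_s / frame_interval_s)) > 1e-9) {
    abort("`duration_s` must be an integer multiple of `frame_interval_s`.")
  }
  structure(
    list(conditions = conditions,
         animals_per_condition = as.integer(animals_per_condition),
         fibers_per_animal = as.integer(fibers_per_animal),
         fiber_type_prop = fiber_type_prop,
         temperatures_C = temperatures_C,
         frame_interval_s = frame_interval_s,
         duration_s = duration_s,
         seed = as.integer(seed)),
    class = "study_design"
  )
}

#' Condition and hierarchy effects for the synthetic study
#'
#' Defines how decay-truth parameters vary across the hierarchy. The baseline
#' truth (per fiber type) is multiplied by per-condition lifetime multipliers
#' and shifted on the DRX amplitude, then perturbed by lognormal
#' animal-level and fiber-level multipliers on the lifetimes and Gaussian
#' shifts on the DRX amplitude. Optional per-temperature lifetime multipliers
#' model temperature sensitivity. Additive Gaussian noise with standard
#' deviation `noise_sd` is applied on the normalized-fluorescence scale.
#'
#' @param baseline Named list of [decay_truth()] objects, one per fiber type
#'   (`"I"`, `"II"`).
#' @param condition_mult Tibble with columns `condition`, `fiber_type`,
#'   `t1_mult`, `t2_mult`, `p1_shift`. Conditions/fiber types not listed get
#'   multiplier 1 and shift 0.
#' @param temperature_mult Tibble with columns `temperature_C`, `t1_mult`,
#'   `t2_mult`; temperatures not listed get multiplier 1.
#' @param animal_cv Lognormal coefficient of variation (sdlog) of the
#'   between-animal lifetime multipliers.
#' @param fiber_cv Same for the within-animal (fiber-level) multipliers.
#' @param animal_p1_sd,fiber_p1_sd Gaussian SDs of the animal- and
#'   fiber-level shifts on the DRX amplitude fraction.
#' @param noise_sd Additive Gaussian noise SD on normalized fluorescence.
#' @param baseline_fluor_range,background_range Uniform ranges (arbitrary
#'   units) from which each fiber's baseline fluorescence intensity and
#'   background level are drawn, making normalization nontrivial.
#' @return A `condition_effects` list.
#' @export
condition_effects <- function(baseline = list(
                                I = decay_truth(0.25, 15, 0.50, 200),
                                II = decay_truth(0.25, 15, 0.50, 200)),
                              condition_mult = NULL,
                              temperature_mult = NULL,
                              animal_cv = 0.075,
                              fiber_cv = 0.15,
                              animal_p1_sd = 0.015,
                              fiber_p1_sd = 0.03,
                              noise_sd = 0.01,
                              baseline_fluor_range = c(400, 800),
                              background_range = c(20, 80)) {
  stopifnot(is.list(baseline), length(baseline) >= 1L)
  ok <- vapply(baseline, inherits, logical(1), "decay_truth")
  if (!all(ok)) abort("every element of `baseline` must be a decay_truth().")
  for (nm in c("animal_cv", "fiber_cv", "animal_p1_sd", "fiber_p1_sd", "noise_sd")) {
    assert_number(get(nm), nm, lower = 0)
  }
  if (!is.null(condition_mult)) {
    assert_columns(condition_mult,
                   c("condition", "fiber_type", "t1_mult", "t2_mult", "p1_shift"),
                   "`condition_mult`")
    if (any(condition_mult$t1_mult <= 0) || any(condition_mult$t2_mult <= 0)) {
      abort("lifetime multipliers must be > 0.")
    }
  }
  if (!is.null(temperature_mult)) {
    assert_columns(temperature_mult, c("temperature_C", "t1_mult", "t2_mult"),
                   "`temperature_mult`")
    if (any(temperature_mult$t1_mult <= 0) || any(temperature_mult$t2_mult <= 0)) {
      abort("lifetime multipliers must be > 0.")
    }
  }
  structure(
    list(baseline = baseline,
         condition_mult = condition_mult,
         temperature_mult = temperature_mult,
         animal_cv = animal_cv, fiber_cv = fiber_cv,
         animal_p1_sd = animal_p1_sd, fiber_p1_sd = fiber_p1_sd,
         noise_sd = noise_sd,
         baseline_fluor_range = baseline_fluor_range,
         background_range = background_range),
    class = "condition_effects"
  )
}

lookup_condition_mult <- function(effects, condition, fiber_type) {
  out <- list(t1_mult = 1, t2_mult = 1, p1_shift = 0)
  cm <- effects$condition_mult
  if (!is.null(cm)) {
    row <- cm[cm$condition == condition & cm$fiber_type == fiber_type, ]
    if (nrow(row) == 1L) {
      out <- list(t1_mult = row$t1_mult, t2_mult = row$t2_mult,
                  p1_shift = row$p1_shift)
    }
  }
  out
}

lookup_temperature_mult <- function(effects, temperature_C) {
  tm <- effects$temperature_mult
  if (is.null(tm)) return(list(t1_mult = 1, t2_mult = 1))
  row <- tm[abs(tm$temperature_C - temperature_C) < 1e-9, ]
  if (nrow(row) == 1L) list(t1_mult = row$t1_mult, t2_mult = row$t2_mult)
  else list(t1_mult = 1, t2_mult = 1)
}

# Draw one fiber's decay truth given baseline + multiplicative perturbations,
# resampling the stochastic parts until the truth invariants hold.
draw_fiber_truth <- function(base, cond_eff, temp_eff, animal_mult, animal_shift,
                             effects, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    fib_t <- exp(rnorm(2, 0, effects$fiber_cv))
    fib_p1 <- rnorm(1, 0, effects$fiber_p1_sd)
    t1 <- base$t1_s * cond_eff$t1_mult * temp_eff$t1_mult * animal_mult[1] * fib_t[1]
    t2 <- base$t2_s * cond_eff$t2_mult * temp_eff$t2_mult * animal_mult[2] * fib_t[2]
    p1 <- base$p1_frac + cond_eff$p1_shift + animal_shift + fib_p1
    p2 <- base$p2_frac
    ok <- p1 >= 0 && p1 <= 1 && p1 + p2 <= 1 && t1 > 0 && t2 > 0 && t1 < t2
    if (ok) return(decay_truth(p1, t1, p2, t2))
  }
  abort("could not draw a valid decay truth in 100 attempts; check effect sizes.")
}

#' Simulate one fiber's Mant-ATP chase trace
#'
#' Evaluates the double-exponential decay model on a time grid, adds i.i.d.
#' Gaussian noise on the normalized-fluorescence scale, then rescales by a
#' baseline fluorescence intensity and adds a background level so that
#' background subtraction and normalization are nontrivial downstream.
#'
#' @param truth A [decay_truth()].
#' @param grid Time points in seconds; must start at 0 and increase.
#' @param noise_sd Gaussian noise SD on normalized fluorescence (>= 0).
#' @param baseline_fluor Baseline (t = 0) fiber fluorescence in arbitrary
#'   units.
#' @param background Background fluorescence level, arbitrary units.
#' @param seed Optional integer seed.
#' @return A tibble with columns `time_s`, `raw_fluor`, `background_fluor`,
#'   `norm_true` (the noiseless model value); the generating truth is
#'   attached as attribute `"truth"`.
#' @examples
#' tr <- simulate_decay(decay_truth(0.25, 15, 0.5, 200), seed = 1)
#' head(tr)
#' @export
simulate_decay <- function(truth, grid = seq(0, 300, by = 5), noise_sd = 0.01,
                           baseline_fluor = 600, background = 50, seed = NULL) {
  if (!inherits(truth, "decay_truth")) {
    abort("`truth` must be a decay_truth() object.")
  }
  if (grid[1] != 0) abort("`grid` must start at 0 (time of washout).")
  if (any(diff(grid) <= 0)) abort("`grid` must be strictly increasing.")
  assert_number(noise_sd, "noise_sd", lower = 0)
  with_seed_or_stream(seed, {
    norm_true <- mant_decay_model(grid, truth$p1_frac, truth$t1_s,
                                  truth$p2_frac, truth$t2_s)
    norm_noisy <- norm_true + rnorm(length(grid), 0, noise_sd)
    out <- tibble(
      time_s = grid,
      raw_fluor = background + baseline_fluor * norm_noisy,
      background_fluor = background,
      norm_true = norm_true
    )
    attr(out, "truth") <- truth
    out
  })
}

#' Simulate a full hierarchical Mant-ATP chase study
#'
#' Draws condition -> animal -> fiber decay truths per [condition_effects()]
#' and generates one noisy trace per fiber and assay temperature. Every trace
#' is labelled with animal id, condition, fiber type and temperature; the
#' generating truth table is returned beside the traces so parameter-recovery
#' tests can compare estimates with truth.
#'
#' @param design A [study_design()].
#' @param effects A [condition_effects()].
#' @return A list with elements `traces` (long tibble: `fiber_id`,
#'   `animal_id`, `condition`, `fiber_type`, `temperature_C`, `time_s`,
#'   `raw_fluor`, `background_fluor`) and `truth` (one row per fiber with the
#'   generating parameters).
#' @examples
#' sim <- simulate_study(study_design(conditions = c("SA", "torpor"),
#'                                    animals_per_condition = 2,
#'                                    fibers_per_animal = c(3, 3), seed = 7))
#' dplyr::count(sim$truth, condition)
#' @export
simulate_study <- function(design, effects = condition_effects()) {
  if (!inherits(design, "study_design")) abort("`design` must be a study_design().")
  if (!inherits(effects, "condition_effects")) {
    abort("`effects` must be a condition_effects().")
  }
  grid <- seq(0, design$duration_s, by = design$frame_interval_s)
  types <- names(effects$baseline)

  withr::with_seed(design$seed, {
    truth_rows <- list()
    trace_rows <- list()
    k <- 0L
    for (cond in design$conditions) {
      for (a in seq_len(design$animals_per_condition)) {
        animal_id <- sprintf("%s_a%02d", cond, a)
        animal_mult <- exp(rnorm(2, 0, effects$animal_cv))
        animal_shift <- rnorm(1, 0, effects$animal_p1_sd)
        for (temp in design$temperatures_C) {
          temp_eff <- lookup_temperature_mult(effects, temp)
          n_fib <- if (design$fibers_per_animal[1] == design$fibers_per_animal[2]) {
            design$fibers_per_animal[1]
          } else {
            sample(design$fibers_per_animal[1]:design$fibers_per_animal[2], 1L)
          }
          if (n_fib < 1L) abort("zero fibers requested for an animal.")
          for (f in seq_len(n_fib)) {
            k <- k + 1L
            fiber_type <- if (runif(1) < design$fiber_type_prop) "II" else "I"
            if (!fiber_type %in% types) fiber_type <- types[[1]]
            base <- effects$baseline[[fiber_type]]
            cond_eff <- lookup_condition_mult(effects, cond, fiber_type)
            tr <- draw_fiber_truth(base, cond_eff, temp_eff, animal_mult,
                                   animal_shift, effects)
            baseline_fluor <- runif(1, effects$baseline_fluor_range[1],
                                    effects$baseline_fluor_range[2])
            background <- runif(1, effects$background_range[1],
                                effects$background_range[2])
            fiber_id <- sprintf("%s_t%g_f%04d", animal_id, temp, k)
            trace <- simulate_decay(tr, grid, effects$noise_sd,
                                    baseline_fluor, background, seed = NULL)
            truth_rows[[k]] <- tibble(
              fiber_id = fiber_id, animal_id = animal_id, condition = cond,
              fiber_type = fiber_type, temperature_C = temp,
              p1_frac = tr$p1_frac, t1_s = tr$t1_s,
              p2_frac = tr$p2_frac, t2_s = tr$t2_s,
              plateau_frac = tr$plateau_frac,
              baseline_fluor = baseline_fluor, background_level = background,
              noise_sd = effects$noise_sd
            )
            trace_rows[[k]] <- tibble(
              fiber_id = fiber_id, animal_id = animal_id, condition = cond,
              fiber_type = fiber_type, temperature_C = temp,
              time_s = trace$time_s, raw_fluor = trace$raw_fluor,
              background_fluor = trace$background_fluor
            )
          }
        }
      }
    }
    list(traces = list_rbind(trace_rows), truth = list_rbind(truth_rows))
  })
}
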