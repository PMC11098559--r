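#' Myosin ATP consumption of a single fiber
#'
#' Converts the fitted DRX/SRX amplitudes and lifetimes into the ATP
#' consumed by myosin per fiber per minute, assuming a myosin-head
#' concentration of 220 uM inside the fiber:
#' \deqn{(P_1/100)\cdot C \cdot (60/T_1) + (P_2/100)\cdot C \cdot (60/T_2)}
#' with amplitudes in percent, lifetimes in seconds and C the head
#' concentration in uM; the result is in uM ATP per fiber volume per minute.
#'
#' @param p1_pct,t1_s DRX amplitude (percent) and lifetime (s).
#' @param p2_pct,t2_s SRX amplitude (percent) and lifetime (s).
#' @param head_concentration_uM Myosin head concentration, uM.
#' @return Numeric vector, uM ATP min^-1.
#' @examples
#' atp_consumption(100, 60, 0, 200) # full DRX at one turnover/min -> 220
#' @export
atp_consumption <- function(p1_pct, t1_s, p2_pct, t2_s,
                            head_concentration_uM = 220) {
  if (any(t1_s <= 0, na.rm = TRUE) || any(t2_s <= 0, na.rm = TRUE)) {
    abort("lifetimes must be > 0 to compute ATP consumption.")
  }
  (p1_pct / 100) * head_concentration_uM * (60 / t1_s) +
    (p2_pct / 100) * head_concentration_uM * (60 / t2_s)
}

#' Build fiber records from accepted decay fits
#'
#' Joins each accepted fit with its derived ATP consumption, giving the
#' per-fiber analysis table used by the group statistics.
#'
#' @param fits Tibble of fits (e.g. the `accepted` element of
#'   [qc_filter()]); needs `p1_pct`, `t1_s`, `p2_pct`, `t2_s` plus label
#'   columns.
#' @param head_concentration_uM Myosin head concentration, uM.
#' @return The input tibble with an `atp_consumption` column (uM min^-1).
#' @export
fiber_records <- function(fits, head_concentration_uM = 220) {
  assert_columns(fits, c("p1_pct", "t1_s", "p2_pct", "t2_s"), "`fits`")
  mutate(fits, atp_consumption = atp_consumption(
    .data$p1_pct, .data$t1_s, .data$p2_pct, .data$t2_s,
    head_concentration_uM))
}

#' Temperature-sensitivity ratios per matched animal
#'
#' For each animal x condition x fiber type with accepted fibers at both
#' assay temperatures, computes the ratio of animal means (warm / cold) for
#' the DRX lifetime, SRX lifetime and ATP consumption. Animals missing one
#' temperature are omitted with a warning.
#'
#' @param records Fiber records ([fiber_records()]) with `temperature_C`.
#' @param temp_warm,temp_cold The two assay temperatures, degrees C.
#' @return Tibble: `animal_id`, `condition`, `fiber_type`, `ratio_t1`,
#'   `ratio_t2`, `ratio_atp`.
#' @export
temperature_ratios <- function(records, temp_warm = 20, temp_cold = 8) {
  assert_columns(records,
                 c("animal_id", "condition", "fiber_type", "temperature_C",
                   "t1_s", "t2_s", "atp_consumption"), "`records`")
  means <- records |>
    filter(.data$temperature_C %in% c(temp_warm, temp_cold)) |>
    group_by(.data$animal_id, .data$condition, .data$fiber_type,
             .data$temperature_C) |>
    summarise(t1_s = mean(.data$t1_s), t2_s = mean(.data$t2_s),
              atp = mean(.data$atp_consumption), .groups = "drop")
  wide <- means |>
    mutate(which_temp = if_else(.data$temperature_C == temp_warm,
                                "warm", "cold")) |>
    select(-"temperature_C") |>
    pivot_wider(names_from = "which_temp",
                values_from = c("t1_s", "t2_s", "atp"))
  needed <- c("t1_s_warm", "t1_s_cold", "t2_s_warm", "t2_s_cold",
              "atp_warm", "atp_cold")
  for (nm in setdiff(needed, names(wide))) wide[[nm]] <- NA_real_
  incomplete <- !complete.cases(wide[, needed])
  if (any(incomplete)) {
    warn(sprintf(
      "%d animal/fiber-type stratum(-a) lack fibers at both temperatures and were omitted.",
      sum(incomplete)))
  }
  wide |>
    filter(!incomplete) |>
    mutate(ratio_t1 = .data$t1_s_warm / .data$t1_s_cold,
           ratio_t2 = .data$t2_s_warm / .data$t2_s_cold,
           ratio_atp = .data$atp_warm / .data$atp_cold) |>
    select("animal_id", "condition", "fiber_type",
           "ratio_t1", "ratio_t2", "ratio_atp")
}

#' Signed percent difference of group b versus group a
#'
#' `100 * (mean_b - mean_a) / mean_a`; a value 35% *lower* in b than in a is
#' reported as -35.
#'
#' @param mean_a Baseline group mean (must be nonzero).
#' @param mean_b Comparison group mean.
#' @return Percent change of b relative to a.
#' @examples
#' percent_difference(100, 65) # -35
#' @export
percent_difference <- function(mean_a, mean_b) {
  if (any(mean_a == 0)) abort("baseline mean is zero; percent difference undefined.")
  100 * (mean_b - mean_a) / mean_a
}
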