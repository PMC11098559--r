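#' Double-exponential Mant-ATP chase decay model
#'
#' Normalized fluorescence of a loaded Mant-ATP chase as a function of time
#' since washout:
#' \deqn{F(t) = 1 - P_1 (1 - e^{-t/T_1}) - P_2 (1 - e^{-t/T_2})}
#' where `p1` is the amplitude fraction of the fast (DRX, disordered-relaxed)
#' component with lifetime `t1` seconds, and `p2`/`t2` describe the slow
#' (SRX, super-relaxed) component. The remainder `1 - p1 - p2` is a
#' non-exchanging plateau. By construction `F(0) = 1` for any parameters.
#'
#' @param time_s Numeric vector of times since washout, seconds.
#' @param p1,p2 Amplitude fractions (not percent) of the fast and slow
#'   components.
#' @param t1,t2 Lifetimes in seconds of the fast and slow components.
#' @return Numeric vector of normalized fluorescence values.
#' @examples
#' mant_decay_model(c(0, 15, 300), p1 = 0.25, t1 = 15, p2 = 0.5, t2 = 200)
#' @export
mant_decay_model <- function(time_s, p1, t1, p2, t2) {
  1 - p1 * (1 - exp(-time_s / t1)) - p2 * (1 - exp(-time_s / t2))
}

#' Construct and validate decay truth parameters
#'
#' A `decay_truth` records the generating parameters of one fiber's decay:
#' the DRX amplitude fraction and lifetime, the SRX amplitude fraction and
#' lifetime, and (implicitly) the non-exchanging plateau `1 - p1 - p2`.
#'
#' @param p1_frac DRX amplitude fraction in \[0, 1\].
#' @param t1_s DRX lifetime, seconds (> 0).
#' @param p2_frac SRX amplitude fraction in \[0, 1\].
#' @param t2_s SRX lifetime, seconds; must exceed `t1_s`.
#' @return A `decay_truth` list with fields `p1_frac`, `t1_s`, `p2_frac`,
#'   `t2_s`, `plateau_frac`.
#' @export
decay_truth <- function(p1_frac, t1_s, p2_frac, t2_s) {
  assert_number(p1_frac, "p1_frac", lower = 0, upper = 1)
  assert_number(p2_frac, "p2_frac", lower = 0, upper = 1)
  assert_number(t1_s, "t1_s", lower = 0, strict_lower = TRUE)
  assert_number(t2_s, "t2_s", lower = 0, strict_lower = TRUE)
  if (p1_frac + p2_frac > 1 + 1e-12) {
    abort("invalid decay truth: p1_frac + p2_frac must be <= 1.")
  }
  if (t1_s >= t2_s) {
    abort("invalid decay truth: t1_s must be < t2_s (DRX is the faster component).")
  }
  structure(
    list(p1_frac = p1_frac, t1_s = t1_s, p2_frac = p2_frac, t2_s = t2_s,
         plateau_frac = 1 - p1_frac - p2_frac),
    class = "decay_truth"
  )
}

#' @export
print.decay_truth <- function(x, ...) {
  cat(sprintf(
    "<decay_truth> DRX %.1f%% / T1 %.3g s, SRX %.1f%% / T2 %.3g s, plateau %.1f%%\n",
    100 * x$p1_frac, x$t1_s, 100 * x$p2_frac, x$t2_s, 100 * x$plateau_frac))
  invisible(x)
}
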