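#' Extract fiber and background traces from an image stack
#'
#' Per frame, every fiber ROI is averaged and the fiber trace is the mean of
#' those ROI means (the conventional average over the three sampled regions
#' of a fiber); the background trace is the mean over the background ROI(s).
#'
#' @param stack Array `frames x rows x cols`, or the list returned by
#'   [simulate_image_stack()].
#' @param roi_geometry ROI masks (`fiber`, `background` lists of logical
#'   matrices); taken from the stack object if omitted.
#' @param time_s Frame times in seconds; taken from the stack object if
#'   omitted, otherwise frame index is used.
#' @return A trace tibble with columns `time_s`, `raw_fluor`,
#'   `background_fluor`.
#' @export
extract_roi_traces <- function(stack, roi_geometry = NULL, time_s = NULL) {
  if (is.list(stack) && !is.null(stack$stack)) {
    roi_geometry <- roi_geometry %||% stack$roi_geometry
    time_s <- time_s %||% stack$time_s
    stack <- stack$stack
  }
  if (length(dim(stack)) != 3L) abort("`stack` must be a frames x rows x cols array.")
  frame_shape <- dim(stack)[2:3]
  check_roi_geometry(roi_geometry, frame_shape)
  nf <- dim(stack)[1]
  time_s <- time_s %||% seq_len(nf) - 1
  if (length(time_s) != nf) abort("`time_s` length must match the number of frames.")

  bad <- which(apply(stack, 1, function(fr) any(!is.finite(fr))))
  if (length(bad)) {
    abort(sprintf("non-finite pixel value(s) in frame(s): %s",
                  paste(bad, collapse = ", ")))
  }
  roi_mean <- function(mask) {
    apply(stack, 1, function(fr) mean(fr[mask]))
  }
  fiber_means <- vapply(roi_geometry$fiber, roi_mean, numeric(nf))
  bg_means <- vapply(roi_geometry$background, roi_mean, numeric(nf))
  tibble(
    time_s = time_s,
    raw_fluor = rowMeans(as.matrix(fiber_means)),
    background_fluor = rowMeans(as.matrix(bg_means))
  )
}

#' Background-correct and normalize a fluorescence trace
#'
#' Subtracts the background trace from the fiber trace frame by frame, then
#' divides by the background-corrected intensity of the final image before
#' washout (t = 0), so the output is exactly 1 at t = 0.
#'
#' @param trace Tibble with columns `time_s`, `raw_fluor`,
#'   `background_fluor`; `time_s[1]` must be 0.
#' @return Tibble `time_s`, `norm_fluor`.
#' @examples
#' tr <- simulate_decay(decay_truth(0.25, 15, 0.5, 200), seed = 1)
#' nd <- normalize_trace(tr)
#' nd$norm_fluor[1] # exactly 1
#' @export
normalize_trace <- function(trace) {
  assert_columns(trace, c("time_s", "raw_fluor", "background_fluor"), "`trace`")
  if (trace$time_s[1] != 0) abort("`trace` must start at time_s = 0 (washout frame).")
  if (any(diff(trace$time_s) <= 0)) abort("`time_s` must be strictly increasing.")
  corrected <- trace$raw_fluor - trace$background_fluor
  if (!is.finite(corrected[1]) || corrected[1] <= 0) {
    abort("background-corrected intensity at t = 0 is not positive; fiber unusable.")
  }
  tibble(time_s = trace$time_s, norm_fluor = corrected / corrected[1])
}

# Residual sum of squares of the decay model at (t1, t2), with the
# amplitudes profiled out by linear least squares (the model is linear in
# p1, p2 once the lifetimes are fixed). Returns rss and the solved
# amplitudes.
profile_amplitudes <- function(time_s, y, t1, t2) {
  a <- 1 - exp(-time_s / t1)
  b <- 1 - exp(-time_s / t2)
  z <- 1 - y
  s11 <- sum(a * a); s12 <- sum(a * b); s22 <- sum(b * b)
  r1 <- sum(a * z); r2 <- sum(b * z)
  det <- s11 * s22 - s12 * s12
  if (!is.finite(det) || det < 1e-12 * max(s11 * s22, 1e-300)) {
    # near-collinear basis (t1 ~ t2): fall back to a single component
    p <- if (s11 > 0) r1 / s11 else 0
    return(list(p1 = p, p2 = 0, rss = sum((z - p * a)^2)))
  }
  p1 <- (s22 * r1 - s12 * r2) / det
  p2 <- (s11 * r2 - s12 * r1) / det
  list(p1 = p1, p2 = p2, rss = sum((z - p1 * a - p2 * b)^2))
}

#' Fitting options for [fit_decay()]
#'
#' @param t1_starts,t2_starts Multi-start grids for the fast and slow
#'   lifetimes, seconds; every pairwise combination is tried and the best
#'   residual sum of squares wins.
#' @param unconstrained If `TRUE`, the final refinement places no box
#'   constraints on the parameters; the default uses loose boxes
#'   (amplitude fractions in \[-0.1, 1.2\], lifetimes in \[0.1, 5000\] s)
#'   to keep noisy traces away from pathological optima.
#' @param lifetime_ratio_flag Flag `LIFETIMES_CLOSE` when the fitted slow/
#'   fast lifetime ratio is below this and their confidence intervals
#'   overlap.
#' @param tol Relative convergence tolerance on parameters and objective.
#' @param max_eval Maximum function evaluations per start.
#' @return A list of options.
#' @export
fit_options <- function(t1_starts = c(2, 10, 30),
                        t2_starts = c(100, 200, 400),
                        unconstrained = FALSE,
                        lifetime_ratio_flag = 5,
                        tol = 1e-10,
                        max_eval = 10000) {
  list(t1_starts = t1_starts, t2_starts = t2_starts,
       unconstrained = unconstrained,
       lifetime_ratio_flag = lifetime_ratio_flag,
       tol = tol, max_eval = max_eval)
}

#' Fit the double-exponential Mant-ATP chase model
#'
#' Nonlinear least squares for
#' `norm_fluor ~ 1 - P1*(1 - exp(-t/T1)) - P2*(1 - exp(-t/T2))`.
#' The lifetimes are optimized on the log scale over a multi-start grid with
#' the amplitudes profiled out linearly at each step, then all four
#' parameters are refined by Levenberg-Marquardt. Components are relabelled
#' post hoc so the faster lifetime is always reported as (P1, T1) = DRX and
#' the slower as (P2, T2) = SRX; amplitudes are reported in percent.
#'
#' @param decay Normalized decay tibble (`time_s`, `norm_fluor`) from
#'   [normalize_trace()], with at least 8 time points.
#' @param options A [fit_options()] list.
#' @return A `decay_fit` object with fields `p1_pct`, `t1_s`, `p2_pct`,
#'   `t2_s`, `se` (named vector of standard errors), `rss`, `converged`,
#'   `qc_flags`, `n`, and the input `data`. Use [tidy()]/[glance()] to get
#'   tibbles and [autoplot()] for a diagnostic plot.
#' @examples
#' nd <- normalize_trace(simulate_decay(decay_truth(0.25, 15, 0.5, 200),
#'                                      noise_sd = 0, seed = 1))
#' fit <- fit_decay(nd)
#' glance(fit)
#' @export
fit_decay <- function(decay, options = fit_options()) {
  assert_columns(decay, c("time_s", "norm_fluor"), "`decay`")
  if (nrow(decay) < 8L) abort("need at least 8 time points to fit the decay.")
  if (any(!is.finite(decay$norm_fluor))) abort("`norm_fluor` contains non-finite values.")
  tt <- decay$time_s
  y <- decay$norm_fluor

  # multi-start outer optimization over log-lifetimes
  obj <- function(lg) profile_amplitudes(tt, y, exp(lg[1]), exp(lg[2]))$rss
  lb <- log(0.1); ub <- log(5000)
  best <- NULL
  for (t1s in options$t1_starts) {
    for (t2s in options$t2_starts) {
      res <- tryCatch(
        nlminb(c(log(t1s), log(t2s)), obj, lower = lb, upper = ub,
               control = list(rel.tol = options$tol,
                              eval.max = options$max_eval,
                              iter.max = options$max_eval)),
        error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$objective < best$objective)) {
        best <- res
      }
    }
  }
  if (is.null(best)) {
    return(new_decay_fit(NA, NA, NA, NA, se = rep(NA_real_, 4), rss = NA,
                         converged = FALSE, qc_flags = "NONCONVERGED",
                         data = decay))
  }
  t1 <- exp(best$par[1]); t2 <- exp(best$par[2])
  amps <- profile_amplitudes(tt, y, t1, t2)
  p1 <- amps$p1; p2 <- amps$p2; rss <- amps$rss
  converged <- best$convergence == 0

  # Levenberg-Marquardt refinement of all four parameters + curvature SEs
  se <- rep(NA_real_, 4)
  start <- list(p1 = p1, t1 = t1, p2 = p2, t2 = t2)
  ctrl <- minpack.lm::nls.lm.control(ftol = options$tol, ptol = options$tol,
                                     maxfev = options$max_eval, maxiter = 1000)
  fit_nls <- tryCatch(suppressWarnings({
    if (options$unconstrained) {
      minpack.lm::nlsLM(norm_fluor ~ 1 - p1 * (1 - exp(-time_s / t1)) -
                          p2 * (1 - exp(-time_s / t2)),
                        data = decay, start = start, control = ctrl)
    } else {
      minpack.lm::nlsLM(norm_fluor ~ 1 - p1 * (1 - exp(-time_s / t1)) -
                          p2 * (1 - exp(-time_s / t2)),
                        data = decay, start = start,
                        lower = c(-0.1, 0.1, -0.1, 0.1),
                        upper = c(1.2, 5000, 1.2, 5000), control = ctrl)
    }
  }), error = function(e) NULL)
  if (!is.null(fit_nls)) {
    cf <- coef(fit_nls)
    rss_nls <- sum(stats::resid(fit_nls)^2)
    if (is.finite(rss_nls) && rss_nls <= rss + 1e-12) {
      p1 <- cf[["p1"]]; t1 <- cf[["t1"]]; p2 <- cf[["p2"]]; t2 <- cf[["t2"]]
      rss <- rss_nls
      converged <- TRUE
    }
    se_try <- tryCatch(suppressWarnings(
      sqrt(diag(vcov(fit_nls)))[c("p1", "t1", "p2", "t2")]),
      error = function(e) rep(NA_real_, 4))
    se <- unname(se_try)
  }

  # label the faster component DRX
  if (t1 > t2) {
    tmp <- c(p1, t1); p1 <- p2; t1 <- t2; p2 <- tmp[1]; t2 <- tmp[2]
    se <- se[c(3, 4, 1, 2)]
  }

  flags <- character(0)
  if (!converged) flags <- c(flags, "NONCONVERGED")
  if (is.finite(p1) && is.finite(p2) && p1 + p2 > 1) {
    flags <- c(flags, "AMPLITUDE_SUM_GT_100")
  }
  if (min(abs(p1), abs(p2)) < 0.01) flags <- c(flags, "DEGENERATE_COMPONENT")
  ratio_close <- t2 / t1 < options$lifetime_ratio_flag
  ci_overlap <- if (all(is.finite(se[c(2, 4)]))) {
    (t1 + 1.96 * se[2]) > (t2 - 1.96 * se[4])
  } else {
    TRUE  # no curvature information: do not rule overlap out
  }
  if (ratio_close && ci_overlap) flags <- c(flags, "LIFETIMES_CLOSE")

  new_decay_fit(p1, t1, p2, t2, se = se, rss = rss, converged = converged,
                qc_flags = flags, data = decay)
}

new_decay_fit <- function(p1, t1, p2, t2, se, rss, converged, qc_flags, data) {
  structure(
    list(p1_pct = 100 * p1, t1_s = t1, p2_pct = 100 * p2, t2_s = t2,
         se = setNames(c(100 * se[1], se[2], 100 * se[3], se[4]),
                       c("p1_pct", "t1_s", "p2_pct", "t2_s")),
         rss = rss, converged = converged, qc_flags = qc_flags,
         n = nrow(data), data = data),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (!x$converged && !is.finite(x$t1_s %||% NA)) {
    cat("<decay_fit> NOT CONVERGED\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<decay_fit> DRX P1 = %.1f%%, T1 = %.3g s | SRX P2 = %.1f%%, T2 = %.3g s\n",
    x$p1_pct, x$t1_s, x$p2_pct, x$t2_s))
  cat(sprintf("  rss = %.3g over %d frames; converged: %s%s\n", x$rss, x$n,
              x$converged,
              if (length(x$qc_flags)) paste0("; flags: ",
                                             paste(x$qc_flags, collapse = ", "))
              else ""))
  invisible(x)
}

#' Tidiers and diagnostics for decay fits
#'
#' `tidy()` returns the parameter table (term, estimate, std.error),
#' `glance()` a one-row fit summary, `autoplot()` a data-plus-fitted-curve
#' diagnostic plot.
#'
#' @param x,object A `decay_fit` from [fit_decay()].
#' @param ... Unused.
#' @return A tibble (`tidy`, `glance`) or a ggplot (`autoplot`).
#' @name decay_fit_methods
NULL

#' @rdname decay_fit_methods
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("p1_pct", "t1_s", "p2_pct", "t2_s"),
         estimate = c(x$p1_pct, x$t1_s, x$p2_pct, x$t2_s),
         std.error = unname(x$se))
}

#' @rdname decay_fit_methods
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(p1_pct = x$p1_pct, t1_s = x$t1_s, p2_pct = x$p2_pct, t2_s = x$t2_s,
         se_p1_pct = x$se[["p1_pct"]], se_t1_s = x$se[["t1_s"]],
         se_p2_pct = x$se[["p2_pct"]], se_t2_s = x$se[["t2_s"]],
         rss = x$rss, n = x$n, converged = x$converged,
         qc_flags = paste(x$qc_flags, collapse = ";"))
}

#' @rdname decay_fit_methods
#' @export
autoplot.decay_fit <- function(object, ...) {
  d <- object$data
  curve <- tibble(
    time_s = seq(min(d$time_s), max(d$time_s), length.out = 200),
    norm_fluor = mant_decay_model(
      seq(min(d$time_s), max(d$time_s), length.out = 200),
      object$p1_pct / 100, object$t1_s, object$p2_pct / 100, object$t2_s))
  ggplot(d, aes(x = .data$time_s, y = .data$norm_fluor)) +
    geom_point(alpha = 0.6) +
    geom_line(data = curve, colour = "firebrick") +
    labs(x = "Time since washout (s)", y = "Normalized fluorescence",
         title = sprintf("DRX %.0f%% / %.3g s, SRX %.0f%% / %.3g s",
                         object$p1_pct, object$t1_s,
                         object$p2_pct, object$t2_s)) +
    theme_bw()
}

#' Fit every fiber in a long trace table
#'
#' Normalizes and fits each fiber's trace, returning one row per fiber with
#' the fit parameters, standard errors, QC flags and the fiber's labels.
#' Fibers whose normalization fails (non-positive corrected t = 0 intensity)
#' are returned with `converged = FALSE` and flag `NORMALIZATION_FAILED`.
#'
#' @param traces Long tibble with columns `fiber_id`, `time_s`, `raw_fluor`,
#'   `background_fluor` and any label columns (carried through).
#' @param options A [fit_options()] list.
#' @return Tibble, one row per fiber.
#' @export
fit_decay_all <- function(traces, options = fit_options()) {
  assert_columns(traces, c("fiber_id", "time_s", "raw_fluor", "background_fluor"),
                 "`traces`")
  label_cols <- intersect(c("animal_id", "condition", "fiber_type",
                            "temperature_C"), names(traces))
  traces |>
    group_by(.data$fiber_id) |>
    tidyr::nest() |>
    ungroup() |>
    mutate(fit = map(.data$data, function(d) {
      labels <- d[1, label_cols, drop = FALSE]
      g <- tryCatch({
        nd <- normalize_trace(d)
        glance(fit_decay(nd, options))
      }, error = function(e) {
        tibble(p1_pct = NA_real_, t1_s = NA_real_, p2_pct = NA_real_,
               t2_s = NA_real_, se_p1_pct = NA_real_, se_t1_s = NA_real_,
               se_p2_pct = NA_real_, se_t2_s = NA_real_,
               rss = NA_real_, n = nrow(d),
               converged = FALSE, qc_flags = "NORMALIZATION_FAILED")
      })
      bind_cols(labels, g)
    })) |>
    select("fiber_id", "fit") |>
    tidyr::unnest("fit")
}

#' Default QC thresholds for decay fits
#'
#' @param require_converged Reject non-converged fits.
#' @param max_rel_se_t2 Maximum relative standard error of the SRX lifetime.
#' @param reject_flags QC flags that trigger rejection.
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(require_converged = TRUE,
                          max_rel_se_t2 = 0.5,
                          reject_flags = "NORMALIZATION_FAILED") {
  list(require_converged = require_converged,
       max_rel_se_t2 = max_rel_se_t2,
       reject_flags = reject_flags)
}

#' Partition decay fits into accepted and rejected sets
#'
#' Deterministic rule-based filter; every rejected fiber carries a
#' machine-readable reason.
#'
#' @param fits Tibble from [fit_decay_all()] (needs `converged`, `qc_flags`,
#'   and — if the SE rule is active — `se_t2_s`).
#' @param thresholds A [qc_thresholds()] list.
#' @return List with tibbles `accepted` and `rejected` (the latter with a
#'   `reason` column).
#' @export
qc_filter <- function(fits, thresholds = qc_thresholds()) {
  assert_columns(fits, c("converged", "qc_flags"), "`fits`")
  reason <- rep(NA_character_, nrow(fits))
  if (thresholds$require_converged) {
    reason[!fits$converged & is.na(reason)] <- "NONCONVERGED"
  }
  for (fl in thresholds$reject_flags) {
    hit <- grepl(fl, fits$qc_flags, fixed = TRUE) & is.na(reason)
    reason[hit] <- fl
  }
  if (is.finite(thresholds$max_rel_se_t2) && "se_t2_s" %in% names(fits)) {
    rel <- fits$se_t2_s / fits$t2_s
    hit <- !is.na(rel) & rel > thresholds$max_rel_se_t2 & is.na(reason)
    reason[hit] <- sprintf("REL_SE_T2_GT_%g", thresholds$max_rel_se_t2)
  }
  list(accepted = fits[is.na(reason), , drop = FALSE],
       rejected = bind_cols(fits[!is.na(reason), , drop = FALSE],
                            tibble(reason = reason[!is.na(reason)])))
}
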