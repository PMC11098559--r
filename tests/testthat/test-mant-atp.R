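test_that("ROI extraction recovers traces and rejects broken stacks", {
  # all-constant stack -> flat trace
  geom <- default_roi_geometry(c(16, 16))
  stack <- array(7, dim = c(5, 16, 16))
  tr <- extract_roi_traces(stack, geom, time_s = seq(0, 20, by = 5))
  expect_equal(tr$raw_fluor, rep(7, 5))
  expect_equal(tr$background_fluor, rep(7, 5))

  # NaN pixel -> error reporting the frame index
  stack[3, 2, 2] <- NaN
  expect_error(extract_roi_traces(stack, geom), "frame\\(s\\): 3")

  # mask/stack shape mismatch
  expect_error(extract_roi_traces(array(1, dim = c(5, 8, 8)), geom),
               "frame_shape")
  # empty mask
  geom2 <- geom
  geom2$fiber$roi1[] <- FALSE
  expect_error(extract_roi_traces(array(1, dim = c(5, 16, 16)), geom2), "empty")
})

test_that("normalization subtracts background and scales by the t = 0 frame", {
  grid <- seq(0, 300, by = 5)
  model <- mant_decay_model(grid, 0.25, 15, 0.5, 200)
  # affine cancellation: raw = 100*model + 20 with background 20
  tr <- tibble::tibble(time_s = grid, raw_fluor = 100 * model + 20,
                       background_fluor = 20)
  expect_equal(normalize_trace(tr)$norm_fluor, model, tolerance = 1e-12)

  # hand division: corrected 80 at t=0 and 20 at t=300 -> 0.25
  tr2 <- tibble::tibble(time_s = c(0, 300),
                        raw_fluor = c(100, 40), background_fluor = c(20, 20))
  expect_equal(normalize_trace(tr2)$norm_fluor[2], 0.25)

  # non-positive corrected t = 0 intensity is unusable
  tr3 <- tibble::tibble(time_s = grid, raw_fluor = 20, background_fluor = 20)
  expect_error(normalize_trace(tr3), "not positive")
})

test_that("noiseless double-exponential fits recover truth to 1e-6 relative", {
  fit <- fit_decay(noiseless_decay())
  expect_true(fit$converged)
  expect_equal(fit$p1_pct, 25, tolerance = 1e-6)
  expect_equal(fit$t1_s, 15, tolerance = 1e-6)
  expect_equal(fit$p2_pct, 50, tolerance = 1e-6)
  expect_equal(fit$t2_s, 200, tolerance = 1e-6)
  # optimality: objective at the fit cannot exceed the objective at truth
  expect_lte(fit$rss, sum((noiseless_decay()$norm_fluor -
                             mant_decay_model(noiseless_decay()$time_s,
                                              0.25, 15, 0.5, 200))^2) + 1e-15)
})

test_that("a pure single exponential yields a degenerate second component", {
  nd <- normalize_trace(simulate_decay(decay_truth(0.45, 20, 0, 500),
                                       noise_sd = 0, seed = 3))
  fit <- fit_decay(nd)
  # independent single-exponential oracle
  oracle <- stats::nls(norm_fluor ~ 1 - p * (1 - exp(-time_s / tau)),
                       data = nd, start = list(p = 0.45, tau = 25),
                       algorithm = "port",
                       control = stats::nls.control(maxiter = 500))
  # the dominant fitted component matches the oracle; the other collapses
  if (abs(fit$p1_pct) >= abs(fit$p2_pct)) {
    dom_p <- fit$p1_pct; dom_t <- fit$t1_s
  } else {
    dom_p <- fit$p2_pct; dom_t <- fit$t2_s
  }
  expect_equal(dom_p, 100 * coef(oracle)[["p"]], tolerance = 1e-3)
  expect_equal(dom_t, coef(oracle)[["tau"]], tolerance = 1e-3)
  expect_lt(min(abs(fit$p2_pct), abs(fit$p1_pct)), 1)
  expect_true(any(c("DEGENERATE_COMPONENT", "LIFETIMES_CLOSE") %in% fit$qc_flags))
})

test_that("a constant trace fits with both amplitudes near zero and is flagged", {
  nd <- tibble::tibble(time_s = seq(0, 300, 5), norm_fluor = 1)
  fit <- fit_decay(nd)
  expect_lt(abs(fit$p1_pct), 1e-6)
  expect_lt(abs(fit$p2_pct), 1e-6)
  expect_true("DEGENERATE_COMPONENT" %in% fit$qc_flags)
})

test_that("DRX labelling is invariant to the ordering of the start grid", {
  nd <- normalize_trace(simulate_decay(decay_truth(0.25, 15, 0.5, 200),
                                       noise_sd = 0.01, seed = 7))
  f1 <- fit_decay(nd, fit_options(t1_starts = c(2, 10, 30),
                                  t2_starts = c(100, 200, 400)))
  f2 <- fit_decay(nd, fit_options(t1_starts = c(400, 200, 100),
                                  t2_starts = c(30, 10, 2)))
  expect_lt(f1$t1_s, f1$t2_s)
  expect_lt(f2$t1_s, f2$t2_s)
  expect_equal(f1$t1_s, f2$t1_s, tolerance = 1e-6)
  expect_equal(f1$p1_pct, f2$p1_pct, tolerance = 1e-6)
})

test_that("noisy replicate fits are efficient relative to the information bound", {
  # Independent oracle: the Cramér-Rao bound at truth from a numerical
  # Jacobian. For an (approximately) unbiased efficient estimator the
  # median absolute relative error is 0.674 * relative SE; we allow 25%
  # slack for Monte-Carlo error and nonlinearity.
  grid <- seq(0, 300, 5)
  truth <- c(p1 = 0.25, t1 = 15, p2 = 0.5, t2 = 200)
  model_at <- function(p) mant_decay_model(grid, p[1], p[2], p[3], p[4])
  J <- vapply(1:4, function(k) {
    h <- truth[k] * 1e-6
    pp <- truth; pm <- truth
    pp[k] <- pp[k] + h; pm[k] <- pm[k] - h
    (model_at(pp) - model_at(pm)) / (2 * h)
  }, numeric(length(grid)))
  rel_se <- sqrt(diag(solve(crossprod(J)))) * 0.01 / truth
  bound <- 0.674 * rel_se

  model <- model_at(truth)
  errs <- t(vapply(1:100, function(i) {
    nd <- withr::with_seed(i, tibble::tibble(
      time_s = grid, norm_fluor = model + rnorm(length(grid), 0, 0.01)))
    f <- fit_decay(nd)
    abs(c(f$p1_pct / 100, f$t1_s, f$p2_pct / 100, f$t2_s) - truth) / truth
  }, numeric(4)))
  med <- apply(errs, 2, median)
  expect_true(all(med < 1.25 * bound))
})

test_that("QC filter partitions deterministically with machine-readable reasons", {
  fits <- tibble::tibble(
    fiber_id = c("a", "b", "c", "d"),
    t2_s = c(200, 210, 190, 205),
    se_t2_s = c(10, 10, 150, 10),
    converged = c(TRUE, FALSE, TRUE, TRUE),
    qc_flags = c("", "NONCONVERGED", "", "NORMALIZATION_FAILED"))
  part <- qc_filter(fits, qc_thresholds(max_rel_se_t2 = 0.5))
  expect_equal(part$accepted$fiber_id, "a")
  expect_setequal(part$rejected$reason,
                  c("NONCONVERGED", "REL_SE_T2_GT_0.5", "NORMALIZATION_FAILED"))

  clean <- dplyr::mutate(fits[1, ], converged = TRUE)
  expect_equal(nrow(qc_filter(clean)$rejected), 0)
})
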