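#' Aggregate fiber records to animal means
#'
#' Group comparisons are performed on animal means (one value per animal per
#' stratum), not on pooled fibers, to respect the hierarchical design. One
#' row is produced per animal x condition x fiber type x temperature with
#' the unweighted mean and SD of every metric present.
#'
#' @param records Fiber records tibble; metrics among `p1_pct`, `p2_pct`,
#'   `t1_s`, `t2_s`, `atp_consumption` are summarised.
#' @return Tibble of animal summaries with `n_fibers` and `mean_*` / `sd_*`
#'   columns.
#' @export
aggregate_by_animal <- function(records) {
  assert_columns(records, c("animal_id"), "`records`")
  metrics <- intersect(c("p1_pct", "p2_pct", "t1_s", "t2_s", "atp_consumption"),
                       names(records))
  if (!length(metrics)) abort("`records` contains no recognised metric columns.")
  keys <- intersect(c("animal_id", "condition", "fiber_type", "temperature_C"),
                    names(records))
  records |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(n_fibers = dplyr::n(),
              across(dplyr::all_of(metrics),
                     list(mean = ~mean(.x), sd = ~sd(.x)),
                     .names = "{.fn}_{.col}"),
              .groups = "drop")
}

#' Classical one-way ANOVA on animal means
#'
#' Fixed-effects one-way analysis of variance (equal-variance F test) of a
#' metric across condition groups, intended to be run on animal summaries.
#'
#' @param data Data frame of (animal-level) values.
#' @param value Name of the numeric response column (string).
#' @param group Name of the grouping column (string).
#' @return One-row tibble: `test`, `statistic` (F), `df1`, `df2`, `p_value`,
#'   `stars`.
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
#' one_way_anova(d, "y", "g")
#' @export
one_way_anova <- function(data, value, group) {
  assert_columns(data, c(value, group), "`data`")
  y <- data[[value]]
  g <- factor(data[[group]])
  sizes <- table(g)
  if (length(sizes) < 2L) abort("one-way ANOVA needs at least 2 groups.")
  if (any(sizes < 2L)) abort("every group needs at least 2 values.")
  res <- oneway.test(y ~ g, var.equal = TRUE)
  f <- unname(res$statistic)
  p <- unname(res$p.value)
  if (!is.finite(f)) { f <- 0; p <- 1 }  # zero-variance degenerate input
  tibble(test = "one-way ANOVA", statistic = f,
         df1 = unname(res$parameter[1]), df2 = unname(res$parameter[2]),
         p_value = p, stars = p_stars(p))
}

#' Sidak multiplicity adjustment
#'
#' Adjusted p-value for a family of `m` comparisons:
#' \eqn{p' = 1 - (1 - p)^m}, capped at 1.
#'
#' @param p Raw p-value(s).
#' @param m Family size (>= 1); defaults to `length(p)`.
#' @return Adjusted p-values.
#' @examples
#' sidak_adjust(0.05, m = 3) # 0.142625
#' @export
sidak_adjust <- function(p, m = length(p)) {
  if (any(m < 1)) abort("`m` must be >= 1.")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  pmin(1, 1 - (1 - p)^m)
}

#' Pairwise comparisons with Sidak correction
#'
#' Pooled-variance two-sample t-tests for every pair of groups, with Sidak
#' adjustment over the family of all pairs.
#'
#' @param data Data frame of values.
#' @param value,group Column names (strings) of the response and grouping
#'   variable.
#' @return Tibble with one row per pair: `group_a`, `group_b`, `estimate`
#'   (mean b - mean a), `statistic`, `df`, `p_value`, `p_adj`, `stars`.
#' @export
sidak_pairwise <- function(data, value, group) {
  assert_columns(data, c(value, group), "`data`")
  g <- factor(data[[group]])
  lev <- levels(g)
  if (length(lev) < 2L) abort("need at least 2 groups for pairwise comparisons.")
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- map(pairs, function(pr) {
    ya <- data[[value]][g == pr[1]]
    yb <- data[[value]][g == pr[2]]
    tt <- t.test(yb, ya, var.equal = TRUE)
    tibble(group_a = pr[1], group_b = pr[2],
           estimate = mean(yb) - mean(ya),
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = unname(tt$p.value))
  })
  out <- list_rbind(rows)
  out$p_adj <- sidak_adjust(out$p_value, m = nrow(out))
  out$stars <- p_stars(out$p_adj)
  out
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Fits `value ~ A * B` and reports the type-II ANOVA table (a standard
#' choice for mildly unbalanced layouts; type II reduces to the classical
#' decomposition when the design is balanced). Pairwise follow-ups should be
#' routed through [sidak_pairwise()].
#'
#' @param data Data frame.
#' @param value,factor_a,factor_b Column names (strings).
#' @return Tibble: `term`, `sumsq`, `df`, `statistic` (F), `p_value`,
#'   `stars`.
#' @export
two_way_anova <- function(data, value, factor_a, factor_b) {
  assert_columns(data, c(value, factor_a, factor_b), "`data`")
  fa <- factor(data[[factor_a]])
  fb <- factor(data[[factor_b]])
  if (nlevels(fa) < 2L || nlevels(fb) < 2L) {
    abort("both factors need at least 2 levels.")
  }
  df <- data.frame(.y = data[[value]], .a = fa, .b = fb)
  fit <- lm(.y ~ .a * .b, data = df)
  tab <- tryCatch(suppressWarnings(car::Anova(fit, type = "II")),
                  error = function(e) NULL)
  if (is.null(tab)) {
    # zero residual variance (e.g. constant data): fall back to the
    # sequential table, identical here since all sums of squares vanish
    tab <- suppressWarnings(anova(fit))
  }
  terms <- rownames(tab)
  keep <- terms != "Residuals"
  f <- tab[keep, "F value"]
  p <- tab[keep, "Pr(>F)"]
  ss <- tab[keep, "Sum Sq"]
  # (near-)constant response: every sum of squares is numerical fuzz and the
  # 0/0 F statistics are reported as 0 with p = 1
  total_ss <- sum((df$.y - mean(df$.y))^2)
  if (total_ss < 1e-12 * max(1, mean(df$.y)^2) * length(df$.y)) {
    f[] <- 0; p[] <- 1
  } else {
    degenerate <- !is.finite(f) & ss < 1e-12 * total_ss
    f[degenerate] <- 0; p[degenerate] <- 1
  }
  pretty <- c(".a" = factor_a, ".b" = factor_b,
              ".a:.b" = paste0(factor_a, ":", factor_b))
  tibble(term = unname(pretty[terms[keep]]), sumsq = ss,
         df = tab[keep, "Df"], statistic = f, p_value = p,
         stars = p_stars(p))
}
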