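#' Simulate a proteomics-style abundance matrix
#'
#' Generates log-normal protein (or PTM-site) abundances across sample
#' groups: each feature gets a baseline log2 abundance, a designated
#' fraction of features is differentially expressed with a fixed log2
#' fold-change in one group, and missingness is left-censored — the
#' probability of a missing cell rises as abundance falls, the situation
#' MinProb-style imputation is designed for.
#'
#' @param n_features Number of features (rows).
#' @param groups Named integer vector of group sizes, e.g.
#'   `c(SA = 5, torpor = 5)`; every group needs >= 2 samples.
#' @param de_fraction Fraction of features that are truly differential.
#' @param log2_fc Absolute log2 fold-change applied to DE features in
#'   `de_group` (sign drawn half up / half down).
#' @param de_group Group receiving the shift; default the last group.
#' @param baseline_mean,baseline_sd Mean and SD of the feature baseline
#'   log2 abundances.
#' @param sample_sd Within-group Gaussian SD on the log2 scale.
#' @param missingness `NULL` for complete data, or a list with
#'   `censor_quantile` (abundance quantile at which missingness reaches 50%)
#'   and `scale` (logistic steepness, log2 units).
#' @param seed Integer seed.
#' @return An `abundance_matrix`: list with `mat` (features x samples, log2
#'   scale, `NA` = missing), `samples` (tibble `sample_id`, `group`),
#'   `scale = "log2"`, and `truth` (tibble `feature_id`, `is_de`,
#'   `log2_fc`, `de_group`).
#' @examples
#' am <- simulate_abundance_matrix(n_features = 100, seed = 1)
#' table(am$truth$is_de)
#' @export
simulate_abundance_matrix <- function(n_features = 1000,
                                      groups = c(SA = 5, torpor = 5),
                                      de_fraction = 0.1,
                                      log2_fc = 2,
                                      de_group = names(groups)[length(groups)],
                                      baseline_mean = 25, baseline_sd = 2.5,
                                      sample_sd = 0.5,
                                      missingness = NULL,
                                      seed = 1L) {
  if (is.null(names(groups)) || any(groups < 2)) {
    abort("`groups` must be a named vector with every group size >= 2.")
  }
  assert_number(de_fraction, "de_fraction", lower = 0, upper = 1)
  if (!de_group %in% names(groups)) abort("`de_group` must name one of `groups`.")
  withr::with_seed(as.integer(seed), {
    sample_ids <- unlist(lapply(names(groups), function(g) {
      sprintf("%s_s%02d", g, seq_len(groups[[g]]))
    }))
    group_of <- rep(names(groups), times = groups)
    n_samples <- length(sample_ids)
    feature_id <- sprintf("feat%05d", seq_len(n_features))

    n_de <- round(de_fraction * n_features)
    is_de <- c(rep(TRUE, n_de), rep(FALSE, n_features - n_de))
    sign_fc <- ifelse(runif(n_features) < 0.5, 1, -1)
    fc <- ifelse(is_de, sign_fc * log2_fc, 0)

    base <- rnorm(n_features, baseline_mean, baseline_sd)
    mat <- matrix(rnorm(n_features * n_samples, 0, sample_sd),
                  n_features, n_samples) + base
    shift_cols <- which(group_of == de_group)
    mat[, shift_cols] <- mat[, shift_cols] + fc
    dimnames(mat) <- list(feature_id, sample_ids)

    if (!is.null(missingness)) {
      cq <- missingness$censor_quantile %||% 0.05
      sc <- missingness$scale %||% 1
      thr <- stats::quantile(mat, cq)
      p_miss <- stats::plogis(-(mat - thr) / sc)
      mat[matrix(runif(length(mat)), nrow(mat)) < p_miss] <- NA_real_
    }

    structure(
      list(mat = mat,
           samples = tibble(sample_id = sample_ids, group = group_of),
           scale = "log2",
           truth = tibble(feature_id = feature_id, is_de = is_de,
                          log2_fc = fc, de_group = de_group)),
      class = "abundance_matrix")
  })
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d features x %d samples (%s scale), %d missing cells\n",
              nrow(x$mat), ncol(x$mat), x$scale, sum(is.na(x$mat))))
  cat("groups:", paste(sprintf("%s (n=%d)", names(table(x$samples$group)),
                               as.integer(table(x$samples$group))),
                       collapse = ", "), "\n")
  invisible(x)
}
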