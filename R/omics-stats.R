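#' Filter, log-transform and impute an abundance matrix
#'
#' Standard proteomics preprocessing: log2-transform (if the matrix is on
#' the raw scale), exclude every feature with fewer than
#' `min_valid_per_group` valid values in at least one group, then impute the
#' remaining missing cells with a MinProb-style downshifted Gaussian drawn
#' per sample: mean = sample mean - `shift` x sample SD, SD = `width` x
#' sample SD. This models left-censored (below detection limit) missingness.
#'
#' @param am An `abundance_matrix` (see [simulate_abundance_matrix()]).
#' @param min_valid_per_group Minimum valid values required in *every*
#'   group.
#' @param width,shift MinProb parameters (fractions of the per-sample SD).
#' @param seed Integer seed for the imputation draws.
#' @return The preprocessed `abundance_matrix` (log2 scale, no missing
#'   cells) with an `imputed` logical matrix marking imputed cells.
#' @export
preprocess_abundance <- function(am, min_valid_per_group = 2,
                                 width = 0.3, shift = 1.8, seed = 1L) {
  if (!inherits(am, "abundance_matrix")) abort("`am` must be an abundance_matrix.")
  mat <- am$mat
  if (am$scale == "raw") {
    if (any(mat <= 0, na.rm = TRUE)) abort("raw abundances must be positive.")
    mat <- log2(mat)
  }
  if (any(colSums(!is.na(mat)) == 0)) {
    abort("a sample has no valid values; cannot preprocess.")
  }
  groups <- split(am$samples$sample_id, am$samples$group)
  valid_per_group <- do.call(cbind, lapply(groups, function(ids) {
    rowSums(!is.na(mat[, ids, drop = FALSE]))
  }))
  keep <- rowSums(valid_per_group >= min_valid_per_group) == ncol(valid_per_group)
  mat <- mat[keep, , drop = FALSE]

  imputed <- is.na(mat)
  withr::with_seed(as.integer(seed), {
    for (j in seq_len(ncol(mat))) {
      miss <- which(imputed[, j])
      if (!length(miss)) next
      obs <- mat[!imputed[, j], j]
      if (length(obs) < 2L) {
        abort(sprintf(
          "sample '%s' has fewer than 2 valid values; cannot estimate imputation parameters.",
          colnames(mat)[j]))
      }
      mu <- mean(obs); s <- sd(obs)
      mat[miss, j] <- rnorm(length(miss), mu - shift * s, width * s)
    }
  })
  out <- am
  out$mat <- mat
  out$scale <- "log2"
  out$imputed <- imputed
  if (!is.null(out$truth)) {
    out$truth <- filter(out$truth, .data$feature_id %in% rownames(mat))
  }
  out
}

#' Per-feature differential expression between two groups
#'
#' Unpaired t-tests per feature with Benjamini-Hochberg correction. A
#' feature is called significant when its FDR is below `fdr_threshold` AND
#' its absolute linear fold-change is at least `fc_threshold` (i.e.
#' |log2FC| >= log2(`fc_threshold`)). Fold-change is `mean(group_b) -
#' mean(group_a)` on the log2 scale.
#'
#' @param am A preprocessed `abundance_matrix` (log2, complete).
#' @param group_a,group_b Group labels to compare (b vs a).
#' @param var_equal Use the pooled-variance t-test (`TRUE`) or Welch
#'   (`FALSE`, default — robust to unequal variances).
#' @param fdr_threshold,fc_threshold Significance thresholds (FDR; linear
#'   fold-change).
#' @return Tibble: `feature_id`, `log2_fc`, `statistic`, `p_value`, `fdr`,
#'   `significant`, `direction`, `flag`.
#' @export
differential_expression <- function(am, group_a, group_b, var_equal = FALSE,
                                    fdr_threshold = 0.05, fc_threshold = 2) {
  if (!inherits(am, "abundance_matrix")) abort("`am` must be an abundance_matrix.")
  if (any(is.na(am$mat))) abort("matrix has missing values; run preprocess_abundance() first.")
  ids_a <- am$samples$sample_id[am$samples$group == group_a]
  ids_b <- am$samples$sample_id[am$samples$group == group_b]
  if (length(ids_a) < 2L || length(ids_b) < 2L) {
    abort("both groups need at least 2 samples.")
  }
  A <- am$mat[, ids_a, drop = FALSE]
  B <- am$mat[, ids_b, drop = FALSE]
  n <- nrow(am$mat)
  p <- numeric(n); stat <- numeric(n); flag <- character(n)
  lfc <- rowMeans(B) - rowMeans(A)
  for (i in seq_len(n)) {
    res <- tryCatch(t.test(B[i, ], A[i, ], var.equal = var_equal),
                    error = function(e) NULL)
    if (is.null(res)) {
      # zero-variance feature: p via a variance floor so the call is defined
      floor_sd <- 1e-8
      tt <- lfc[i] / (floor_sd * sqrt(1 / length(ids_a) + 1 / length(ids_b)))
      dfree <- length(ids_a) + length(ids_b) - 2
      p[i] <- 2 * pt(-abs(tt), dfree)
      stat[i] <- tt
      flag[i] <- "VAR_FLOOR"
    } else {
      p[i] <- res$p.value
      stat[i] <- unname(res$statistic)
      flag[i] <- ""
    }
  }
  fdr <- p.adjust(p, method = "BH")
  tibble(feature_id = rownames(am$mat),
         log2_fc = unname(lfc), statistic = stat, p_value = p, fdr = fdr,
         significant = fdr < fdr_threshold & abs(lfc) >= log2(fc_threshold),
         direction = if_else(lfc >= 0, "up", "down"),
         flag = flag)
}

#' Volcano plot of differential-expression results
#'
#' @param de Tibble from [differential_expression()].
#' @return A ggplot object (-log10 FDR vs log2 fold-change).
#' @export
plot_volcano <- function(de) {
  assert_columns(de, c("log2_fc", "fdr", "significant", "direction"), "`de`")
  ggplot(de, aes(x = .data$log2_fc, y = -log10(.data$fdr))) +
    geom_point(aes(colour = if_else(.data$significant,
                                    .data$direction, "ns")), alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(up = "firebrick", down = "steelblue", ns = "grey60"),
      name = NULL) +
    geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    labs(x = "log2 fold-change", y = "-log10 FDR") +
    theme_bw()
}

#' PTM-site z-scores across samples
#'
#' Standardizes each site's quantification across all samples (mean 0, unit
#' sample SD), then averages per condition. A positive condition-mean
#' z-score is called hyper-modified in that condition, a negative one
#' hypo-modified. Sites with zero variance across samples are excluded with
#' a warning.
#'
#' @param am An `abundance_matrix` of site-level quantifications (complete).
#' @return List with `z` (long tibble: `site_id`, `sample_id`, `group`,
#'   `z`) and `condition_means` (`site_id`, `condition`, `mean_z`, `call`).
#' @export
ptm_zscores <- function(am) {
  if (!inherits(am, "abundance_matrix")) abort("`am` must be an abundance_matrix.")
  if (any(is.na(am$mat))) abort("matrix has missing values; impute or filter first.")
  sds <- apply(am$mat, 1, sd)
  zero <- sds == 0
  if (any(zero)) {
    warn(sprintf("%d site(s) with zero variance excluded from z-scoring.",
                 sum(zero)))
  }
  mat <- am$mat[!zero, , drop = FALSE]
  z <- t(scale(t(mat)))  # per-site standardization
  long <- as_tibble(z, rownames = "site_id") |>
    pivot_longer(-"site_id", names_to = "sample_id", values_to = "z") |>
    left_join(am$samples, by = "sample_id") |>
    rename(group = "group")
  cm <- long |>
    group_by(.data$site_id, .data$group) |>
    summarise(mean_z = mean(.data$z), .groups = "drop") |>
    rename(condition = "group") |>
    mutate(call = if_else(.data$mean_z > 0, "hyper", "hypo"))
  list(z = long, condition_means = cm)
}

#' Principal component analysis of samples
#'
#' Centered (optionally unit-scaled) PCA of the samples in feature space;
#' the standard clustering view of a proteomics experiment.
#'
#' @param am A preprocessed `abundance_matrix`.
#' @param k Number of components to return (<= rank).
#' @param scale. Scale features to unit variance first.
#' @return Tibble of sample scores (`sample_id`, `group`, `PC1..PCk`) with
#'   attribute `"var_explained"` (fraction per component).
#' @export
pca_samples <- function(am, k = 2, scale. = FALSE) {
  if (!inherits(am, "abundance_matrix")) abort("`am` must be an abundance_matrix.")
  if (any(is.na(am$mat))) abort("matrix has missing values; preprocess first.")
  X <- t(am$mat)
  if (scale.) {
    keep <- apply(X, 2, sd) > 0
    X <- X[, keep, drop = FALSE]
  }
  pc <- prcomp(X, center = TRUE, scale. = scale.)
  rank <- sum(pc$sdev > 1e-10)
  if (k > rank) abort(sprintf("k = %d exceeds the matrix rank (%d).", k, rank))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE], rownames = "sample_id") |>
    left_join(am$samples, by = "sample_id") |>
    select("sample_id", "group", dplyr::everything())
  attr(scores, "var_explained") <- ve[seq_len(k)]
  scores
}
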