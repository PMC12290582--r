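# Group statistics: rank tests with Holm-Bonferroni correction, Cohen's d,
# correlation of deviant responses with their likelihood, and subdivision
# split analyses.

#' Holm-Bonferroni adjustment over a declared family
#'
#' Step-down correction: sort the p-values, multiply the i-th smallest by
#' `family_size - i + 1`, enforce monotonicity, cap at 1. The declared
#' family may exceed the number of p-values supplied (tests reported
#' elsewhere count towards the family).
#'
#' @param p Vector of raw p-values.
#' @param family_size Declared family size (at least `length(p)`).
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(p, family_size = length(p)) {
  if (family_size < length(p)) {
    stop("family_size (", family_size, ") is smaller than the number of ",
         "tests (", length(p), ")")
  }
  ord <- order(p)
  mult <- family_size - seq_along(p) + 1
  adj <- cummax(pmin(p[ord] * mult, 1))
  out <- numeric(length(p))
  out[ord] <- adj
  out
}

#' Compare two conditions across subjects
#'
#' Two-tailed Wilcoxon rank-sum test between the per-subject distributions
#' of a condition pair, with a Holm-Bonferroni-corrected p-value over the
#' declared family size and Cohen's d with pooled standard deviation.
#'
#' @param summary Data frame with columns `subject`, `condition`, `value`
#'   (optionally pre-filtered to one ROI).
#' @param pair Character vector of the two condition labels.
#' @param correction_family Declared family size for the correction.
#' @return A `comparison_result`: `statistic`, `two_tailed_p`,
#'   `corrected_p`, `cohens_d`, `pair`.
#' @export
compare_conditions <- function(summary, pair, correction_family = 1) {
  stopifnot(length(pair) == 2,
            all(c("subject", "condition", "value") %in% names(summary)))
  if (correction_family < 1) stop("correction_family must be at least 1")
  x <- summary$value[summary$condition == pair[1]]
  y <- summary$value[summary$condition == pair[2]]
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 subjects")
  wt <- suppressWarnings(stats::wilcox.test(x, y,
                                            alternative = "two.sided"))
  d <- tryCatch(pooled_cohens_d(x, y), error = function(e) 0)
  structure(list(statistic = unname(wt$statistic),
                 two_tailed_p = wt$p.value,
                 corrected_p = min(1, wt$p.value * correction_family),
                 cohens_d = d, pair = pair),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison %s vs %s> W = %g, p = %.3g (corrected %.3g), d = %.3g\n",
              x$pair[1], x$pair[2], x$statistic, x$two_tailed_p,
              x$corrected_p, x$cohens_d))
  invisible(x)
}

#' All pairwise deviant-position comparisons in each ROI
#'
#' Runs `dev4` vs `dev5`, `dev4` vs `dev6` and `dev5` vs `dev6` within each
#' ROI and applies Holm-Bonferroni over the full family (3 pairs x ROIs by
#' default, i.e. 12 for four ROIs).
#'
#' @param summary Data frame with `subject`, `roi`, `condition`, `value`.
#' @param family_size Declared family; defaults to 3 x number of ROIs.
#' @return Data frame with one row per ROI and pair, including raw and
#'   Holm-corrected p-values and Cohen's d.
#' @export
deviant_comparisons <- function(summary, family_size = NULL) {
  rois <- unique(summary$roi)
  pairs <- list(c("dev4", "dev5"), c("dev4", "dev6"), c("dev5", "dev6"))
  family_size <- family_size %||% (length(pairs) * length(rois))
  rows <- do.call(rbind, lapply(rois, function(r) {
    sub <- summary[summary$roi == r, ]
    do.call(rbind, lapply(pairs, function(pr) {
      cmp <- compare_conditions(sub, pr, correction_family = 1)
      data.frame(roi = r, a = pr[1], b = pr[2],
                 statistic = cmp$statistic, p = cmp$two_tailed_p,
                 cohens_d = cmp$cohens_d)
    }))
  }))
  rows$corrected_p <- holm_adjust(rows$p, family_size)
  rows
}

#' Correlation of deviant responses with their likelihood of occurrence
#'
#' Pearson correlation between per-run responses to the three deviant
#' positions and the corresponding hazards (1/3, 1/2, 1), pooling the
#' position-by-run pairs (9 runs give 27 samples). Under prediction-error
#' coding the correlation is negative.
#'
#' @param responses Runs x 3 matrix (columns `dev4`, `dev5`, `dev6`) of
#'   region-averaged responses.
#' @param hazards Likelihood of each deviant position.
#' @return List with `estimate`, `p`, `n` and `undefined` (TRUE when the
#'   responses have zero variance).
#' @export
likelihood_correlation <- function(responses,
                                   hazards = deviant_hazard(4:6)) {
  responses <- as.matrix(responses)
  stopifnot(ncol(responses) == length(hazards))
  y <- as.vector(t(responses))
  x <- rep(hazards, nrow(responses))
  if (length(y) < 3) stop("need at least 3 paired samples")
  if (stats::sd(y) == 0) {
    return(list(estimate = NA_real_, p = NA_real_, n = length(y),
                undefined = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(estimate = unname(ct$estimate), p = ct$p.value, n = length(y),
       undefined = FALSE)
}

#' Effect size between direction-only and rate-only SSA indices
#'
#' Cohen's d with pooled standard deviation between the per-voxel SSA
#' indices of the two stimulus-combination partitions of one subject's SSA
#' region.
#'
#' @param si_dir,si_rate Per-voxel SSA indices for the direction-only and
#'   rate-only partitions.
#' @return Cohen's d (positive when direction exceeds rate).
#' @export
si_modality_effect <- function(si_dir, si_rate) {
  si_dir <- si_dir[is.finite(si_dir)]
  si_rate <- si_rate[is.finite(si_rate)]
  if (length(si_dir) == 0 || length(si_rate) == 0) {
    stop("both SSA index sets must be nonempty")
  }
  pooled_cohens_d(si_dir, si_rate)
}

#' Cohort summary of a per-subject effect size
#'
#' @param d Vector of per-subject Cohen's d values.
#' @return List with `mean`, `se` and `n`.
#' @export
cohort_effect_summary <- function(d) {
  list(mean = mean(d), se = stats::sd(d) / sqrt(length(d)), n = length(d))
}

#' Compare SSA and model-evidence maps across a mask subdivision
#'
#' Splits a parent ROI into `submask` and its complement and summarises the
#' SSA-index and log-K distributions in each part, with two-sample rank
#' tests between the parts.
#'
#' @param si_map Per-voxel SSA index (full-length vector).
#' @param k_map Per-voxel group Bayes factor.
#' @param parent Integer indices of the parent ROI.
#' @param submask Integer indices of the subdivision (subset of `parent`).
#' @return List with per-subdivision summaries and the comparison tests.
#' @export
split_mask_analysis <- function(si_map, k_map, parent, submask) {
  if (!all(submask %in% parent)) stop("submask must lie within the parent ROI")
  other <- setdiff(parent, submask)
  if (length(other) == 0) {
    warning("complement subdivision is empty; comparisons skipped")
  }
  summarise <- function(idx) {
    si <- si_map[idx]; lk <- log(k_map[idx])
    list(n = length(idx), si = si, log_k = lk,
         si_median = stats::median(si, na.rm = TRUE),
         log_k_median = stats::median(lk, na.rm = TRUE),
         frac_k_gt_1 = mean(lk > 0, na.rm = TRUE))
  }
  tests <- if (length(other) > 0) {
    list(si_p = suppressWarnings(
           stats::wilcox.test(si_map[submask], si_map[other])$p.value),
         log_k_p = suppressWarnings(
           stats::wilcox.test(log(k_map[submask]),
                              log(k_map[other]))$p.value))
  } else list(si_p = NA_real_, log_k_p = NA_real_)
  list(subdivision = summarise(submask),
       complement = if (length(other) > 0) summarise(other) else NULL,
       tests = tests)
}
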