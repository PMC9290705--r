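#' ROI summary of a fitted parameter map
#'
#' Mean of the map over the ROI voxels after removing exclusion-mask voxels
#' (vessels / bile ducts) and voxels without a valid fit. Returns `NA` with
#' `n_voxels = 0` when nothing is left (missing-flagged, not an error).
#'
#' @param map A [parameter_map()].
#' @param roi Logical array of ROI voxels.
#' @param exclusion Optional logical array of voxels to exclude.
#' @return List with `value` (the mean) and `n_voxels` retained.
#' @export
summarize_roi <- function(map, roi, exclusion = NULL) {
  stopifnot(inherits(map, "parameter_map"))
  use <- as.logical(roi) & map$valid
  if (!is.null(exclusion)) use <- use & !as.logical(exclusion)
  n <- sum(use)
  list(value = if (n > 0) mean(map$values[use]) else NA_real_,
       n_voxels = n)
}

#' Normality-gated three-group comparison
#'
#' Compares one MRI parameter between the ligated, non-ligated and sham
#' lobes at one timepoint (sham observations, scanned once, enter every
#' timepoint's comparison). Each group's centered values are screened with
#' Shapiro-Wilk; if every group passes at `alpha_normality` the omnibus test
#' is one-way ANOVA with pairwise t tests, otherwise Kruskal-Wallis with
#' pairwise Wilcoxon rank-sum tests. Pairwise p-values are
#' Bonferroni-corrected over the three pairwise comparisons.
#'
#' @param observations Per-lobe observation table (one row per lobe; needs
#'   columns `lobe`, `timepoint_weeks` and the parameter).
#' @param parameter Column name of the parameter to compare.
#' @param timepoint Timepoint in weeks.
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @return List of class `comparison_result`: `parameter`, `timepoint`,
#'   `test_used` (`"anova"` or `"kruskal_wallis"`), `statistic`,
#'   `p_value_raw`, `p_value_corrected` (Bonferroni over the pairwise
#'   family), `pairwise` (named vector of corrected pairwise p-values),
#'   `normality_p` per group.
#' @export
compare_groups <- function(observations, parameter, timepoint,
                           alpha_normality = 0.05) {
  obs <- observations[
    (!is.na(observations$timepoint_weeks) &
       observations$timepoint_weeks == timepoint) |
      observations$lobe == "sham", , drop = FALSE]
  x <- obs[[parameter]]
  g <- factor(obs$lobe, levels = c("ligated", "non_ligated", "sham"))
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  counts <- table(g)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  }

  if (all(tapply(x, g, stats::var) == 0)) {
    return(structure(list(parameter = parameter, timepoint = timepoint,
                          test_used = NA_character_, statistic = NA_real_,
                          p_value_raw = NA_real_, p_value_corrected = NA_real_,
                          pairwise = NULL, normality_p = NULL,
                          degenerate = TRUE),
                     class = "comparison_result"))
  }

  normality_p <- vapply(split(x, g), function(v) {
    if (stats::var(v) == 0) return(0)  # degenerate group: treat as non-normal
    if (length(v) < 3) return(NA_real_)  # too small to assess; no evidence
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  normal <- all(normality_p > alpha_normality, na.rm = TRUE)

  if (normal) {
    fit <- stats::aov(x ~ g)
    an <- summary(fit)[[1]]
    stat <- an[["F value"]][1]
    p_raw <- an[["Pr(>F)"]][1]
    pw <- stats::pairwise.t.test(x, g, p.adjust.method = "bonferroni",
                                 pool.sd = FALSE)$p.value
    test_used <- "anova"
  } else {
    kt <- stats::kruskal.test(x, g)
    stat <- unname(kt$statistic)
    p_raw <- kt$p.value
    pw <- suppressWarnings(
      stats::pairwise.wilcox.test(x, g,
                                  p.adjust.method = "bonferroni")$p.value)
    test_used <- "kruskal_wallis"
  }
  # constant (zero-variance) inputs can make the omnibus p degenerate to 1
  if (!is.finite(p_raw)) p_raw <- 1
  pairwise <- stats::na.omit(as.vector(pw))
  nm <- outer(rownames(pw), colnames(pw), paste, sep = " vs ")
  names(pairwise) <- nm[!is.na(as.vector(pw))]

  structure(list(parameter = parameter, timepoint = timepoint,
                 test_used = test_used, statistic = stat,
                 p_value_raw = p_raw,
                 p_value_corrected = min(1, p_raw * 1),
                 pairwise = pairwise, normality_p = normality_p,
                 degenerate = FALSE),
            class = "comparison_result")
}

#' Spearman rank correlation of an MRI parameter with a histology axis
#'
#' Spearman rho with average-rank tie handling (ordinal Metavir stages carry
#' massive ties) and a two-sided p-value from the t approximation.
#'
#' @param observations Per-lobe observation table with `fibrosis_stage` and
#'   `activity_stage` columns.
#' @param parameter Column name of the MRI parameter.
#' @param histology_axis `"fibrosis"` or `"inflammation"`.
#' @return List of class `correlation_result`: `parameter`,
#'   `histology_axis`, `r`, `p_value`, `n`. Zero variance in either variable
#'   leaves `r = NA` (undefined-flagged).
#' @export
spearman_correlate <- function(observations, parameter,
                               histology_axis = c("fibrosis", "inflammation")) {
  histology_axis <- match.arg(histology_axis)
  stage_col <- if (histology_axis == "fibrosis") "fibrosis_stage" else "activity_stage"
  x <- observations[[parameter]]
  y <- observations[[stage_col]]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need >= 3 paired observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(parameter = parameter, histology_axis = histology_axis,
                 r = r, p_value = p, n = length(x)),
            class = "correlation_result")
}

#' Forward selection of fibrosis-related parameters
#'
#' Keeps the parameters whose fibrosis-axis Spearman correlation satisfies
#' `|r| > r_threshold` and `p < p_threshold`. By default native T1 is
#' dropped whenever delta-T1 is also selected (the two carry largely the
#' same contrast-uptake information and the reference combination uses
#' delta-T1, T2 and ADC); pass `exclude_if_selected = NULL` to keep every
#' qualifying parameter.
#'
#' @param correlations List of `correlation_result`s against the fibrosis
#'   axis.
#' @param r_threshold Absolute-rho threshold (default 0.60).
#' @param p_threshold p-value threshold (default 0.05).
#' @param exclude_if_selected Named list: drop the *name* when the *value*
#'   is also selected. Default `list(t1_native = "delta_t1")`.
#' @return Character vector of selected parameter names.
#' @export
select_features <- function(correlations, r_threshold = 0.60,
                            p_threshold = 0.05,
                            exclude_if_selected = list(t1_native = "delta_t1")) {
  ok <- vapply(correlations, function(cr) {
    !is.na(cr$r) && abs(cr$r) > r_threshold &&
      !is.na(cr$p_value) && cr$p_value < p_threshold
  }, logical(1))
  selected <- vapply(correlations, `[[`, character(1), "parameter")[ok]
  for (drop_name in names(exclude_if_selected)) {
    if (drop_name %in% selected &&
        exclude_if_selected[[drop_name]] %in% selected) {
      selected <- setdiff(selected, drop_name)
    }
  }
  selected
}

#' Pair-counting (Mann-Whitney) area under the ROC curve
#'
#' Probability that a random positive's score exceeds a random negative's,
#' with 0.5 credit for ties; computed from ranks.
#'
#' @param scores_pos,scores_neg Scores of the positive / negative class.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores_pos, scores_neg) {
  n1 <- length(scores_pos); n0 <- length(scores_neg)
  if (n1 == 0 || n0 == 0) stop("both classes must be nonempty", call. = FALSE)
  r <- rank(c(scores_pos, scores_neg))  # average ranks handle ties
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve points
#'
#' Sensitivity and specificity at every candidate cutoff (midpoints between
#' adjacent distinct scores, plus sentinels below and above the score
#' range), with "positive" predicted when score > cutoff.
#'
#' @param scores_pos,scores_neg Class scores.
#' @return Data frame with `cutoff`, `sensitivity`, `specificity`.
#' @export
roc_curve_points <- function(scores_pos, scores_neg) {
  s <- sort(unique(c(scores_pos, scores_neg)))
  cuts <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  sens <- vapply(cuts, function(c) mean(scores_pos > c), numeric(1))
  spec <- vapply(cuts, function(c) mean(scores_neg <= c), numeric(1))
  data.frame(cutoff = cuts, sensitivity = sens, specificity = spec)
}

#' ROC analysis of a single or combined MRI score
#'
#' Evaluates an MRI parameter — or a logistic-regression combination of
#' several — as a classifier of fibrotic lobes. The positive class defaults
#' to `fibrosis_stage >= 1`. A single parameter is used directly as the
#' score, sign-oriented so that higher means more fibrotic (orientation
#' chosen by the AUC >= 0.5 convention). Several parameters are combined
#' into the linear predictor of a binomial logistic model fitted on the same
#' observations (the standard "joint detection" workflow); its coefficients
#' are returned for transparency. The AUC is the pair-counting
#' (Mann-Whitney) estimate; the operating cutoff maximizes Youden's
#' J = sensitivity + specificity - 1 over midpoints between adjacent sorted
#' scores, ties broken by the lowest cutoff.
#'
#' @param observations Per-lobe observation table.
#' @param score_spec Character vector of parameter column names; length 1
#'   for a single-parameter ROC, longer for a logistic combination.
#' @param label_rule Function mapping the observation table to a logical
#'   positive-class vector; default `fibrosis_stage >= 1`.
#' @return List of class `roc_result`: `score_name`, `auc`, `cutoff`,
#'   `sensitivity`, `specificity`, `youden_j`, `orientation`,
#'   `coefficients` (combined scores only), `curve` (ROC points), `n_pos`,
#'   `n_neg`.
#' @export
roc_analysis <- function(observations, score_spec,
                         label_rule = function(obs) obs$fibrosis_stage >= 1) {
  labels <- label_rule(observations)
  keep <- !is.na(labels) &
    rowSums(is.na(as.data.frame(observations[, score_spec, drop = FALSE]))) == 0
  obs <- observations[keep, , drop = FALSE]
  labels <- labels[keep]
  if (all(labels) || !any(labels)) {
    stop("ROC needs both a positive and a negative class", call. = FALSE)
  }

  coefficients <- NULL
  orientation <- 1
  if (length(score_spec) == 1) {
    score <- obs[[score_spec]]
    if (roc_auc(score[labels], score[!labels]) < 0.5) {
      orientation <- -1
      score <- -score
    }
    score_name <- score_spec
  } else {
    dat <- as.data.frame(obs[, score_spec, drop = FALSE])
    dat$.y <- as.integer(labels)
    form <- stats::as.formula(paste(".y ~", paste(score_spec, collapse = " + ")))
    fit <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = dat))
    score <- unname(stats::predict(fit, type = "link"))
    coefficients <- stats::coef(fit)
    score_name <- paste0("combination(", paste(score_spec, collapse = "+"), ")")
  }

  pos <- score[labels]; neg <- score[!labels]
  auc <- roc_auc(pos, neg)
  curve <- roc_curve_points(pos, neg)
  j <- curve$sensitivity + curve$specificity - 1
  # lowest qualifying cutoff; the tolerance treats J values that are equal
  # up to floating-point rounding (sums of small fractions) as tied
  best <- which(j >= max(j) - 1e-9)[1]
  structure(list(score_name = score_name, auc = auc,
                 cutoff = curve$cutoff[best] * orientation,
                 sensitivity = curve$sensitivity[best],
                 specificity = curve$specificity[best],
                 youden_j = j[best],
                 orientation = orientation,
                 coefficients = coefficients,
                 curve = curve,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_result")
}
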