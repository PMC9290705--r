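test_that("ROI summaries exclude vessels and flag empty retained sets", {
  vals <- array(7, c(4, 4)); ok <- array(TRUE, c(4, 4))
  m <- parameter_map(vals, "x", "", ok)
  roi <- array(TRUE, c(4, 4)); none <- array(FALSE, c(4, 4))
  expect_equal(summarize_roi(m, roi)$value, 7)
  # ROI fully excluded -> missing, not an error
  s <- summarize_roi(m, roi, exclusion = roi)
  expect_true(is.na(s$value))
  expect_equal(s$n_voxels, 0)
  expect_equal(summarize_roi(m, none)$n_voxels, 0)
})

test_that("contaminated exclusion voxels never leak into the summary", {
  tp <- tissue_params(900, 400, 35, 13, adc = 1.2, d = 1.0)
  v <- simulate_lobe_volumes(tp, acquisition_protocol(),
                             grid_shape = c(8, 8, 2), sigma = 0)
  maps <- fit_lobe_maps(v)
  clean <- summarize_roi(maps$t2, v$roi_mask, v$exclusion_mask)$value
  expect_equal(clean, 35, tolerance = 1e-6)
  # forgetting the exclusion mask shifts the T1 summary: the vessel voxels
  # carry out-of-distribution signal, so leakage is detectable
  leaky <- summarize_roi(maps$t1_native, v$roi_mask | v$exclusion_mask)$value
  strict <- summarize_roi(maps$t1_native, v$roi_mask, v$exclusion_mask)$value
  expect_equal(strict, 900, tolerance = 1e-6)
  expect_gt(abs(leaky - strict), 1)
})

make_obs <- function(lig, non, sham, tp = 2) {
  tibble::tibble(
    animal_id = seq_along(c(lig, non, sham)),
    lobe = rep(c("ligated", "non_ligated", "sham"),
               c(length(lig), length(non), length(sham))),
    timepoint_weeks = c(rep(tp, length(lig) + length(non)),
                        rep(NA_real_, length(sham))),
    value = c(lig, non, sham))
}

test_that("group comparison gates on normality and corrects pairwise p-values", {
  # three identical groups: F = 0, p = 1
  obs <- make_obs(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  r <- compare_groups(obs, "value", 2)
  expect_equal(r$test_used, "anova")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value_raw, 1)
  expect_true(r$p_value_corrected >= r$p_value_raw)
  expect_true(all(r$pairwise <= 1))

  # a heavily log-normal group trips the Shapiro-Wilk gate
  set.seed(51)
  obs2 <- make_obs(exp(rnorm(12, 0, 2)), rnorm(12), rnorm(12))
  r2 <- compare_groups(obs2, "value", 2)
  expect_equal(r2$test_used, "kruskal_wallis")

  # degenerate all-constant input is flagged, not an error
  obs3 <- make_obs(rep(1, 5), rep(1, 5), rep(1, 5))
  expect_true(compare_groups(obs3, "value", 2)$degenerate)

  expect_error(compare_groups(make_obs(1, 1, 1), "value", 2), ">= 2 groups")
})

test_that("well-separated groups are detected in nearly all replicates", {
  hits <- 0L
  for (seed in 1:40) {
    set.seed(seed)
    obs <- make_obs(rnorm(12, 5, 1), rnorm(12, 0, 1), rnorm(12, 0, 1))
    r <- compare_groups(obs, "value", 2)
    if (r$p_value_raw < 0.001) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})

test_that("Spearman correlation matches the brute-force rank oracle", {
  obs <- tibble::tibble(value = c(1, 2, 3), fibrosis_stage = c(10, 20, 30),
                        activity_stage = c(30, 10, 20))
  expect_equal(spearman_correlate(obs, "value", "fibrosis")$r, 1)
  expect_equal(spearman_correlate(obs, "value", "inflammation")$r, -0.5)
  # random instances with heavy ordinal ties
  set.seed(61)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    obs2 <- tibble::tibble(value = rnorm(n),
                           fibrosis_stage = sample(0:4, n, replace = TRUE),
                           activity_stage = sample(0:3, n, replace = TRUE))
    r <- spearman_correlate(obs2, "value", "fibrosis")
    expect_equal(r$r, oracle_spearman(obs2$value, obs2$fibrosis_stage),
                 tolerance = 1e-12)
  }
  # zero-variance stage vector: undefined-flagged
  obs3 <- tibble::tibble(value = rnorm(10), fibrosis_stage = rep(2, 10),
                         activity_stage = rep(1, 10))
  expect_true(is.na(spearman_correlate(obs3, "value", "fibrosis")$r))
  expect_error(spearman_correlate(obs3[1:2, ], "value", "fibrosis"), ">= 3")
})

test_that("permuted labels give near-zero correlation at n = 100", {
  hits <- 0L
  for (seed in 1:40) {
    set.seed(seed + 100)
    obs <- tibble::tibble(value = rnorm(100),
                          fibrosis_stage = sample(rep(0:4, each = 20)),
                          activity_stage = 0L)
    if (abs(spearman_correlate(obs, "value", "fibrosis")$r) < 0.2) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / 40, 0.95)
})

test_that("feature selection applies the r/p rule and the delta-T1 exclusion", {
  cor_res <- function(p, r, pv) {
    structure(list(parameter = p, r = r, p_value = pv,
                   histology_axis = "fibrosis"), class = "correlation_result")
  }
  # the published fibrosis column: native T1 0.667, delta-T1 0.704,
  # T2 0.635, T2* -0.411, ADC -0.718, skewness -0.131, ...
  cors <- list(cor_res("t1_native", 0.667, 1e-4),
               cor_res("delta_t1", 0.704, 1e-4),
               cor_res("t2", 0.635, 1e-4),
               cor_res("t2star", -0.411, 0.014),
               cor_res("adc_mean", -0.718, 1e-4),
               cor_res("skewness", -0.131, 0.293),
               cor_res("f", 0.105, 0.420))
  expect_setequal(select_features(cors, exclude_if_selected = NULL),
                  c("t1_native", "delta_t1", "t2", "adc_mean"))
  expect_setequal(select_features(cors), c("delta_t1", "t2", "adc_mean"))
  # all-null input selects nothing
  null_cors <- list(cor_res("a", 0, 0.9), cor_res("b", 0.1, 0.5))
  expect_equal(length(select_features(null_cors)), 0)
})

test_that("pair-counting AUC matches enumeration and trapezoidal integration", {
  expect_equal(roc_auc(c(2, 3), 1), 1)
  expect_equal(roc_auc(c(1, 3), 2), 0.5)  # 1 concordant + 1 discordant
  set.seed(71)
  for (i in 1:30) {
    pos <- round(rnorm(sample(3:15, 1), 1), 1)  # rounding forces ties
    neg <- round(rnorm(sample(3:15, 1), 0), 1)
    a <- roc_auc(pos, neg)
    expect_equal(a, oracle_auc_pairs(pos, neg), tolerance = 1e-12)
    expect_equal(a, oracle_auc_trapezoid(pos, neg), tolerance = 1e-12)
  }
})

test_that("AUC and Spearman are invariant under strictly increasing transforms", {
  set.seed(72)
  pos <- rnorm(20, 1); neg <- rnorm(25)
  expect_equal(roc_auc(exp(pos), exp(neg)), roc_auc(pos, neg))
  x <- rnorm(30); y <- sample(0:4, 30, replace = TRUE)
  o1 <- tibble::tibble(value = x, fibrosis_stage = y, activity_stage = 0L)
  o2 <- tibble::tibble(value = x^3 + 10 * x, fibrosis_stage = y,
                       activity_stage = 0L)
  expect_equal(spearman_correlate(o1, "value", "fibrosis")$r,
               spearman_correlate(o2, "value", "fibrosis")$r)
})

test_that("Youden cutoff maximizes J at the lowest qualifying midpoint", {
  obs <- tibble::tibble(value = c(0.9, 0.8, 0.7, 0.2),
                        fibrosis_stage = c(1L, 1L, 0L, 0L),
                        activity_stage = 0L)
  r <- roc_analysis(obs, "value")
  expect_equal(r$auc, 1)
  expect_equal(r$cutoff, 0.75)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$youden_j, 1)
  # exhaustive-scan oracle on random instances
  set.seed(73)
  for (i in 1:20) {
    pos <- rnorm(10, 1); neg <- rnorm(12)
    if (roc_auc(pos, neg) < 0.5) {   # keep the higher-scoring class positive
      tmp <- pos; pos <- neg; neg <- tmp
    }
    obs2 <- tibble::tibble(value = c(pos, neg),
                           fibrosis_stage = rep(c(1L, 0L),
                                                c(length(pos), length(neg))),
                           activity_stage = 0L)
    got <- roc_analysis(obs2, "value")
    want <- oracle_youden(pos, neg)
    expect_equal(got$youden_j, want$j, tolerance = 1e-12)
    expect_equal(got$cutoff, want$cutoff, tolerance = 1e-12)
    expect_equal(got$youden_j, got$sensitivity + got$specificity - 1,
                 tolerance = 1e-12)
  }
  # single-class input is an error
  all_pos <- tibble::tibble(value = 1:3, fibrosis_stage = 1L,
                            activity_stage = 0L)
  expect_error(roc_analysis(all_pos, "value"), "both")
})

test_that("low-valued markers are sign-oriented to AUC >= 0.5", {
  set.seed(74)
  obs <- tibble::tibble(value = c(rnorm(15, 0), rnorm(15, 2)),
                        fibrosis_stage = rep(c(1L, 0L), each = 15),
                        activity_stage = 0L)
  r <- roc_analysis(obs, "value")
  expect_gte(r$auc, 0.5)
  expect_equal(r$orientation, -1)
})

test_that("pair-counting AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(75)
  for (i in 1:10) {
    pos <- round(rnorm(20, 0.8), 1); neg <- round(rnorm(25), 1)
    ref <- as.numeric(suppressMessages(
      pROC::auc(rep(c(1, 0), c(20, 25)), c(pos, neg))))
    expect_equal(roc_auc(pos, neg), ref, tolerance = 1e-12)
  }
})

test_that("logistic combination dominates single parameters on separable data", {
  set.seed(76)
  n <- 300
  stage <- rep(c(0L, 1L), each = n / 2)
  obs <- tibble::tibble(
    a = stage * 2 + rnorm(n), b = -stage * 1.5 + rnorm(n),
    c = stage * 1 + rnorm(n),
    fibrosis_stage = stage, activity_stage = 0L)
  singles <- vapply(c("a", "b", "c"),
                    function(p) roc_analysis(obs, p)$auc, numeric(1))
  comb <- roc_analysis(obs, c("a", "b", "c"))
  expect_gte(comb$auc, max(singles) - 0.02)
  expect_equal(length(comb$coefficients), 4)  # intercept + 3 slopes
})

test_that("pairwise Bonferroni correction equals brute force over the family", {
  set.seed(77)
  for (i in 1:10) {
    lig <- rnorm(8, 2); non <- rnorm(8); sham <- rnorm(8)
    obs <- make_obs(lig, non, sham)
    r <- compare_groups(obs, "value", 2)
    if (r$test_used != "anova") next
    raw <- c("non_ligated vs ligated" = t.test(non, lig)$p.value,
             "sham vs ligated" = t.test(sham, lig)$p.value,
             "sham vs non_ligated" = t.test(sham, non)$p.value)
    # brute-force Bonferroni over the 3-comparison family
    want <- setNames(pmin(1, 3 * raw), names(raw))
    expect_equal(r$pairwise[names(want)], want, tolerance = 1e-12)
    expect_gte(r$p_value_corrected, r$p_value_raw)
    expect_lte(r$p_value_corrected, 1)
  }
})
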