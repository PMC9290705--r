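#' Pipeline configuration
#'
#' Everything one reproducible run needs: the cohort design, the fit
#' options, the statistics options and the master seed. The configuration
#' round-trips losslessly through YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param design A [cohort_design()].
#' @param fit_options List: `discard_first_echo` (default `TRUE`, applied
#'   to both T2 and T2*), `vfa_refine` (default `TRUE`), `adc_b_low` /
#'   `adc_b_high` (0 / 800 s/mm2), `ivim_b_split` (200 s/mm2).
#' @param stats_options List: `alpha_normality` (0.05), `r_threshold`
#'   (0.60), `p_threshold` (0.05), `roc_label` (`"fibrosis_ge_1"`),
#'   `roc_single` (parameters given individual ROC curves).
#' @param write_volumes Write every simulated volume as NIfTI (off by
#'   default; the parameter maps and tables are always written).
#' @param log_level `"quiet"` or `"info"`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = cohort_design(),
                            fit_options = list(),
                            stats_options = list(),
                            write_volumes = FALSE,
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  fit_defaults <- list(discard_first_echo = TRUE, vfa_refine = TRUE,
                       adc_b_low = 0, adc_b_high = 800, ivim_b_split = 200)
  stats_defaults <- list(alpha_normality = 0.05, r_threshold = 0.60,
                         p_threshold = 0.05, roc_label = "fibrosis_ge_1",
                         roc_single = c("t1_native", "delta_t1", "t2",
                                        "adc_mean"))
  structure(list(design = design,
                 fit_options = utils::modifyList(fit_defaults, fit_options),
                 stats_options = utils::modifyList(stats_defaults, stats_options),
                 write_volumes = write_volumes,
                 log_level = log_level),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns the restored
#'   [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  config_from_list(yaml::read_yaml(path))
}

config_to_list <- function(config) {
  d <- config$design
  list(design = list(
         timepoints = d$timepoints,
         n_pbdl_per_timepoint = d$n_pbdl_per_timepoint,
         n_sham = d$n_sham,
         parameter_table = lapply(as.list(as.data.frame(d$parameter_table)),
                                  function(col) as.vector(col)),
         protocol = unclass(d$protocol),
         snr = d$snr, noise_sigma = d$noise_sigma,
         histology_mode = d$histology_mode, jitter_prob = d$jitter_prob,
         dwi_mode = d$dwi_mode, grid_shape = d$grid_shape, seed = d$seed),
       fit_options = config$fit_options,
       stats_options = as.list(config$stats_options),
       write_volumes = config$write_volumes,
       log_level = config$log_level)
}

config_from_list <- function(x) {
  d <- x$design
  design <- cohort_design(
    timepoints = unlist(d$timepoints),
    n_pbdl_per_timepoint = d$n_pbdl_per_timepoint,
    n_sham = d$n_sham,
    parameter_table = tibble::as_tibble(lapply(d$parameter_table, unlist)),
    protocol = do.call(acquisition_protocol, lapply(d$protocol, unlist)),
    snr = d$snr, noise_sigma = d$noise_sigma,
    histology_mode = d$histology_mode, jitter_prob = d$jitter_prob,
    dwi_mode = d$dwi_mode, grid_shape = unlist(d$grid_shape), seed = d$seed)
  pipeline_config(design = design,
                  fit_options = lapply(x$fit_options, function(v)
                    if (is.list(v)) unlist(v) else v),
                  stats_options = lapply(x$stats_options, function(v)
                    if (is.list(v)) unlist(v) else v),
                  write_volumes = isTRUE(x$write_volumes),
                  log_level = x$log_level)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config_to_list(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Fit all parameter maps for one simulated lobe
#'
#' Runs the relaxometry and diffusion fits on the volumes of one lobe and
#' returns the full map set. The fit region is the union of ROI and
#' exclusion masks, so that contaminated exclusion voxels carry fitted
#' values and any downstream summary that forgets to exclude them is
#' visibly wrong.
#'
#' @param volumes A `lobe_volumes` object.
#' @param fit_options See [pipeline_config()].
#' @return Named list of [parameter_map()]s: `t1_native`, `t1_post`,
#'   `delta_t1`, `t2`, `t2star`, `adc`, and the IVIM maps `f`, `d`,
#'   `d_star`.
#' @export
fit_lobe_maps <- function(volumes, fit_options = list()) {
  fo <- utils::modifyList(list(discard_first_echo = TRUE, vfa_refine = TRUE,
                               adc_b_low = 0, adc_b_high = 800,
                               ivim_b_split = 200),
                          fit_options)
  c(lobe_relaxometry_maps(volumes, fo), lobe_diffusion_maps(volumes, fo))
}

lobe_relaxometry_maps <- function(v, fo) {
  prot <- v$protocol
  fit_region <- v$roi_mask | v$exclusion_mask
  t1n <- fit_t1_vfa(v$t1_vfa_native, prot, roi = fit_region,
                    refine = fo$vfa_refine)$t1
  t1p <- fit_t1_vfa(v$t1_vfa_post, prot, roi = fit_region,
                    refine = fo$vfa_refine)$t1
  t1n$quantity <- "t1_native"; t1p$quantity <- "t1_post"
  list(t1_native = t1n, t1_post = t1p,
       delta_t1 = compute_delta_t1(t1n, t1p),
       t2 = fit_monoexp_decay(v$t2_echoes, prot$t2_map_tes,
                              discard_first = fo$discard_first_echo,
                              quantity = "t2", roi = fit_region),
       t2star = fit_monoexp_decay(v$t2star_echoes, prot$t2star_map_tes,
                                  discard_first = fo$discard_first_echo,
                                  quantity = "t2star", roi = fit_region))
}

lobe_diffusion_maps <- function(v, fo) {
  fit_region <- v$roi_mask | v$exclusion_mask
  ivim <- fit_ivim(v$dwi, v$protocol$dwi_b_values,
                   b_split = fo$ivim_b_split, roi = fit_region)
  list(adc = compute_adc(v$dwi, v$protocol$dwi_b_values,
                         b_low = fo$adc_b_low, b_high = fo$adc_b_high,
                         roi = fit_region),
       f = ivim$f, d = ivim$d, d_star = ivim$d_star)
}

# one observation row: ROI summaries of every fitted map for one lobe
observe_lobe <- function(maps, roi, exclusion, row) {
  s <- function(m) summarize_roi(m, roi, exclusion)$value
  hs <- histogram_summary(maps$adc, roi & !exclusion)
  tibble::tibble(
    animal_id = row$animal_id, group = row$group, lobe = row$lobe,
    timepoint_weeks = row$timepoint_weeks,
    t1_native = s(maps$t1_native), delta_t1 = s(maps$delta_t1),
    t2 = s(maps$t2), t2star = s(maps$t2star),
    adc_mean = hs$mean, adc_skewness = hs$skewness,
    adc_kurtosis = hs$kurtosis,
    f = s(maps$f), d = s(maps$d), d_star = s(maps$d_star),
    fibrosis_stage = row$fibrosis_stage,
    activity_stage = row$activity_stage)
}

#' Run the full simulate-fit-summarize-analyse pipeline
#'
#' Executes the five pipeline stages — cohort simulation, relaxometry fits,
#' diffusion fits, ROI summarization, and cohort statistics — and writes the
#' results bundle to `out_dir`: `observations.csv` (one row per lobe),
#' `comparisons.csv` (three-group tests per parameter and timepoint),
#' `correlations.csv` (Spearman vs fibrosis and inflammation),
#' `selected_features.json`, `roc.json` with `roc_curves.csv`, a
#' machine-readable `manifest.json` (seed, config hash, stages) and a
#' human-readable `summary.txt`. Identical configuration and seed produce
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the observation table, comparison /
#'   correlation tables, selected features, ROC results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  say <- function(...) if (config$log_level == "info") message(sprintf(...))
  stages <- list()
  run_stage <- function(name, fn) {
    say("stage %s ...", name)
    out <- tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    stages[[length(stages) + 1L]] <<- list(name = name, status = "completed")
    out
  }

  design <- config$design
  set.seed(design$seed)
  lobe_seeds_pool <- sample.int(.Machine$integer.max - 1L, 100000L)

  # -- stage 1: simulate ----------------------------------------------------
  sim <- run_stage("simulate", function() {
    cohort <- sample_cohort(design)
    volumes <- vector("list", nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      r <- cohort[i, ]
      par <- tissue_params(r$t1_native, r$delta_t1, r$t2, r$t2star, r$adc,
                           r$d, r$d_star, r$f, r$m0)
      volumes[[i]] <- simulate_lobe_volumes(
        par, design$protocol, grid_shape = design$grid_shape,
        snr = design$snr, sigma = design$noise_sigma,
        dwi_mode = design$dwi_mode, seed = lobe_seeds_pool[i])
      if (config$write_volumes) {
        write_lobe_volumes(volumes[[i]], file.path(out_dir, "volumes"),
                           r$animal_id, r$lobe)
      }
    }
    list(cohort = cohort, volumes = volumes)
  })

  # -- stages 2-3: voxel-wise fits ------------------------------------------
  relax_maps <- run_stage("relaxometry", function() {
    lapply(sim$volumes, lobe_relaxometry_maps, fo = config$fit_options)
  })
  diff_maps <- run_stage("diffusion", function() {
    lapply(sim$volumes, lobe_diffusion_maps, fo = config$fit_options)
  })

  # -- stage 4: ROI summaries -> observation table --------------------------
  observations <- run_stage("summarize", function() {
    rows <- lapply(seq_len(nrow(sim$cohort)), function(i) {
      observe_lobe(c(relax_maps[[i]], diff_maps[[i]]),
                   sim$volumes[[i]]$roi_mask,
                   sim$volumes[[i]]$exclusion_mask,
                   sim$cohort[i, ])
    })
    do.call(rbind, rows)
  })

  # -- stage 5: cohort statistics -------------------------------------------
  stats_out <- run_stage("stats", function() {
    so <- config$stats_options
    present <- table(observations$lobe)
    missing_groups <- setdiff(c("ligated", "non_ligated", "sham"),
                              names(present)[present >= 2])
    if (length(missing_groups) > 0) {
      stop(sprintf("group '%s' has fewer than 2 observations; %s",
                   missing_groups[1],
                   "the three-group comparisons need all of ligated, non_ligated, sham"))
    }
    params <- c("t1_native", "delta_t1", "t2", "t2star", "adc_mean",
                "adc_skewness", "adc_kurtosis", "f", "d", "d_star")
    comparisons <- do.call(rbind, lapply(design$timepoints, function(tp) {
      do.call(rbind, lapply(params, function(p) {
        cr <- compare_groups(observations, p, tp, so$alpha_normality)
        data.frame(parameter = p, timepoint_weeks = tp,
                   test_used = cr$test_used %||% NA_character_,
                   statistic = cr$statistic, p_value_raw = cr$p_value_raw,
                   p_value_corrected = cr$p_value_corrected,
                   stringsAsFactors = FALSE)
      }))
    }))
    correlations <- do.call(rbind, lapply(params, function(p) {
      do.call(rbind, lapply(c("fibrosis", "inflammation"), function(ax) {
        cr <- spearman_correlate(observations, p, ax)
        data.frame(parameter = p, histology_axis = ax, r = cr$r,
                   p_value = cr$p_value, n = cr$n, stringsAsFactors = FALSE)
      }))
    }))
    fib_cors <- lapply(params, function(p)
      spearman_correlate(observations, p, "fibrosis"))
    selected <- select_features(fib_cors, so$r_threshold, so$p_threshold)
    label_rule <- switch(so$roc_label,
                         fibrosis_ge_1 = function(o) o$fibrosis_stage >= 1,
                         stop("unknown roc_label: ", so$roc_label))
    roc_single <- lapply(intersect(so$roc_single, params), function(p)
      roc_analysis(observations, p, label_rule))
    roc_combined <- if (length(selected) >= 2) {
      roc_analysis(observations, selected, label_rule)
    } else NULL
    list(comparisons = comparisons, correlations = correlations,
         selected = selected, roc_single = roc_single,
         roc_combined = roc_combined)
  })

  # -- outputs ---------------------------------------------------------------
  manifest <- list(package = "pbdlmrq",
                   version = as.character(utils::packageVersion("pbdlmrq")),
                   seed = design$seed, config_hash = hash,
                   stages = stages)
  write_result_csv(observations, file.path(out_dir, "observations.csv"),
                   hash, sidecar = TRUE)
  write_result_csv(stats_out$comparisons, file.path(out_dir, "comparisons.csv"),
                   hash)
  write_result_csv(stats_out$correlations, file.path(out_dir, "correlations.csv"),
                   hash)
  jsonlite::write_json(stats_out$selected,
                       file.path(out_dir, "selected_features.json"))
  rocs <- c(stats_out$roc_single,
            if (!is.null(stats_out$roc_combined)) list(stats_out$roc_combined))
  roc_json <- lapply(rocs, function(r) {
    r[c("score_name", "auc", "cutoff", "sensitivity", "specificity",
        "youden_j", "n_pos", "n_neg")]
  })
  jsonlite::write_json(roc_json, file.path(out_dir, "roc.json"),
                       auto_unbox = TRUE, digits = NA)
  curves <- do.call(rbind, lapply(rocs, function(r)
    cbind(score_name = r$score_name, r$curve)))
  write_result_csv(curves, file.path(out_dir, "roc_curves.csv"), hash)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  summary_lines <- c(
    "PBDL multiparametric MRI pipeline run",
    sprintf("config hash : %s", hash),
    sprintf("seed        : %d", design$seed),
    sprintf("lobes       : %d", nrow(observations)),
    sprintf("selected    : %s", paste(stats_out$selected, collapse = ", ")),
    vapply(roc_json, function(r)
      sprintf("ROC %-28s AUC %.3f sens %.3f spec %.3f",
              r$score_name, r$auc, r$sensitivity, r$specificity),
      character(1)))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  say("%s", paste(summary_lines, collapse = "\n"))

  invisible(list(observations = observations,
                 comparisons = stats_out$comparisons,
                 correlations = stats_out$correlations,
                 selected = stats_out$selected,
                 roc = rocs, manifest = manifest))
}
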