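#' Group-level tissue parameter calibration table
#'
#' Per-(group, timepoint, parameter) means and standard deviations that the
#' cohort generator samples from. The relaxation and diffusion cells
#' (native T1, delta-T1, T2, T2*, ADC, D) are the published group summaries
#' of the PBDL study this package models: ligated and non-ligated lobes at
#' 2, 4, 6 and 8 weeks after surgery, and sham livers scanned once
#' (`timepoint_weeks = NA`). The IVIM perfusion fraction `f`, the
#' pseudo-diffusion `d_star` and the proton-density scale `m0` are not
#' tabulated in the source study; their defaults (f = 0.20 +/- 0.05,
#' D* = 50 +/- 10 (1e-3 mm2/s), m0 = 1000 +/- 0) are typical rodent-liver
#' values and are identical across groups, so they carry no group signal.
#'
#' @return A tibble with columns `group` (`ligated`, `non_ligated`, `sham`),
#'   `timepoint_weeks` (2/4/6/8, `NA` for sham), `parameter`, `mean`, `sd`.
#' @examples
#' tab <- pbdl_parameter_table()
#' subset(tab, parameter == "delta_t1" & group == "ligated")
#' @export
pbdl_parameter_table <- function() {
  wk <- c(2, 4, 6, 8)
  cell <- function(group, tp, parameter, mean, sd) {
    tibble::tibble(group = group, timepoint_weeks = tp,
                   parameter = parameter, mean = mean, sd = sd)
  }
  rows <- list(
    cell("ligated", wk, "t1_native",
         c(966.310, 923.000, 970.500, 1040.174),
         c(125.350, 90.563, 49.003, 69.728)),
    cell("non_ligated", wk, "t1_native",
         c(832.903, 783.938, 771.703, 814.143),
         c(77.624, 67.704, 37.172, 66.827)),
    cell("sham", NA_real_, "t1_native", 901.000, 58.541),

    cell("ligated", wk, "delta_t1",
         c(468.083, 525.875, 539.750, 580.176),
         c(91.293, 85.271, 18.321, 74.484)),
    cell("non_ligated", wk, "delta_t1",
         c(382.190, 467.900, 324.533, 349.867),
         c(73.450, 36.292, 69.037, 105.714)),
    cell("sham", NA_real_, "delta_t1", 458.375, 40.281),

    cell("ligated", wk, "t2",
         c(35.922, 41.490, 38.312, 40.145),
         c(2.652, 2.227, 0.666, 2.932)),
    cell("non_ligated", wk, "t2",
         c(32.239, 32.136, 31.864, 30.429),
         c(1.426, 0.877, 0.597, 2.413)),
    cell("sham", NA_real_, "t2", 33.087, 1.489),

    cell("ligated", wk, "t2star",
         c(12.729, 12.405, 11.794, 12.355),
         c(1.695, 1.172, 0.869, 0.910)),
    cell("non_ligated", wk, "t2star",
         c(13.705, 13.981, 14.293, 14.683),
         c(1.727, 1.570, 0.972, 1.327)),
    cell("sham", NA_real_, "t2star", 13.833, 1.235),

    cell("ligated", wk, "adc",
         c(1.179, 1.258, 1.179, 1.097),
         c(0.108, 0.059, 0.104, 0.065)),
    cell("non_ligated", wk, "adc",
         c(1.292, 1.370, 1.292, 1.360),
         c(0.129, 0.103, 0.122, 0.229)),
    cell("sham", NA_real_, "adc", 1.363, 0.057),

    cell("ligated", wk, "d",
         c(1.087, 0.915, 0.869, 0.959),
         c(0.129, 0.092, 0.164, 0.073)),
    cell("non_ligated", wk, "d",
         c(1.009, 1.001, 0.930, 0.946),
         c(0.115, 0.251, 0.158, 0.069)),
    cell("sham", NA_real_, "d", 1.021, 0.100)
  )
  # untabulated parameters: identical cells for every group/timepoint
  flat <- do.call(rbind, rows)
  combos <- unique(flat[, c("group", "timepoint_weeks")])
  defaults <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    cell(combos$group[i], combos$timepoint_weeks[i],
         c("f", "d_star", "m0"),
         c(0.20, 50, 1000), c(0.05, 10, 0))
  }))
  out <- rbind(flat, defaults)
  out[order(out$parameter, out$group, out$timepoint_weeks), ]
}

#' Cohort design for the synthetic PBDL study
#'
#' Describes the study to simulate: four post-surgery timepoints with
#' `n_pbdl_per_timepoint` ligated mice each (every PBDL mouse contributes a
#' ligated and a non-ligated lobe) plus `n_sham` sham mice scanned once, the
#' per-cell (mean, sd) calibration table, the histology staging mode, the
#' imaging noise level and the acquisition protocol.
#'
#' @param timepoints Weeks post surgery, default `c(2, 4, 6, 8)`.
#' @param n_pbdl_per_timepoint PBDL mice per timepoint (default 12).
#' @param n_sham Sham mice (default 6), scanned once and reused in every
#'   timepoint comparison.
#' @param parameter_table Calibration table, see [pbdl_parameter_table()].
#' @param protocol An [acquisition_protocol()].
#' @param snr Per-series SNR used when simulating voxel data.
#' @param noise_sigma Optional absolute Rician sigma overriding `snr`.
#' @param histology_mode `"deterministic"` or `"jittered"`, see
#'   [assign_histology()].
#' @param jitter_prob Per-stage perturbation probability in jittered mode.
#' @param dwi_mode DWI generation model, `"monoexp"` or `"ivim"`.
#' @param grid_shape Voxel grid per lobe for image simulation.
#' @param seed Integer seed governing every random draw downstream.
#' @return Object of class `cohort_design`.
#' @export
cohort_design <- function(timepoints = c(2, 4, 6, 8),
                          n_pbdl_per_timepoint = 12,
                          n_sham = 6,
                          parameter_table = pbdl_parameter_table(),
                          protocol = acquisition_protocol(),
                          snr = 50, noise_sigma = NULL,
                          histology_mode = c("deterministic", "jittered"),
                          jitter_prob = 0.2,
                          dwi_mode = c("monoexp", "ivim"),
                          grid_shape = c(8, 8, 2),
                          seed = 1L) {
  histology_mode <- match.arg(histology_mode)
  dwi_mode <- match.arg(dwi_mode)
  stopifnot(n_pbdl_per_timepoint >= 0, n_sham >= 0, length(timepoints) >= 1)
  if (any(!c("group", "timepoint_weeks", "parameter", "mean", "sd") %in%
          names(parameter_table))) {
    stop("parameter_table must have columns group, timepoint_weeks, parameter, mean, sd",
         call. = FALSE)
  }
  if (any(parameter_table$sd < 0)) stop("parameter sd must be >= 0", call. = FALSE)
  structure(
    list(timepoints = timepoints,
         n_pbdl_per_timepoint = n_pbdl_per_timepoint,
         n_sham = n_sham,
         parameter_table = parameter_table,
         protocol = protocol,
         snr = snr, noise_sigma = noise_sigma,
         histology_mode = histology_mode, jitter_prob = jitter_prob,
         dwi_mode = dwi_mode, grid_shape = grid_shape,
         seed = as.integer(seed)),
    class = "cohort_design"
  )
}

# look up (mean, sd) for one cell; sham cells are stored with NA timepoint
lookup_cell <- function(tab, group, timepoint, parameter) {
  hit <- tab$group == group & tab$parameter == parameter &
    (if (group == "sham") is.na(tab$timepoint_weeks)
     else !is.na(tab$timepoint_weeks) & tab$timepoint_weeks == timepoint)
  if (sum(hit) != 1) {
    stop(sprintf("parameter table has no unique entry for (%s, %s, %s)",
                 group, timepoint, parameter), call. = FALSE)
  }
  c(mean = tab$mean[hit], sd = tab$sd[hit])
}

# normal draw truncated to (lower, upper); resamples, falls back to clamping
rtruncnorm1 <- function(mean, sd, lower = -Inf, upper = Inf, max_tries = 1000) {
  if (sd == 0) return(min(max(mean, lower), upper))
  for (i in seq_len(max_tries)) {
    x <- stats::rnorm(1, mean, sd)
    if (x > lower && x < upper) return(x)
  }
  min(max(mean, lower), upper)
}

#' Assign Metavir fibrosis / activity stages
#'
#' Encodes the histological trajectory of the PBDL model: ligated lobes
#' progress F1 (2 w), F2 (4 w), F2 (6 w), F3 (8 w) in fibrosis, with
#' necro-inflammatory activity peaking early (A2, A3, A2, A3); non-ligated
#' lobes and sham livers show neither fibrosis nor activity (F0, A0). In
#' `"jittered"` mode each ligated stage is perturbed by +/-1 with probability
#' `jitter_prob` and clipped to its valid range, except the 8-week ligated
#' endpoint, which is pinned at (F3, A3).
#'
#' @param group `"ligated"`, `"non_ligated"` or `"sham"`.
#' @param timepoint_weeks 2, 4, 6 or 8 (ignored for sham).
#' @param mode `"deterministic"` (default) or `"jittered"`.
#' @param jitter_prob Perturbation probability per stage in jittered mode.
#' @param seed Optional seed.
#' @return List with integer `fibrosis_stage` (0-4) and `activity_stage`
#'   (0-3).
#' @examples
#' assign_histology("ligated", 8)            # F3, A3
#' assign_histology("sham", 2)               # F0, A0
#' @export
assign_histology <- function(group, timepoint_weeks,
                             mode = c("deterministic", "jittered"),
                             jitter_prob = 0.2, seed = NULL) {
  mode <- match.arg(mode)
  if (!group %in% c("ligated", "non_ligated", "sham")) {
    stop("unknown group: ", group, call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (group != "ligated") {
    return(list(fibrosis_stage = 0L, activity_stage = 0L))
  }
  fib_traj <- c(`2` = 1L, `4` = 2L, `6` = 2L, `8` = 3L)
  act_traj <- c(`2` = 2L, `4` = 3L, `6` = 2L, `8` = 3L)
  key <- as.character(timepoint_weeks)
  if (!key %in% names(fib_traj)) {
    stop("unknown timepoint: ", timepoint_weeks, call. = FALSE)
  }
  fib <- fib_traj[[key]]; act <- act_traj[[key]]
  if (mode == "jittered" && timepoint_weeks != 8) {
    jitter1 <- function(stage, lo, hi) {
      if (stats::runif(1) < jitter_prob) {
        stage <- stage + sample(c(-1L, 1L), 1)
      }
      min(max(stage, lo), hi)
    }
    fib <- jitter1(fib, 0L, 4L)
    act <- jitter1(act, 0L, 3L)
  }
  list(fibrosis_stage = fib, activity_stage = act)
}

#' Sample a synthetic cohort's ground-truth parameters and histology
#'
#' Draws, for every lobe of every animal in the design, a full set of tissue
#' parameters from the Normal(mean, sd) of its (group, timepoint) calibration
#' cell, truncated to physical validity (positive relaxation times and
#' diffusivities, `f` in [0, 1], `d_star > d`, post-contrast T1 > 0), plus a
#' Metavir histology score. Each PBDL mouse contributes two rows (ligated and
#' non-ligated lobe, same `animal_id`); each sham mouse contributes one
#' whole-liver row with `timepoint_weeks = NA` (scanned once, reused in every
#' timepoint comparison).
#'
#' @param design A [cohort_design()].
#' @return A tibble with one row per lobe: `animal_id`, `group`
#'   (`pbdl`/`sham`), `lobe`, `timepoint_weeks`, the nine tissue parameters,
#'   and `fibrosis_stage` / `activity_stage`.
#' @examples
#' cohort <- sample_cohort(cohort_design(seed = 7))
#' nrow(cohort)  # 48 PBDL mice x 2 lobes + 6 sham = 102
#' @export
sample_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  tab <- design$parameter_table
  par_names <- c("t1_native", "delta_t1", "t2", "t2star", "adc",
                 "d", "d_star", "f", "m0")

  cell_cache <- new.env(parent = emptyenv())
  cells_for <- function(group, timepoint) {
    key <- paste(group, timepoint)
    if (is.null(cell_cache[[key]])) {
      cells <- lapply(par_names, function(p)
        lookup_cell(tab, group, timepoint, p))
      names(cells) <- par_names
      cell_cache[[key]] <- cells
    }
    cell_cache[[key]]
  }

  draw_lobe <- function(group, timepoint) {
    cells <- cells_for(group, timepoint)
    g <- function(p, lower = -Inf, upper = Inf) {
      rtruncnorm1(cells[[p]][["mean"]], cells[[p]][["sd"]], lower, upper)
    }
    t1n <- g("t1_native", lower = 0)
    dt1 <- g("delta_t1", upper = t1n)
    d <- g("d", lower = 0)
    out <- list(
      t1_native = t1n, delta_t1 = dt1,
      t2 = g("t2", lower = 0), t2star = g("t2star", lower = 0),
      adc = g("adc", lower = 0), d = d,
      d_star = g("d_star", lower = d),
      f = g("f", lower = 0, upper = 1),
      m0 = g("m0", lower = 0))
    out
  }

  n_rows <- 2L * design$n_pbdl_per_timepoint * length(design$timepoints) +
    design$n_sham
  animal_id <- lobe <- character(n_rows)
  group <- character(n_rows)
  timepoint <- rep(NA_real_, n_rows)
  pars_mat <- matrix(NA_real_, n_rows, length(par_names),
                     dimnames = list(NULL, par_names))
  fib <- act <- integer(n_rows)

  r <- 0L
  emit <- function(id, grp, lb, tp) {
    r <<- r + 1L
    animal_id[r] <<- id; group[r] <<- grp; lobe[r] <<- lb
    timepoint[r] <<- tp
    pars_mat[r, ] <<- unlist(draw_lobe(lb, tp))[par_names]
    hist <- assign_histology(lb, tp, design$histology_mode,
                             design$jitter_prob)
    fib[r] <<- hist$fibrosis_stage
    act[r] <<- hist$activity_stage
  }
  for (tp in design$timepoints) {
    for (i in seq_len(design$n_pbdl_per_timepoint)) {
      id <- sprintf("pbdl_%02dw_%02d", tp, i)
      emit(id, "pbdl", "ligated", tp)
      emit(id, "pbdl", "non_ligated", tp)
    }
  }
  for (i in seq_len(design$n_sham)) {
    emit(sprintf("sham_%02d", i), "sham", "sham", NA_real_)
  }
  out <- tibble::as_tibble(as.data.frame(pars_mat))
  tibble::tibble(animal_id = animal_id, group = group, lobe = lobe,
                 timepoint_weeks = timepoint, out,
                 fibrosis_stage = fib, activity_stage = act)
}
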