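#' Spoiled-gradient-echo steady-state signal
#'
#' Forward model behind variable-flip-angle T1 mapping:
#' `S(theta) = m0 * sin(theta) * (1 - E1) / (1 - E1 * cos(theta))`, with
#' `E1 = exp(-TR / T1)`. This is the standard closed-form steady-state
#' signal of an ideally spoiled gradient-echo sequence.
#'
#' @param t1 Longitudinal relaxation time, msec (vectorised).
#' @param m0 Proton-density scale (vectorised).
#' @param flip_angle_deg Flip angle in degrees (scalar).
#' @param tr Repetition time, msec.
#' @return Signal intensity, same shape as `t1`/`m0`.
#' @export
vfa_signal <- function(t1, m0, flip_angle_deg, tr) {
  theta <- flip_angle_deg * pi / 180
  e1 <- exp(-tr / t1)
  m0 * sin(theta) * (1 - e1) / (1 - e1 * cos(theta))
}

#' Mono-exponential echo decay
#'
#' `S(TE) = m0 * exp(-TE / t_relax)`; serves both spin-echo T2 and
#' gradient-echo T2* trains.
#'
#' @param t_relax T2 or T2*, msec (vectorised).
#' @param m0 Signal at TE = 0 (vectorised).
#' @param te Echo time, msec (scalar).
#' @return Signal intensity.
#' @export
echo_decay_signal <- function(t_relax, m0, te) {
  m0 * exp(-te / t_relax)
}

#' Diffusion-weighted signal models
#'
#' `dwi_signal_monoexp()` is the mono-exponential model
#' `S(b) = s0 * exp(-b * ADC)`; `dwi_signal_ivim()` is the bi-exponential
#' intravoxel-incoherent-motion model
#' `S(b) = s0 * ((1 - f) * exp(-b * D) + f * exp(-b * D*))`.
#' Diffusivities are given in 1e-3 mm2/s and b in s/mm2, so the exponent is
#' `-b * D * 1e-3`.
#'
#' @param s0 Signal at b = 0 (vectorised).
#' @param adc,d,d_star Diffusivities, 1e-3 mm2/s.
#' @param f Perfusion fraction in [0, 1].
#' @param b b-value, s/mm2 (scalar).
#' @return Signal intensity.
#' @export
dwi_signal_monoexp <- function(s0, adc, b) {
  s0 * exp(-b * adc * 1e-3)
}

#' @rdname dwi_signal_monoexp
#' @export
dwi_signal_ivim <- function(s0, f, d, d_star, b) {
  s0 * ((1 - f) * exp(-b * d * 1e-3) + f * exp(-b * d_star * 1e-3))
}

#' Add Rician noise to a magnitude signal
#'
#' Magnitude MRI noise: independent Gaussian noise of scale `sigma` on the
#' real and imaginary channels followed by the magnitude operation,
#' `M = sqrt((S + n1)^2 + n2^2)`. At high SNR the mean of `M` converges to
#' `S`; at `S = 0` it converges to `sigma * sqrt(pi / 2)` (Rayleigh).
#'
#' @param signal Noiseless magnitude signal (any numeric array).
#' @param sigma Rician scale parameter, >= 0. `sigma = 0` returns the input.
#' @return Noisy magnitudes, same shape as `signal`.
#' @export
add_rician_noise <- function(signal, sigma) {
  if (length(sigma) != 1 || !is.finite(sigma) || sigma < 0) {
    stop("sigma must be a single nonnegative number", call. = FALSE)
  }
  if (sigma == 0) return(signal)
  n <- length(signal)
  out <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  if (!is.null(dim(signal))) dim(out) <- dim(signal)
  out
}

# Exclusion-mask voxels ("vessels / bile ducts") are simulated from a
# deliberately out-of-distribution parameter set derived from the lobe's
# tissue parameters — longer relaxation times, faster diffusion, brighter
# proton density, the signature of blood/bile — so that any leakage of
# excluded voxels into an ROI summary is detectable in every fitted map,
# including the scale-invariant ones (T1/T2/ADC do not see a plain m0
# rescaling).
vessel_params <- function(p) {
  list(t1_native = min(3 * p$t1_native, 9000),
       delta_t1 = 0.1 * p$delta_t1,
       t2 = min(3 * p$t2, 9000),
       t2star = min(3 * p$t2star, 9000),
       adc = 2.5 * p$adc,
       d = 2.5 * p$d,
       d_star = min(2 * p$d_star, 400),
       f = min(3 * p$f, 0.9),
       m0 = 5 * p$m0)
}

#' Simulate the full multi-sequence voxel data for one liver lobe
#'
#' Generates, on a common voxel grid, every series the downstream fits
#' consume: VFA spoiled-gradient-echo signals at each protocol flip angle for
#' the native T1 and (separately) for the post-contrast T1
#' `t1_native - delta_t1`; the T2 and T2* echo trains; and the DWI series at
#' the protocol b-values, either mono-exponential with `adc` (default) or
#' bi-exponential IVIM with `(f, d, d_star)`. Rician noise is applied to
#' every series.
#'
#' Noise scale: `snr` is interpreted per acquired series, relative to that
#' series' peak noiseless in-ROI signal (`sigma = max(series) / snr`), the
#' usual way SNR is quoted on the brightest image of an acquisition. An
#' absolute Rician `sigma` (same for all series) may be given instead.
#'
#' The grid carries an ROI mask and a disjoint exclusion mask emulating
#' vessels / bile ducts; exclusion voxels receive out-of-distribution signal
#' (`EXCLUSION_SIGNAL_FACTOR` times the local level) so that ROI summaries
#' that accidentally include them are visibly contaminated. Background voxels
#' (neither mask) carry zero signal plus noise.
#'
#' @param params A [tissue_params()] object (ground truth for this lobe).
#' @param protocol An [acquisition_protocol()].
#' @param grid_shape Integer vector of voxel grid dimensions, e.g.
#'   `c(8, 8, 2)`.
#' @param snr Per-series signal-to-noise ratio (peak signal / Rician sigma).
#'   Ignored when `sigma` is given.
#' @param sigma Optional absolute Rician scale applied to all series.
#' @param dwi_mode `"monoexp"` (DWI generated from `adc`) or `"ivim"`
#'   (generated from `f`, `d`, `d_star`).
#' @param roi_fraction Approximate fraction of grid voxels inside the ROI.
#' @param seed Optional integer seed for reproducibility.
#' @return A list of class `lobe_volumes` with elements `t1_vfa_native`,
#'   `t1_vfa_post` (arrays, last dimension = flip angle), `t2_echoes`,
#'   `t2star_echoes` (last dimension = echo), `dwi` (last dimension =
#'   b-value), `roi_mask`, `exclusion_mask` (logical arrays of
#'   `grid_shape`), plus the `protocol`, `params`, `dwi_mode` and the
#'   per-series `sigmas` actually applied.
#' @examples
#' vols <- simulate_lobe_volumes(
#'   tissue_params(966, 468, 35.9, 12.7, adc = 1.18, d = 1.09),
#'   acquisition_protocol(), grid_shape = c(6, 6, 2), sigma = 0)
#' dim(vols$dwi)
#' @export
simulate_lobe_volumes <- function(params, protocol, grid_shape = c(8, 8, 2),
                                  snr = 50, sigma = NULL,
                                  dwi_mode = c("monoexp", "ivim"),
                                  roi_fraction = 0.75, seed = NULL) {
  stopifnot(inherits(params, "tissue_params"),
            inherits(protocol, "acquisition_protocol"))
  dwi_mode <- match.arg(dwi_mode)
  if (any(grid_shape < 1)) stop("grid_shape must be positive", call. = FALSE)
  if (!is.null(sigma) && sigma < 0) stop("noise sigma must be >= 0", call. = FALSE)
  if (is.null(sigma) && (!is.finite(snr) || snr <= 0)) {
    stop("snr must be positive and finite", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  nvox <- prod(grid_shape)
  masks <- make_lobe_masks(grid_shape, roi_fraction)
  roi <- masks$roi; excl <- masks$exclusion

  # one series = one array with the acquisition index as last dimension;
  # ROI voxels carry the tissue signal, exclusion voxels the vessel signal
  build_series <- function(tissue_vals, vessel_vals) {
    k <- length(tissue_vals)
    mat <- matrix(0, nrow = nvox, ncol = k)
    mat[roi, ] <- rep(tissue_vals, each = sum(roi))
    mat[excl, ] <- rep(vessel_vals, each = sum(excl))
    array(mat, dim = c(grid_shape, k))
  }

  forward_set <- function(p) {
    t1_post <- p$t1_native - p$delta_t1
    list(
      t1_vfa_native = vapply(protocol$t1_map_flip_angles, function(a)
        vfa_signal(p$t1_native, p$m0, a, protocol$t1_map_tr), numeric(1)),
      t1_vfa_post = vapply(protocol$t1_map_flip_angles, function(a)
        vfa_signal(t1_post, p$m0, a, protocol$t1_map_tr), numeric(1)),
      t2_echoes = vapply(protocol$t2_map_tes, function(te)
        echo_decay_signal(p$t2, p$m0, te), numeric(1)),
      t2star_echoes = vapply(protocol$t2star_map_tes, function(te)
        echo_decay_signal(p$t2star, p$m0, te), numeric(1)),
      dwi = if (dwi_mode == "monoexp") {
        vapply(protocol$dwi_b_values, function(b)
          dwi_signal_monoexp(p$m0, p$adc, b), numeric(1))
      } else {
        vapply(protocol$dwi_b_values, function(b)
          dwi_signal_ivim(p$m0, p$f, p$d, p$d_star, b), numeric(1))
      })
  }

  tissue_sig <- forward_set(params)
  vessel_sig <- forward_set(vessel_params(params))
  series <- Map(build_series, tissue_sig, vessel_sig)
  peaks <- vapply(tissue_sig, max, numeric(1))
  sigmas <- if (is.null(sigma)) peaks / snr else setNames(rep(sigma, 5), names(peaks))
  noisy <- Map(add_rician_noise, series, as.list(sigmas))

  structure(
    c(noisy,
      list(roi_mask = array(roi, dim = grid_shape),
           exclusion_mask = array(excl, dim = grid_shape),
           protocol = protocol, params = params, dwi_mode = dwi_mode,
           sigmas = sigmas)),
    class = "lobe_volumes"
  )
}

# ROI / exclusion layout on an index grid: the ROI is a centred block of
# roughly roi_fraction of the voxels; a thin strip inside that block is
# carved out as the exclusion mask ("vessel"), so the two are disjoint.
make_lobe_masks <- function(grid_shape, roi_fraction = 0.75) {
  nvox <- prod(grid_shape)
  idx <- arrayInd(seq_len(nvox), .dim = grid_shape)
  # shrink the first dimension symmetrically to hit roi_fraction
  keep1 <- max(1, round(grid_shape[1] * roi_fraction))
  lo <- floor((grid_shape[1] - keep1) / 2) + 1
  roi <- idx[, 1] >= lo & idx[, 1] < lo + keep1
  excl <- rep(FALSE, nvox)
  if (grid_shape[1] >= 4 && sum(roi) > grid_shape[2]) {
    vessel_row <- lo  # first ROI row becomes the "vessel"
    excl <- idx[, 1] == vessel_row & roi
    roi <- roi & !excl
  }
  list(roi = roi, exclusion = excl)
}

#' Collapse a multi-volume series to a voxel-by-acquisition matrix
#'
#' Utility used by the fitting routines: reshapes an array whose last
#' dimension indexes acquisitions (flip angles, echoes or b-values) into an
#' `n_voxels x n_acquisitions` matrix.
#'
#' @param series Array with acquisition as last dimension.
#' @return Numeric matrix.
#' @export
series_matrix <- function(series) {
  d <- dim(series)
  if (is.null(d) || length(d) < 2) stop("series must be an array", call. = FALSE)
  matrix(series, nrow = prod(d[-length(d)]), ncol = d[length(d)])
}
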