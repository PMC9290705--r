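#' Two-point apparent diffusion coefficient map
#'
#' `ADC = ln(S_low / S_high) / (b_high - b_low)` per voxel, by default from
#' the b = 0 and b = 800 s/mm2 volumes, reported in 1e-3 mm2/s. Voxels with
#' nonpositive signal at either b, or with `S_high > S_low` (noise-induced
#' negative ADC), are marked invalid; the negative-ADC count is recorded in
#' the diagnostics.
#'
#' @param series Array whose last dimension indexes b-values.
#' @param b_values b-values of the series, s/mm2.
#' @param b_low,b_high The two b-values used (defaults 0 and 800).
#' @param roi Optional logical array restricting the fit.
#' @return A [parameter_map()] named `"adc"` in 1e-3 mm2/s.
#' @examples
#' s <- array(c(1000, 1000 * exp(-0.8 * 1.179)), c(1, 1, 2))
#' compute_adc(s, c(0, 800))$values  # 1.179
#' @export
compute_adc <- function(series, b_values, b_low = 0, b_high = 800,
                        roi = NULL) {
  S <- series_matrix(series)
  if (ncol(S) != length(b_values)) {
    stop("series does not match b_values", call. = FALSE)
  }
  i_lo <- match(b_low, b_values); i_hi <- match(b_high, b_values)
  if (is.na(i_lo) || is.na(i_hi)) {
    stop(sprintf("requested b-values (%g, %g) not in series; available: %s",
                 b_low, b_high, paste(b_values, collapse = ", ")),
         call. = FALSE)
  }
  grid <- dim(series)[-length(dim(series))]
  s0 <- S[, i_lo]; sb <- S[, i_hi]
  adc <- log(s0 / sb) / (b_high - b_low) * 1e3   # to 1e-3 mm2/s
  ok <- is.finite(adc) & s0 > 0 & sb > 0 & adc > 0
  n_negative <- sum(is.finite(adc) & adc <= 0 & s0 > 0 & sb > 0)
  neg_vals <- adc[is.finite(adc) & adc <= 0]
  adc[!ok] <- NA_real_
  ok <- apply_roi(ok, roi)
  adc[!ok] <- NA_real_
  shape <- function(x) { dim(x) <- grid; x }
  parameter_map(shape(adc), "adc", "1e-3 mm2/s", shape(ok),
                diagnostics = list(n_negative_adc = n_negative,
                                   negative_adc_values = neg_vals,
                                   n_invalid = sum(!ok)))
}

# upper bound for fitted pseudo-diffusion, 1e-3 mm2/s (= 0.5 mm2/s)
IVIM_DSTAR_CAP <- 500

#' Segmented-then-full bi-exponential IVIM fit
#'
#' Voxel-wise intravoxel-incoherent-motion fit of
#' `S(b) = S0 * ((1 - f) * exp(-b D) + f * exp(-b D*))` over the full
#' b-value ladder. Initialization follows the segmented strategy standard
#' for liver IVIM: (i) log-linear fit over `b >= b_split` (where the
#' pseudo-diffusion compartment has decayed away) gives D and an intercept;
#' (ii) the perfusion fraction starts at `f = 1 - intercept / S0`;
#' (iii) D* is found by one-dimensional least squares on the full curve with
#' the other parameters held. A full Levenberg-Marquardt fit of
#' `(S0, f, D, D*)` then refines all parameters under the bounds
#' `f` in [0, 1], `D` in (0, cap], `D*` in (0, cap] with cap = 500 (1e-3
#' mm2/s); S0 is the *fitted* b = 0 intercept (the measured S0 is only the
#' starting value). Voxels where D and D* cross are swapped back and
#' flagged; fit divergence marks the voxel invalid; `f` pinned at a bound is
#' flagged (a pure mono-exponential voxel has unidentifiable D*).
#'
#' @param series Array whose last dimension indexes b-values.
#' @param b_values b-values, s/mm2, ascending, starting at 0.
#' @param b_split Threshold above which the signal is treated as
#'   mono-exponential for initialization (default 200 s/mm2).
#' @param roi Optional logical array restricting the fit.
#' @return List of class `ivim_result` with [parameter_map()]s `f`, `d`,
#'   `d_star` (plus `s0`), `fit_mode = "segmented_then_full"`, and shared
#'   diagnostics (per-voxel convergence flag, residual norms at
#'   initialization and after the full fit, bound-pin flags).
#' @export
fit_ivim <- function(series, b_values, b_split = 200, roi = NULL) {
  S <- series_matrix(series)
  if (ncol(S) != length(b_values)) stop("series does not match b_values", call. = FALSE)
  if (b_values[1] != 0) stop("b-value ladder must start at 0", call. = FALSE)
  hi <- b_values >= b_split
  if (length(b_values) < 4 || sum(hi) < 2 || sum(!hi) < 1) {
    stop("need >= 4 b-values spanning both sides of b_split", call. = FALSE)
  }
  grid <- dim(series)[-length(dim(series))]
  nvox <- nrow(S)
  b <- b_values

  ivim_model <- function(par, b) {
    par[["s0"]] * ((1 - par[["f"]]) * exp(-b * par[["d"]] * 1e-3) +
                     par[["f"]] * exp(-b * par[["ds"]] * 1e-3))
  }

  f_map <- d_map <- ds_map <- s0_map <- rep(NA_real_, nvox)
  converged <- pinned_f <- swapped <- rep(FALSE, nvox)
  res_init <- res_full <- rep(NA_real_, nvox)

  # vectorized segmented initialization: log-linear over b >= b_split
  bh <- b[hi]
  Yh <- log(S[, hi, drop = FALSE])
  Yh[!is.finite(Yh)] <- NA_real_
  Wh <- !is.na(Yh)
  nh <- rowSums(Wh)
  Bh <- matrix(bh, nvox, length(bh), byrow = TRUE); Bh[!Wh] <- 0
  Yh0 <- Yh; Yh0[!Wh] <- 0
  sx <- rowSums(Bh); sy <- rowSums(Yh0)
  sxx <- rowSums(Bh^2); sxy <- rowSums(Bh * Yh0)
  den <- nh * sxx - sx^2
  slope <- (nh * sxy - sx * sy) / den
  interc <- exp((sy - slope * sx) / nh)
  d0 <- pmax(-slope * 1e3, 1e-4)            # 1e-3 mm2/s
  s0_meas <- S[, 1]
  f0 <- pmin(pmax(1 - interc / s0_meas, 0), 1)

  usable <- nh >= 2 & is.finite(d0) & s0_meas > 0
  if (!is.null(roi)) usable <- usable & as.logical(roi)  # skip background
  for (v in which(usable)) {
    sv <- S[v, ]
    # 1-D search for d_star on the full curve, others held at init
    rss_ds <- function(ds) {
      sum((sv - ivim_model(list(s0 = s0_meas[v], f = f0[v],
                                d = d0[v], ds = ds), b))^2)
    }
    ds0 <- if (f0[v] > 1e-6) {
      stats::optimize(rss_ds, c(d0[v], IVIM_DSTAR_CAP))$minimum
    } else {
      10 * d0[v]   # f = 0: d_star unidentifiable, any starting value
    }
    # a start exactly on the f = 0 boundary zeroes the d_star Jacobian
    # column; nudge just inside (Levenberg-Marquardt damping handles the
    # remaining near-singularity)
    f_start <- min(max(f0[v], 1e-4), 1 - 1e-4)
    ds_start <- max(ds0, 2 * d0[v])
    start <- c(s0 = s0_meas[v], f = f_start, d = d0[v], ds = ds_start)
    residfun <- function(par) {
      sv - ivim_model(as.list(par), b)
    }
    res_init[v] <- sqrt(sum(residfun(start)^2))
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, fn = residfun,
        lower = c(.Machine$double.eps, 0, 1e-6, 1e-6),
        upper = c(Inf, 1, IVIM_DSTAR_CAP, IVIM_DSTAR_CAP),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- fit$par
    f_v <- cf[["f"]]; d_v <- cf[["d"]]; ds_v <- cf[["ds"]]
    if (ds_v < d_v) {            # compartments crossed: relabel
      tmp <- d_v; d_v <- ds_v; ds_v <- tmp
      f_v <- 1 - f_v
      swapped[v] <- TRUE
    }
    f_map[v] <- f_v; d_map[v] <- d_v; ds_map[v] <- ds_v
    s0_map[v] <- cf[["s0"]]
    res_full[v] <- sqrt(fit$deviance)
    converged[v] <- fit$info %in% 1:4
    pinned_f[v] <- f_v <= 1e-8 || f_v >= 1 - 1e-8
  }

  ok <- is.finite(d_map) & converged
  ok <- apply_roi(ok, roi)
  for (m in c("f_map", "d_map", "ds_map", "s0_map")) {
    x <- get(m); x[!ok] <- NA_real_; assign(m, x)
  }
  shape <- function(x) { dim(x) <- grid; x }
  diag <- list(converged = shape(converged),
               residual_norm_init = shape(res_init),
               residual_norm_full = shape(res_full),
               f_at_bound = shape(pinned_f),
               compartments_swapped = shape(swapped),
               n_invalid = sum(!ok))
  structure(
    list(f = parameter_map(shape(f_map), "f", "fraction", shape(ok), diag),
         d = parameter_map(shape(d_map), "d", "1e-3 mm2/s", shape(ok), diag),
         d_star = parameter_map(shape(ds_map), "d_star", "1e-3 mm2/s",
                                shape(ok), diag),
         s0 = parameter_map(shape(s0_map), "s0", "a.u.", shape(ok), diag),
         fit_mode = "segmented_then_full",
         diagnostics = diag),
    class = "ivim_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' ROI histogram summary of a parameter map
#'
#' Mean, Fisher skewness (third standardized moment) and Fisher excess
#' kurtosis (fourth standardized moment minus 3) of the map values over the
#' ROI voxels with a valid fit, using bias-uncorrected moment ratios
#' (`bias_correct = TRUE` switches to the sample-adjusted G1/G2 variants).
#' Skewness needs at least 3 usable voxels and kurtosis at least 4; a
#' zero-variance (constant) ROI leaves both undefined (`NA`), with the mean
#' still reported.
#'
#' @param map A [parameter_map()].
#' @param roi Logical array; intersected with the map's valid mask.
#' @param bias_correct Use bias-corrected skewness/kurtosis (default
#'   `FALSE`).
#' @return List with `mean`, `skewness`, `kurtosis`, `n_voxels`.
#' @examples
#' m <- parameter_map(array(1:5, 5), "x", "", array(rep(TRUE, 5), 5))
#' histogram_summary(m, array(rep(TRUE, 5), 5))$skewness  # 0
#' @export
histogram_summary <- function(map, roi = NULL, bias_correct = FALSE) {
  stopifnot(inherits(map, "parameter_map"))
  use <- map$valid
  if (!is.null(roi)) use <- use & as.logical(roi)
  x <- map$values[use]
  n <- length(x)
  if (n == 0) {
    return(list(mean = NA_real_, skewness = NA_real_, kurtosis = NA_real_,
                n_voxels = 0L))
  }
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  skew <- kurt <- NA_real_
  if (n >= 3 && m2 > 0) {
    g1 <- mean((x - mu)^3) / m2^1.5
    skew <- if (bias_correct) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
  }
  if (n >= 4 && m2 > 0) {
    g2 <- mean((x - mu)^4) / m2^2 - 3
    kurt <- if (bias_correct) {
      ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
    } else g2
  }
  list(mean = mu, skewness = skew, kurtosis = kurt, n_voxels = n)
}
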