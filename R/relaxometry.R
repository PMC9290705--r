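#' Voxel-wise variable-flip-angle T1 fit
#'
#' Estimates T1 and m0 per voxel from spoiled-gradient-echo signals acquired
#' at two or more flip angles. The fit is initialized from the linearized
#' form of the steady-state signal equation — regressing `S/sin(theta)` on
#' `S/tan(theta)`, whose slope is `E1 = exp(-TR/T1)` — and then refined by
#' Levenberg-Marquardt nonlinear least squares on the full model. With
#' exactly two flip angles the linearized solution already interpolates the
#' data (zero residual), so it is the Levenberg-Marquardt fixed point and
#' refinement terminates immediately; the refinement step therefore only
#' iterates for over-determined (3+ angle) protocols or when the linearized
#' solve is inexact.
#'
#' Voxels whose linearized slope falls outside (0, 1), or whose T1 falls
#' outside the validity window (0.1, 10000] msec, are marked invalid (an
#' all-zero voxel is invalid, not an error).
#'
#' @param signals_per_angle Array whose last dimension indexes flip angles
#'   (matching `protocol$t1_map_flip_angles`).
#' @param protocol An [acquisition_protocol()].
#' @param roi Optional logical array restricting the fit.
#' @param refine Run Levenberg-Marquardt refinement after the linearized
#'   solve (default `TRUE`; skipped voxel-wise when the linearized residual
#'   is already at machine precision).
#' @param valid_range Acceptance window for fitted T1, msec.
#' @return List with elements `t1` and `m0`, both [parameter_map()]s;
#'   diagnostics carry the per-voxel residual norm and a refinement count.
#' @examples
#' prot <- acquisition_protocol()
#' s <- sapply(prot$t1_map_flip_angles, function(a) vfa_signal(901, 1000, a, 15))
#' fit <- fit_t1_vfa(array(s, c(1, 1, 2)), prot)
#' fit$t1$values  # 901
#' @export
fit_t1_vfa <- function(signals_per_angle, protocol, roi = NULL,
                       refine = TRUE,
                       valid_range = RELAXATION_VALID_RANGE) {
  angles <- protocol$t1_map_flip_angles
  if (length(angles) < 2) stop("need at least 2 flip angles", call. = FALSE)
  S <- series_matrix(signals_per_angle)
  if (ncol(S) != length(angles)) {
    stop("signal series does not match the protocol's flip angle count",
         call. = FALSE)
  }
  tr <- protocol$t1_map_tr
  grid <- dim(signals_per_angle)[-length(dim(signals_per_angle))]
  th <- angles * pi / 180
  Y <- sweep(S, 2, sin(th), "/")
  X <- sweep(S, 2, tan(th), "/")
  xbar <- rowMeans(X); ybar <- rowMeans(Y)
  sxx <- rowSums((X - xbar)^2)
  sxy <- rowSums((X - xbar) * (Y - ybar))
  slope <- sxy / sxx                      # = E1
  intercept <- ybar - slope * xbar
  ok <- is.finite(slope) & slope > 0 & slope < 1
  t1 <- rep(NA_real_, nrow(S)); m0 <- rep(NA_real_, nrow(S))
  t1[ok] <- -tr / log(slope[ok])
  m0[ok] <- intercept[ok] / (1 - slope[ok])
  ok <- ok & is.finite(t1) & t1 > valid_range[1] & t1 <= valid_range[2] &
    is.finite(m0) & m0 > 0
  ok <- apply_roi(ok, roi)

  # residual of the nonlinear model at the linearized solution
  resid_norm <- rep(NA_real_, nrow(S))
  pred <- function(t1v, m0v) {
    e1 <- exp(-tr / t1v)
    vapply(seq_along(th), function(j) {
      m0v * sin(th[j]) * (1 - e1) / (1 - e1 * cos(th[j]))
    }, numeric(length(t1v)))
  }
  if (any(ok)) {
    P <- pred(t1[ok], m0[ok])
    if (is.null(dim(P))) P <- matrix(P, nrow = 1)
    resid_norm[ok] <- sqrt(rowSums((S[ok, , drop = FALSE] - P)^2))
  }

  n_refined <- 0L
  if (refine && any(ok)) {
    scale <- pmax(rowSums(abs(S)), .Machine$double.eps)
    need <- which(ok & resid_norm / scale > 1e-10)
    for (v in need) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          s ~ m0v * sin(theta) * (1 - exp(-tr / t1v)) /
            (1 - exp(-tr / t1v) * cos(theta)),
          data = list(s = S[v, ], theta = th, tr = tr),
          start = list(t1v = t1[v], m0v = m0[v]),
          lower = c(valid_range[1], .Machine$double.eps),
          upper = c(valid_range[2], Inf),
          control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        cf <- stats::coef(fit)
        t1[v] <- cf[["t1v"]]; m0[v] <- cf[["m0v"]]
        resid_norm[v] <- sqrt(sum(stats::resid(fit)^2))
        n_refined <- n_refined + 1L
      }
    }
  }

  t1[!ok] <- NA_real_; m0[!ok] <- NA_real_
  shape <- function(x) { dim(x) <- grid; x }
  diag <- list(residual_norm = shape(resid_norm), n_refined = n_refined,
               n_invalid = sum(!ok))
  list(t1 = parameter_map(shape(t1), "t1", "msec", shape(ok), diag),
       m0 = parameter_map(shape(m0), "m0", "a.u.", shape(ok), diag))
}

#' Voxel-wise log-linear mono-exponential decay fit (T2 / T2*)
#'
#' Fits `S(TE) = m0 * exp(-TE / T)` per voxel by ordinary least squares of
#' `ln(S)` on TE over the retained echoes, the way clinical workstations
#' generate T2 and T2* maps. The first echo is discarded by default (short-TE
#' effect); echoes with nonpositive signal are dropped per voxel; voxels left
#' with fewer than two usable echoes, or with a nonnegative or nonfinite
#' slope (no decay information), are marked invalid. The decay time is
#' `T = -1 / slope`.
#'
#' @param echo_signals Array whose last dimension indexes echoes.
#' @param te_list Echo times, msec, matching the last dimension.
#' @param discard_first Drop the first echo before fitting (default `TRUE`).
#' @param quantity Label for the output map (`"t2"` or `"t2star"`).
#' @param roi Optional logical array restricting the fit.
#' @param valid_range Acceptance window for the fitted decay time, msec.
#' @return A [parameter_map()]; diagnostics include per-voxel residual norm
#'   of the log-domain fit and the per-voxel count of retained echoes.
#' @examples
#' tes <- c(17.4, 34.8, 52.2, 69.6, 87.0, 104.4)
#' s <- array(500 * exp(-tes / 35.9), c(1, 1, 6))
#' fit_monoexp_decay(s, tes)$values  # 35.9
#' @export
fit_monoexp_decay <- function(echo_signals, te_list, discard_first = TRUE,
                              quantity = "t2", roi = NULL,
                              valid_range = RELAXATION_VALID_RANGE) {
  nte <- length(te_list)
  if (nte < 3) stop("need at least 3 echoes before discard", call. = FALSE)
  S <- series_matrix(echo_signals)
  if (ncol(S) != nte) stop("signal series does not match te_list", call. = FALSE)
  grid <- dim(echo_signals)[-length(dim(echo_signals))]
  keep <- if (discard_first) -1L else seq_len(nte)
  S <- S[, keep, drop = FALSE]
  te <- te_list[keep]

  Y <- suppressWarnings(log(S))           # negatives handled just below
  Y[S <= 0 | !is.finite(S)] <- NA_real_   # per-voxel echo drop
  W <- !is.na(Y)
  n <- rowSums(W)
  TE <- matrix(te, nrow = nrow(S), ncol = length(te), byrow = TRUE)
  TEw <- TE; TEw[!W] <- 0
  Yw <- Y; Yw[!W] <- 0
  sx <- rowSums(TEw); sy <- rowSums(Yw)
  sxx <- rowSums(TEw^2); sxy <- rowSums(TEw * Yw)
  denom <- n * sxx - sx^2
  slope <- (n * sxy - sx * sy) / denom
  intercept <- (sy - slope * sx) / n

  tval <- -1 / slope
  ok <- n >= 2 & is.finite(slope) & slope < 0 &
    is.finite(tval) & tval > valid_range[1] & tval <= valid_range[2]
  tval[!ok] <- NA_real_

  fitted <- intercept + slope * TE
  res2 <- (Y - fitted)^2; res2[!W] <- 0
  resid_norm <- sqrt(rowSums(res2))
  resid_norm[!ok] <- NA_real_

  ok <- apply_roi(ok, roi)
  tval[!ok] <- NA_real_
  shape <- function(x) { dim(x) <- grid; x }
  parameter_map(shape(tval), quantity, "msec", shape(ok),
                diagnostics = list(residual_norm = shape(resid_norm),
                                   n_echoes_used = shape(n),
                                   n_invalid = sum(!ok)))
}

#' Post-contrast T1 shortening map
#'
#' Voxel-wise `delta-T1 = T1_native - T1_post` on the intersection of the
#' two maps' valid masks. Negative values (post-contrast T1 above native,
#' possible under noise) are retained, not clipped, and counted in the
#' diagnostics.
#'
#' @param native_map,post_map [parameter_map()]s on the same grid.
#' @return A [parameter_map()] named `"delta_t1"`.
#' @export
compute_delta_t1 <- function(native_map, post_map) {
  stopifnot(inherits(native_map, "parameter_map"),
            inherits(post_map, "parameter_map"))
  if (!identical(dim(native_map$values), dim(post_map$values))) {
    stop("native and post-contrast maps are on different grids", call. = FALSE)
  }
  valid <- native_map$valid & post_map$valid
  if (!any(valid)) {
    warning("native and post-contrast valid masks do not overlap; ",
            "delta-T1 map is empty")
  }
  vals <- rep(NA_real_, length(valid))
  vals[valid] <- native_map$values[valid] - post_map$values[valid]
  dim(vals) <- dim(native_map$values)
  parameter_map(vals, "delta_t1", "msec", valid,
                diagnostics = list(n_negative = sum(vals[valid] < 0),
                                   n_invalid = sum(!valid)))
}
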