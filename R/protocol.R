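#' MRI acquisition protocol
#'
#' Bundle of the sequence timing and encoding constants every voxel-wise fit
#' needs: the spoiled-gradient-echo repetition time and flip angles used for
#' variable-flip-angle (VFA) T1 mapping, the echo-time trains for multi-echo
#' spin-echo T2 and gradient-echo T2* mapping, and the diffusion b-value
#' ladder. Defaults reproduce the 3.0 T mouse liver protocol used throughout
#' this package: two flip angles (5 deg, 26 deg) at TR 15 msec, six T2 echoes
#' from 17.4 to 104.4 msec, five T2* echoes from 6.71 to 51.43 msec, and nine
#' b-values from 0 to 1000 s/mm2.
#'
#' @param t1_map_tr Repetition time of the VFA T1-mapping sequence, msec.
#' @param t1_map_flip_angles Flip angles in degrees, each in (0, 90].
#' @param t2_map_tes Echo times of the T2-mapping train, msec, strictly
#'   increasing.
#' @param t2star_map_tes Echo times of the T2*-mapping train, msec, strictly
#'   increasing.
#' @param dwi_b_values Diffusion weightings in s/mm2, strictly increasing and
#'   starting at 0.
#' @return An object of class `acquisition_protocol` (a validated list with
#'   the five fields above).
#' @examples
#' p <- acquisition_protocol()
#' p$dwi_b_values
#' @export
acquisition_protocol <- function(t1_map_tr = 15,
                                 t1_map_flip_angles = c(5, 26),
                                 t2_map_tes = c(17.4, 34.8, 52.2, 69.6, 87.0, 104.4),
                                 t2star_map_tes = c(6.71, 17.89, 29.07, 40.25, 51.43),
                                 dwi_b_values = c(0, 50, 100, 150, 200, 400, 600, 800, 1000)) {
  stopifnot(is.numeric(t1_map_tr), length(t1_map_tr) == 1, t1_map_tr > 0)
  if (length(t1_map_flip_angles) < 2) {
    stop("VFA T1 mapping needs at least two flip angles", call. = FALSE)
  }
  if (any(t1_map_flip_angles <= 0) || any(t1_map_flip_angles > 90)) {
    stop("flip angles must lie in (0, 90] degrees", call. = FALSE)
  }
  check_te <- function(te, what) {
    if (any(te <= 0) || any(diff(te) <= 0)) {
      stop(what, " echo times must be positive and strictly increasing",
           call. = FALSE)
    }
  }
  check_te(t2_map_tes, "T2")
  check_te(t2star_map_tes, "T2*")
  if (dwi_b_values[1] != 0 || any(diff(dwi_b_values) <= 0)) {
    stop("b-values must start at 0 and be strictly increasing", call. = FALSE)
  }
  structure(
    list(t1_map_tr = t1_map_tr,
         t1_map_flip_angles = as.numeric(t1_map_flip_angles),
         t2_map_tes = as.numeric(t2_map_tes),
         t2star_map_tes = as.numeric(t2star_map_tes),
         dwi_b_values = as.numeric(dwi_b_values)),
    class = "acquisition_protocol"
  )
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat("<acquisition_protocol>\n")
  cat("  VFA T1 map : TR", x$t1_map_tr, "msec, flip angles",
      paste(x$t1_map_flip_angles, collapse = ", "), "deg\n")
  cat("  T2 map TEs : ", paste(x$t2_map_tes, collapse = ", "), " msec\n", sep = "")
  cat("  T2* map TEs: ", paste(x$t2star_map_tes, collapse = ", "), " msec\n", sep = "")
  cat("  DWI b      : ", paste(x$dwi_b_values, collapse = ", "), " s/mm2\n", sep = "")
  invisible(x)
}

#' Ground-truth tissue parameter set for one liver lobe
#'
#' Holds the quantities the simulator imprints on a voxel volume and the fits
#' are expected to recover: native T1 and the post-contrast T1 shortening
#' `delta_t1` (so T1_post = `t1_native - delta_t1`), T2 and T2* (all msec),
#' the apparent diffusion coefficient `adc` and IVIM true diffusion `d` and
#' pseudo-diffusion `d_star` (all in 1e-3 mm2/s), the perfusion fraction `f`,
#' and the proton-density signal scale `m0` (arbitrary units).
#'
#' @param t1_native,delta_t1,t2,t2star Relaxation quantities, msec.
#' @param adc,d,d_star Diffusion quantities, 1e-3 mm2/s; `d_star > d > 0`.
#' @param f Perfusion fraction in [0, 1].
#' @param m0 Proton-density scale, arbitrary units, > 0.
#' @return An object of class `tissue_params`.
#' @examples
#' tp <- tissue_params(t1_native = 966.31, delta_t1 = 468.08, t2 = 35.9,
#'                     t2star = 12.7, adc = 1.179, d = 1.087)
#' tp$t1_native - tp$delta_t1  # post-contrast T1
#' @export
tissue_params <- function(t1_native, delta_t1, t2, t2star, adc,
                          d, d_star = 50, f = 0.20, m0 = 1000) {
  vals <- c(t1_native = t1_native, delta_t1 = delta_t1, t2 = t2,
            t2star = t2star, adc = adc, d = d, d_star = d_star,
            f = f, m0 = m0)
  if (any(!is.finite(vals))) stop("tissue parameters must be finite", call. = FALSE)
  if (t1_native <= 0 || t2 <= 0 || t2star <= 0) {
    stop("relaxation times must be positive", call. = FALSE)
  }
  if (delta_t1 >= t1_native) {
    stop("delta_t1 must be smaller than t1_native (post-contrast T1 > 0)",
         call. = FALSE)
  }
  if (f < 0 || f > 1) stop("perfusion fraction f must lie in [0, 1]", call. = FALSE)
  if (!(d_star > d && d > 0)) stop("need d_star > d > 0", call. = FALSE)
  if (adc <= 0) stop("adc must be positive", call. = FALSE)
  if (m0 <= 0) stop("m0 must be positive", call. = FALSE)
  structure(as.list(vals), class = "tissue_params")
}
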