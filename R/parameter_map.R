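#' Voxel-wise fitted parameter map
#'
#' Container for one fitted quantity on a voxel grid: the values, the mask of
#' voxels with a successful (valid) fit, and per-voxel diagnostics.
#'
#' @param values Numeric array of fitted values (`NA` where invalid).
#' @param quantity Name of the quantity, e.g. `"t1_native"`, `"adc"`.
#' @param unit Unit string, e.g. `"msec"` or `"1e-3 mm2/s"`.
#' @param valid Logical array, same shape as `values`.
#' @param diagnostics Named list of per-voxel or summary diagnostics
#'   (residual norms, convergence flags, counts).
#' @return Object of class `parameter_map`.
#' @export
parameter_map <- function(values, quantity, unit, valid,
                          diagnostics = list()) {
  if (!identical(dim(values), dim(valid)) &&
      !(is.null(dim(values)) && is.null(dim(valid)) &&
        length(values) == length(valid))) {
    stop("values and valid mask must share a grid", call. = FALSE)
  }
  bad <- valid & (!is.finite(values))
  if (any(bad)) stop("valid voxels must hold finite values", call. = FALSE)
  structure(list(values = values, quantity = quantity, unit = unit,
                 valid = valid, diagnostics = diagnostics),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  nv <- sum(x$valid)
  cat(sprintf("<parameter_map> %s [%s]: %d/%d valid voxels",
              x$quantity, x$unit, nv, length(x$valid)))
  if (nv > 0) {
    cat(sprintf(", mean %.4g", mean(x$values[x$valid])))
  }
  cat("\n")
  invisible(x)
}

# default validity window for fitted relaxation times, msec; guards
# log-domain blow-ups from near-zero or near-unity decay estimates
RELAXATION_VALID_RANGE <- c(0.1, 10000)

# restrict a validity mask to an optional ROI
apply_roi <- function(valid, roi) {
  if (is.null(roi)) return(valid)
  valid & as.logical(roi)
}
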