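#' Write simulated lobe volumes as NIfTI
#'
#' One compressed NIfTI file per series element (flip angle, echo or
#' b-value), named `<animal>_<lobe>_<sequence>_<index>.nii.gz`, plus the ROI
#' and exclusion masks.
#'
#' @param volumes A `lobe_volumes` object from [simulate_lobe_volumes()].
#' @param dir Output directory (created if needed).
#' @param animal,lobe Identifiers used in the file names.
#' @return Invisibly, the vector of files written.
#' @export
write_lobe_volumes <- function(volumes, dir, animal, lobe) {
  stopifnot(inherits(volumes, "lobe_volumes"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  put <- function(arr, tag) {
    f <- file.path(dir, sprintf("%s_%s_%s.nii.gz", animal, lobe, tag))
    RNifti::writeNifti(arr, f)
    written <<- c(written, f)
  }
  for (seq_name in c("t1_vfa_native", "t1_vfa_post", "t2_echoes",
                     "t2star_echoes", "dwi")) {
    arr <- volumes[[seq_name]]
    nd <- length(dim(arr))
    k <- dim(arr)[nd]
    flat <- series_matrix(arr)
    for (i in seq_len(k)) {
      vol <- array(flat[, i], dim = dim(arr)[-nd])
      put(vol, sprintf("%s_%02d", seq_name, i))
    }
  }
  put(volumes$roi_mask * 1L, "roi_mask")
  put(volumes$exclusion_mask * 1L, "exclusion_mask")
  invisible(written)
}

#' Read / write an FSL-style b-value file
#'
#' Plain text, one b-value per line.
#'
#' @param b_values Numeric vector of b-values.
#' @param path File path.
#' @return `read_bvals()` returns the numeric vector.
#' @export
write_bvals <- function(b_values, path) {
  writeLines(format(b_values, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' @rdname write_bvals
#' @export
read_bvals <- function(path) {
  as.numeric(readLines(path))
}

#' Write a results table as CSV with a provenance header
#'
#' Prepends `# config_hash: <hash>` comment lines so every output records
#' the run it came from; numeric columns are rounded to 6 significant
#' digits for the human-readable table (a full-precision JSON sidecar is
#' written alongside when `sidecar = TRUE`).
#'
#' @param df Data frame.
#' @param path Output CSV path.
#' @param config_hash Provenance string recorded in the header.
#' @param sidecar Also write `<path>.full.json` at full precision.
#' @return Invisibly, `path`.
#' @export
write_result_csv <- function(df, path, config_hash = NA_character_,
                             sidecar = FALSE) {
  if (sidecar) {
    jsonlite::write_json(df, paste0(path, ".full.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", config_hash), con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Read a results CSV written by [write_result_csv()]
#'
#' @param path CSV path.
#' @return A data frame (the provenance header is skipped).
#' @export
read_result_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
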