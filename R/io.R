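#' Write and read voxel tables as NIfTI-1 volumes
#'
#' Converts between the long voxel-table representation used throughout the
#' package and NIfTI-1 volumes on disk (one file per parameter, RAS+ identity
#' affine with B0 along the third axis). Requires the RNifti package.
#'
#' @param data Voxel table with integer grid columns `x`, `y`, `z` and the
#'   parameter columns to export.
#' @param dims Grid dimensions.
#' @param params Character vector of column names to write.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return `write_maps_nifti()` returns the written paths invisibly;
#'   `read_maps_nifti()` returns a voxel tibble.
#' @export
write_maps_nifti <- function(data, dims, params = c("R1", "R2", "AI"),
                             dir = ".", prefix = "map") {
  if (!requireNamespace("RNifti", quietly = TRUE))
    abort("RNifti is required for NIfTI export.")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  idx <- cbind(data$x, data$y, data$z)
  paths <- vapply(params, function(p) {
    arr <- array(NA_real_, dims)
    arr[idx] <- data[[p]]
    path <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, p))
    RNifti::writeNifti(RNifti::asNifti(arr), path)
    path
  }, character(1))
  invisible(paths)
}

#' @rdname write_maps_nifti
#' @param paths Named character vector of NIfTI paths (names become columns).
#' @export
read_maps_nifti <- function(paths) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    abort("RNifti is required for NIfTI import.")
  arrs <- lapply(paths, function(p) as.array(RNifti::readNifti(p)))
  dims <- dim(arrs[[1]])
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  out <- tibble(x = g$x, y = g$y, z = g$z)
  nm <- names(paths) %||% paste0("map", seq_along(paths))
  for (i in seq_along(arrs)) out[[nm[i]]] <- as.vector(arrs[[i]])
  out
}

#' Write a binned curve to CSV / read it back
#'
#' @param curve A `binned_curve`.
#' @param path File path.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  out <- as_tibble(utils::read.csv(path))
  class(out) <- c("binned_curve", class(out))
  out
}

#' Export orientation fits as JSON
#'
#' @param fits A named list of `orientation_fit` objects.
#' @param path File path.
#' @export
write_fits_json <- function(fits, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    abort("jsonlite is required for JSON export.")
  payload <- lapply(fits, function(f)
    list(model = f$model, target = f$target,
         params = as.list(f$params), r_squared = f$r_squared))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
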