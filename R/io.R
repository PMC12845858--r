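#' Write a radial or line profile to CSV
#'
#' Full-precision CSV with header `radius,intensity` (or custom names).
#'
#' @param profile A [radial_profile()] or two-column data frame.
#' @param path Output path.
#' @param col_names Header names for the two columns.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path,
                              col_names = c("radius", "intensity")) {
  if (!is.data.frame(profile) || nrow(profile) == 0L)
    stop("refusing to write an empty profile: ", path)
  df <- stats::setNames(profile[, 1:2], col_names)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an intensity map as 32-bit float TIFF
#'
#' Values are stored peak-normalized to \[0, 1\] (the float TIFF container
#' is defined on that range); the peak value needed to undo the scaling is
#' returned and recorded in run manifests.
#'
#' @param map An [intensity_map()] or numeric matrix.
#' @param path Output path.
#' @return Invisibly, a list with `path` and `peak` (the pre-normalization
#'   maximum).
#' @export
write_map_tiff <- function(map, path) {
  v <- if (is.list(map)) map$values else map
  if (!is.matrix(v) || length(v) == 0L) stop("refusing to write empty map: ", path)
  peak <- max(v)
  if (peak > 0) v <- v / peak
  tiff::writeTIFF(v, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(list(path = path, peak = peak))
}

#' Write an intensity map as peak-normalized 8-bit PNG
#'
#' @inheritParams write_map_tiff
#' @return `path`, invisibly.
#' @export
write_map_png <- function(map, path) {
  v <- if (is.list(map)) map$values else map
  if (!is.matrix(v) || length(v) == 0L) stop("refusing to write empty map: ", path)
  if (max(v) > 0) v <- v / max(v)
  png::writePNG(v, path)
  invisible(path)
}

#' Write a metrics list as JSON
#'
#' Stable key order (input order), unboxed scalars, full precision.
#'
#' @param metrics Named list of scalars/vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  if (length(metrics) == 0L || is.null(names(metrics)))
    stop("metrics must be a non-empty named list")
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records every effective parameter of a run (including the seed and the
#' package version) as JSON, sufficient to reproduce the run's outputs
#' bitwise.
#'
#' @param params Named list of effective parameters.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(params, path) {
  params$package <- "psexcite"
  params$version <- as.character(utils::packageVersion("psexcite"))
  write_metrics_json(params, path)
}
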