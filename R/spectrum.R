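#' Mass spectrum container
#'
#' @param mz Strictly ascending m/z values (Da).
#' @param intensity Non-negative intensities, same length.
#' @param spot_id Optional spot identifier.
#' @param meta Optional named list of acquisition metadata.
#' @return A `mass_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity, spot_id = NULL, meta = list()) {
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ")
  if (is.unsorted(mz, strictly = TRUE)) {
    warning("m/z not strictly ascending; sorting")
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
  }
  structure(list(mz = mz, intensity = intensity, spot_id = spot_id,
                 meta = meta), class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat("<mass_spectrum> ", length(x$mz), " points, m/z [",
      round(x$mz[1], 3), ", ", round(x$mz[length(x$mz)], 3), "]",
      if (!is.null(x$spot_id)) paste0(", spot ", x$spot_id), "\n", sep = "")
  invisible(x)
}

#' Spectral matrix container
#'
#' All spots resampled onto one common m/z grid: an `n_spots x n_gridpoints`
#' intensity (or SNR) matrix plus the per-spot calibration offsets.
#'
#' @param grid Ascending common m/z grid.
#' @param mat Intensity matrix, one row per spot.
#' @param spot_ids Spot identifiers (default 1..n).
#' @param offsets_ppm Per-spot calibration offsets that were removed.
#' @param snr Whether values are SNR-transformed.
#' @return A `spectral_matrix`.
#' @export
spectral_matrix <- function(grid, mat, spot_ids = seq_len(nrow(mat)),
                            offsets_ppm = rep(NA_real_, nrow(mat)),
                            snr = FALSE) {
  mat <- as.matrix(mat)
  if (ncol(mat) != length(grid)) stop("matrix width must match grid length")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be ascending")
  structure(list(grid = grid, mat = mat, spot_ids = spot_ids,
                 offsets_ppm = offsets_ppm, snr = snr),
            class = "spectral_matrix")
}

#' @export
print.spectral_matrix <- function(x, ...) {
  cat("<spectral_matrix> ", nrow(x$mat), " spots x ", length(x$grid),
      " grid points, m/z [", round(x$grid[1], 3), ", ",
      round(x$grid[length(x$grid)], 3), "], ",
      if (x$snr) "SNR" else "intensity", " values\n", sep = "")
  invisible(x)
}
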