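plate_row_names <- function(n) {
  # A..Z, AA, AB, ... (1536-well plates use A..AF for 32 rows)
  one <- LETTERS
  two <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(one, two)[seq_len(n)]
}

#' Lay mixtures out on a MALDI plate grid
#'
#' Assigns mixtures to spots row-major on a rows x cols grid (default
#' 32 x 48 = 1536 spots) with alphanumeric well names (A1 ... AF48).
#'
#' @param n_mixtures Number of mixtures (<= rows * cols).
#' @param rows,cols Grid geometry.
#' @param pitch_um Spot pitch metadata, micrometers (carried, not computed
#'   on).
#' @return A `plate_layout` data frame: `spot`, `row`, `col`, `well`.
#' @export
#' @examples
#' layout_plate(3)
layout_plate <- function(n_mixtures, rows = 32L, cols = 48L, pitch_um = 1000) {
  capacity <- rows * cols
  if (n_mixtures > capacity) {
    stop("plate capacity exceeded: ", n_mixtures, " mixtures > ", capacity,
         " spots")
  }
  stopifnot(n_mixtures >= 1L)
  spot <- seq_len(n_mixtures)
  r <- (spot - 1L) %/% cols + 1L
  c_ <- (spot - 1L) %% cols + 1L
  out <- data.frame(spot = spot, row = r, col = c_,
                    well = paste0(plate_row_names(rows)[r], c_))
  attr(out, "geometry") <- list(rows = rows, cols = cols, pitch_um = pitch_um)
  class(out) <- c("plate_layout", "data.frame")
  out
}

#' Build an acoustic transfer list for a presence matrix
#'
#' One droplet record per presence-matrix "1" (source library well ->
#' destination spot) plus one matrix-solution record per spot. The per-spot
#' liquid budget is enforced: `droplet_nl * n_present + matrix_nl` must not
#' exceed `max_spot_nl` (spots merge beyond ~200 nL on a 1536-spot grid).
#'
#' @param matrix A `presence_matrix`.
#' @param layout A [layout_plate()] for `nrow(matrix)` mixtures.
#' @param library_wells Character vector of source well names, one per
#'   compound column (default: row-major wells of a 1536-well library plate).
#' @param droplet_nl Droplet volume per inclusion (nL).
#' @param matrix_nl MALDI matrix volume per spot (nL).
#' @param max_spot_nl Per-spot volume bound (nL).
#' @return A `transfer_list` data frame: `SourceWell`, `DestinationWell`,
#'   `VolumeNL`.
#' @export
write_transfer_list <- function(matrix, layout,
                                library_wells = NULL,
                                droplet_nl = 2.5, matrix_nl = 30,
                                max_spot_nl = 200) {
  if (nrow(layout) != nrow(matrix)) stop("layout does not cover all mixtures")
  if (is.null(library_wells)) {
    lw <- layout_plate(ncol(matrix))
    library_wells <- lw$well
  }
  if (length(library_wells) != ncol(matrix)) {
    stop("every compound needs a source well")
  }
  vol <- rowSums(matrix) * droplet_nl + matrix_nl
  over <- which(vol > max_spot_nl)
  if (length(over)) {
    stop("per-spot volume exceeds ", max_spot_nl, " nL at spot(s) ",
         paste(head(over, 5), collapse = ", "), " (", max(vol), " nL)")
  }
  ones <- which(unclass_matrix(matrix) == 1L, arr.ind = TRUE)
  ones <- ones[order(ones[, 1], ones[, 2]), , drop = FALSE]
  rec <- data.frame(
    SourceWell = c(library_wells[ones[, 2]], rep("MATRIX", nrow(matrix))),
    DestinationWell = c(layout$well[ones[, 1]], layout$well),
    VolumeNL = c(rep(droplet_nl, nrow(ones)), rep(matrix_nl, nrow(matrix))))
  class(rec) <- c("transfer_list", "data.frame")
  rec
}

#' Plate capacity and dispense bookkeeping
#'
#' `plate_capacity_bits` is the direct-mapping capacity of a plate: one bit
#' per (compound, spot) pair. `n_dispenses` is how many droplets a library
#' well can source before depletion.
#'
#' @param n_compounds Compounds per mixture.
#' @param n_spots Spots on the plate.
#' @return Bits (numeric).
#' @export
#' @examples
#' plate_capacity_bits(575, 1536) / 1e6   # 0.88 megabits
plate_capacity_bits <- function(n_compounds, n_spots = 1536L) {
  as.numeric(n_compounds) * n_spots
}

#' @rdname plate_capacity_bits
#' @param well_volume_ul Library well volume, microliters.
#' @param droplet_nl Droplet volume, nanoliters.
#' @export
#' @examples
#' n_dispenses(4, 2.5)   # 1600
n_dispenses <- function(well_volume_ul = 4, droplet_nl = 2.5) {
  floor(well_volume_ul * 1000 / droplet_nl)
}
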