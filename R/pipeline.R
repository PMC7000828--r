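#' Configuration for an end-to-end write/read run
#'
#' A fully serializable description of a storage experiment; a run is
#' reproducible bit-for-bit from its config and seed.
#'
#' @param payload Bit vector, bilevel image matrix, or image file path.
#' @param mapping `"direct"` (one bit per compound per spot) or `"sparse"`
#'   (constant-weight codebook rows).
#' @param n_compounds Compounds per mixture for the direct mapping.
#' @param codebook For sparse mapping: a `codebook`, or a list of arguments
#'   for [build_codebook()] (default the full-scale geometry is *not*
#'   assumed; supply what the experiment needs).
#' @param subset Library product indices used as columns (default: the first
#'   `n` products). Treated as a validated subset: data plates are simulated
#'   without reaction failures unless `validated = FALSE`.
#' @param validated Whether the subset comes from validated library wells.
#' @param library A `ugi_library` (default: the packaged 1500-product
#'   library).
#' @param sim A [sim_params()] for simulation-backed runs.
#' @param detector `"threshold"` (single sodiated peak), `"logistic"` or
#'   `"forest"` (multi-peak).
#' @param train_fraction Labeled fraction of spots used to fit thresholds or
#'   classifiers.
#' @param tol Peak lookup half-window, ppm.
#' @param raw_tau Raw-intensity threshold used when reading without SNR
#'   normalization (noiseless runs).
#' @param seed Master seed for the run.
#' @return A `run_config` list.
#' @export
run_config <- function(payload, mapping = c("direct", "sparse"),
                       n_compounds = 32L, codebook = NULL, subset = NULL,
                       validated = TRUE, library = NULL,
                       sim = sim_params(), detector = c("threshold",
                                                        "logistic", "forest"),
                       train_fraction = 0.3, tol = 15, raw_tau = 1,
                       seed = 1L) {
  mapping <- match.arg(mapping)
  detector <- match.arg(detector)
  if (mapping == "sparse" && is.null(codebook)) {
    stop("sparse mapping needs a codebook (or build_codebook() arguments)")
  }
  structure(list(payload = payload, mapping = mapping,
                 n_compounds = as.integer(n_compounds), codebook = codebook,
                 subset = subset, validated = validated, library = library,
                 sim = sim, detector = detector,
                 train_fraction = train_fraction, tol = tol,
                 raw_tau = raw_tau, seed = as.integer(seed)),
            class = "run_config")
}

#' Choose a mass-resolvable library subset
#'
#' Greedily selects `n` products in library order, skipping any product whose
#' monoisotopic mass falls within `tol` ppm of an already selected one, so
#' that every column of a data plate has a unique single-peak identity (the
#' packaged library contains exact isomers, which a sodiated-peak readout
#' cannot distinguish).
#'
#' @param library A `ugi_library`.
#' @param n Subset size.
#' @param tol Mass-resolution tolerance, ppm.
#' @return Integer vector of `n` product indices.
#' @export
select_subset <- function(library, n, tol = 5) {
  picked <- integer(0)
  Mp <- numeric(0)
  for (i in seq_len(nrow(library))) {
    M <- library$M[i]
    if (!length(picked) || all(2 * abs(M - Mp) / (M + Mp) * 1e6 > tol)) {
      picked <- c(picked, i)
      Mp <- c(Mp, M)
      if (length(picked) == n) return(picked)
    }
  }
  stop("library has fewer than ", n, " mass-resolvable products at ",
       tol, " ppm")
}

resolve_config <- function(config) {
  if (is.null(config$library)) {
    config$library <- enumerate_library(read_reagents())
  }
  if (!is.null(config$codebook) && !inherits(config$codebook, "codebook")) {
    config$codebook <- do.call(build_codebook, config$codebook)
  }
  n_cols <- if (config$mapping == "direct") config$n_compounds
            else config$codebook$n
  if (is.null(config$subset)) {
    config$subset <- select_subset(config$library, n_cols)
  }
  if (length(config$subset) != n_cols) {
    stop("subset length must equal the number of compound columns")
  }
  config
}

payload_bits <- function(payload) {
  if (is.character(payload) || is.matrix(payload)) bits_from_image(payload)
  else {
    stopifnot(all(payload %in% c(0L, 1L)))
    payload
  }
}

#' Write pipeline: payload to plate artifacts
#'
#' Encodes the payload into a presence matrix, lays the mixtures out on the
#' plate and builds the acoustic transfer list.
#'
#' @param config A [run_config()].
#' @return List: `config` (resolved), `bits`, `matrix` (`presence_matrix`
#'   with the subset attached), `layout`, `transfers`, `codebook` (sparse
#'   mapping only).
#' @export
run_write <- function(config) {
  config <- resolve_config(config)
  bits <- payload_bits(config$payload)
  pm <- if (config$mapping == "direct") {
    direct_encode(bits, config$n_compounds)
  } else sparse_encode(bits, config$codebook)
  attr(pm, "subset") <- config$subset
  layout <- layout_plate(nrow(pm))
  transfers <- write_transfer_list(pm, layout)
  list(config = config, bits = bits, matrix = pm, layout = layout,
       transfers = transfers, codebook = config$codebook)
}

#' Read pipeline: spectra to recovered payload
#'
#' Calibrates every spectrum against the spiked reference, resamples onto the
#' common m/z grid, SNR-transforms (unless reading raw intensities), calls
#' compound presence with the configured detector — thresholds or classifiers
#' fitted on the labeled training fraction of spots when `truth` is supplied
#' — and decodes the presence matrix back to bits (nearest-codeword
#' correction for the sparse mapping).
#'
#' @param config A [run_config()] (resolved or not).
#' @param spectra A `sim_plate`, list of `mass_spectrum`, or
#'   `spectral_matrix`.
#' @param truth Optional ground-truth `presence_matrix`; required for
#'   detector training, used for reporting when available.
#' @param n_bits Payload length (taken from `truth` metadata when absent).
#' @return List: `bits`, `matrix` (read presence matrix), `report`
#'   (`read_report` vs truth, when available), `detector` (fitted thresholds
#'   or classifiers), `offsets_ppm`, `decode` (sparse decode detail or NULL).
#' @export
run_read <- function(config, spectra, truth = NULL, n_bits = NULL) {
  config <- resolve_config(config)
  use_snr <- config$sim$preset != "noiseless"
  if (inherits(spectra, "sim_plate")) spectra <- spectra$spectra
  if (inherits(spectra, "spectral_matrix")) {
    smat <- spectra
    offs <- smat$offsets_ppm
  } else {
    ref_mz <- adduct_mz(config$sim$ref_mass, "Na")
    cal <- lapply(spectra, calibrate_offset, ref_mz = ref_mz)
    offs <- vapply(cal, `[[`, numeric(1), "offset_ppm")
    grid <- seq(config$sim$mz_range[1], config$sim$mz_range[2],
                by = config$sim$grid_step)
    smat <- resample_to_grid(lapply(cal, `[[`, "spectrum"), grid,
                             offsets_ppm = offs)
  }
  if (use_snr) smat <- snr_transform(smat)

  n_spots <- nrow(smat$mat)
  detector <- NULL
  if (config$detector == "threshold") {
    if (!is.null(truth)) {
      old <- get_rng_state(); on.exit(set_rng_state(old))
      set.seed(config$seed)
      train_idx <- sort(sample.int(n_spots,
                                   max(2L, round(config$train_fraction *
                                                 n_spots))))
      detector <- fit_thresholds(smat, truth[train_idx, , drop = FALSE],
                                 config$library, config$subset,
                                 train_idx = train_idx, tol = config$tol)
      pred <- single_peak_read(smat, config$library, config$subset, detector)
    } else {
      pred <- single_peak_read(smat, config$library, config$subset,
                               config$raw_tau, tol = config$tol)
    }
  } else {
    if (is.null(truth)) stop("classifier detectors need labeled truth")
    detector <- train_classifiers(smat, truth, config$library, config$subset,
                                  method = config$detector,
                                  split = config$train_fraction,
                                  seed = config$seed)
    pred <- multi_peak_read(detector, smat)
  }

  if (is.null(n_bits)) n_bits <- attr(truth, "n_bits")
  decode <- NULL
  bits <- if (config$mapping == "direct") {
    direct_decode(pred, n_bits = n_bits)
  } else {
    decode <- sparse_decode(unclass_matrix(pred), config$codebook,
                            n_bits = n_bits)
    decode$bits
  }
  if (!is.null(truth)) attr(bits, "dim_image") <- attr(truth, "dim_image")
  report <- if (!is.null(truth)) evaluate_read(pred, truth) else NULL
  list(bits = bits, matrix = pred, report = report, detector = detector,
       offsets_ppm = offs, decode = decode)
}

#' Full write -> simulate -> read round trip
#'
#' Runs the complete pipeline on synthetic spectra and reports payload
#' recovery. The data plate is simulated without reaction failures when the
#' subset is validated (see [run_config()]).
#'
#' @param config A [run_config()].
#' @return List: `write`, `plate` (`sim_plate`), `read`, `bit_accuracy`
#'   (payload bits), `report` (cell-level `read_report`).
#' @export
roundtrip <- function(config) {
  config <- resolve_config(config)
  wr <- run_write(config)
  mask <- if (isTRUE(config$validated)) rep(FALSE, ncol(wr$matrix)) else NULL
  plate <- simulate_plate(wr$matrix, config$library, config$sim,
                          seed = config$seed, failure_mask = mask)
  rd <- run_read(config, plate, truth = wr$matrix,
                 n_bits = length(wr$bits))
  list(write = wr, plate = plate, read = rd,
       bit_accuracy = mean(rd$bits == wr$bits), report = rd$report)
}
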