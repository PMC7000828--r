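#' Simulate MALDI FT-ICR spectra for a written plate
#'
#' Produces one labeled synthetic spectrum per presence-matrix row. Each
#' present, non-failed compound contributes Gaussian peaks at its `[M+H]+`,
#' `[M+Na]+` and `[M+K]+` m/z (FWHM = m/z / R), each with carbon-binomial isotope
#' satellites, all shifted by the spot's multiplicative ppm mass offset. The
#' compound's abundance is lognormal per (spot, compound), multiplied by a
#' fixed per-compound ionization efficiency and divided by
#' `n_present^competition_exponent` (competitive ionization). Some compounds
#' additionally show a sodiated complex with a residual starting reagent (the
#' aldehyde). A fixed set of matrix-background peaks is shared across spots,
#' a truncated-Gaussian baseline is added, and the sodiated reference
#' compound is spiked into every spot. Identical (matrix, params, seed) give
#' identical spectra.
#'
#' @param matrix A `presence_matrix` (rows = spots, columns = compounds).
#' @param library A `ugi_library`; columns map to `attr(matrix, "subset")`
#'   product indices (default: the first `ncol(matrix)` products).
#' @param params A [sim_params()] object.
#' @param seed Integer seed (RNG state restored on exit).
#' @param failure_mask Optional logical override (TRUE = failed) of the
#'   per-compound reaction-failure mask, e.g. from [inject_failures()].
#' @param efficiency Optional override of the fixed per-compound ionization
#'   efficiencies (numeric, one per compound column).
#' @param complex_mask Optional logical override of which compounds carry a
#'   reagent-complex side channel.
#' @return A `sim_plate` list: `spectra` (list of `mass_spectrum` on a shared
#'   grid), `grid`, `labels` (the input matrix), `offsets_ppm`,
#'   `failure_mask`, `complex_mask`, `params`, `seed`.
#' @export
simulate_plate <- function(matrix, library, params = sim_params(), seed = 1L,
                           failure_mask = NULL, efficiency = NULL,
                           complex_mask = NULL) {
  subset <- attr(matrix, "subset")
  if (is.null(subset)) subset <- seq_len(ncol(matrix))
  if (max(subset) > nrow(library)) stop("subset exceeds library size")
  old <- get_rng_state(); on.exit(set_rng_state(old)); set.seed(seed)

  n_spots <- nrow(matrix); n_cmp <- ncol(matrix)
  grid <- seq(params$mz_range[1], params$mz_range[2], by = params$grid_step)
  M <- library$M[subset]

  # plate-level draws (order fixed for reproducibility)
  if (is.null(failure_mask)) {
    failure_mask <- inject_failures(matrix, library, params$p_fail)
  }
  eff_draw <- rlnorm(n_cmp, 0, params$efficiency_sdlog)
  if (is.null(efficiency)) efficiency <- eff_draw
  cmx_draw <- runif(n_cmp) < params$p_complex
  if (is.null(complex_mask)) complex_mask <- cmx_draw
  # sodiated complex with a residual starting reagent (the aldehyde)
  reagents <- attr(library, "reagents")
  complex_mz <- rep(NA_real_, n_cmp)
  if (!is.null(reagents)) {
    ald_mass <- reagents$mass[match(library$aldehyde[subset], reagents$name)]
    complex_mz <- adduct_mz(M + ald_mass, "Na")
  } else complex_mask[] <- FALSE
  matrix_mz <- sort(runif(params$n_matrix_peaks, params$mz_range[1] + 5,
                          params$mz_range[2] - 5))
  matrix_int <- rlnorm(params$n_matrix_peaks, params$matrix_meanlog,
                       params$matrix_sdlog)
  offsets_ppm <- rnorm(n_spots, 0, params$offset_ppm_sd)

  # per-compound peak template: relative m/z centers and fractions
  env <- lapply(seq_len(n_cmp), function(m) {
    e <- isotope_envelope(library$formula[subset[m]], params$isotope_peaks)
    centers <- fracs <- numeric(0)
    for (a in names(params$adduct_fracs)) {
      centers <- c(centers, adduct_mz(M[m], a) + e$offset)
      fracs <- c(fracs, params$adduct_fracs[[a]] * e$abundance)
    }
    list(centers = centers, fracs = fracs)
  })
  ref_mz <- adduct_mz(params$ref_mass, "Na")
  if (ref_mz < params$mz_range[1] || ref_mz > params$mz_range[2]) {
    stop("reference mass outside the simulated m/z range")
  }

  dropped <- FALSE
  spectra <- vector("list", n_spots)
  for (s in seq_len(n_spots)) {
    shift <- 1 + offsets_ppm[s] * 1e-6
    intensity <- if (params$noise_sd > 0 || params$noise_mu > 0) {
      pmax(rnorm(length(grid), params$noise_mu, params$noise_sd), 0)
    } else numeric(length(grid))
    present <- which(matrix[s, ] == 1L)
    n_present <- length(present)
    scale <- if (n_present > 0) n_present^(-params$competition_exponent) else 1
    for (m in present) {
      A <- rlnorm(1, params$abundance_meanlog, params$abundance_sdlog) * scale
      if (failure_mask[m]) next
      pk <- env[[m]]
      ok <- add_peaks(intensity, grid, pk$centers * shift,
                      A * efficiency[m] * pk$fracs, params$resolving_power)
      intensity <- ok$intensity
      dropped <- dropped || ok$dropped
      if (complex_mask[m] && !is.na(complex_mz[m])) {
        ok <- add_peaks(intensity, grid, complex_mz[m] * shift,
                        A * params$complex_frac, params$resolving_power)
        intensity <- ok$intensity
        dropped <- dropped || ok$dropped
      }
    }
    if (params$n_matrix_peaks > 0) {
      intensity <- add_peaks(intensity, grid, matrix_mz * shift, matrix_int,
                             params$resolving_power)$intensity
    }
    intensity <- add_peaks(intensity, grid, ref_mz * shift,
                           params$ref_intensity,
                           params$resolving_power)$intensity
    spectra[[s]] <- mass_spectrum(grid, intensity, spot_id = s)
  }
  if (dropped) {
    warning("some peaks fell outside the simulated m/z range and were dropped")
  }
  structure(list(spectra = spectra, grid = grid, labels = matrix,
                 offsets_ppm = offsets_ppm, failure_mask = failure_mask,
                 complex_mask = complex_mask, efficiency = efficiency,
                 params = params, seed = seed),
            class = "sim_plate")
}

# add Gaussian peaks (apex height `height`, FWHM = center / R) to an
# intensity vector on a uniform grid; returns whether any peak was dropped
add_peaks <- function(intensity, grid, centers, heights, R) {
  heights <- rep_len(heights, length(centers))
  lo <- grid[1]; step <- grid[2] - grid[1]; n <- length(grid)
  dropped <- FALSE
  for (i in seq_along(centers)) {
    ctr <- centers[i]
    if (ctr < lo || ctr > grid[n]) { dropped <- TRUE; next }
    sigma <- (ctr / R) / (2 * sqrt(2 * log(2)))
    i0 <- max(1L, floor((ctr - 6 * sigma - lo) / step) + 1L)
    i1 <- min(n, ceiling((ctr + 6 * sigma - lo) / step) + 1L)
    idx <- i0:i1
    intensity[idx] <- intensity[idx] +
      heights[i] * exp(-((grid[idx] - ctr)^2) / (2 * sigma^2))
  }
  list(intensity = intensity, dropped = dropped)
}

#' Draw a per-compound reaction-failure mask
#'
#' Reaction failure is a library-level property: a well whose synthesis
#' failed emits no product peaks anywhere it is dispensed. The mask is one
#' Bernoulli draw per compound, fixed for the whole plate.
#'
#' @param matrix Presence matrix (only its column count is used).
#' @param library Library (unused beyond validation; kept for symmetry).
#' @param p_fail Failure probability in `[0, 1]`.
#' @param seed Optional seed (RNG state restored on exit).
#' @return Logical vector, TRUE = failed, length `ncol(matrix)`.
#' @export
inject_failures <- function(matrix, library = NULL, p_fail = 0.10,
                            seed = NULL) {
  stopifnot(p_fail >= 0, p_fail <= 1)
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old)); set.seed(seed)
  }
  runif(ncol(matrix)) < p_fail
}

#' Spike a reference calibrant peak into a spectrum
#'
#' Adds a Gaussian peak for the sodiated reference compound at the given
#' (possibly offset) m/z. With `intensity = 0` the spectrum is returned
#' unchanged (the peak list semantics are additive).
#'
#' @param spectrum A `mass_spectrum`.
#' @param ref_mass Neutral reference mass, Da; its sodiated m/z (shifted by
#'   `offset_ppm`) must lie in the spectrum range.
#' @param intensity Apex intensity.
#' @param resolving_power FWHM = m/z / R.
#' @param offset_ppm Multiplicative mass offset applied to the peak position.
#' @return The spectrum with the calibrant added.
#' @export
spike_reference <- function(spectrum, ref_mass, intensity = 400,
                            resolving_power = 1.3e5, offset_ppm = 0) {
  mzv <- spectrum$mz
  ctr <- adduct_mz(ref_mass, "Na") * (1 + offset_ppm * 1e-6)
  if (ctr < mzv[1] || ctr > mzv[length(mzv)]) {
    stop("reference m/z outside the spectrum range")
  }
  if (intensity == 0) return(spectrum)
  res <- add_peaks(spectrum$intensity, mzv, ctr, intensity, resolving_power)
  mass_spectrum(mzv, res$intensity, spot_id = spectrum$spot_id)
}
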