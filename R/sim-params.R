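#' Simulation parameters for synthetic plate spectra
#'
#' Bundles every knob of the MALDI FT-ICR plate simulator. Defaults emulate
#' the acquisition regime of the real instrument: m/z 300-1000 on a 0.001 Da
#' grid, resolving power 1.3e5 (so FWHM = m/z / R, about 0.005 Da at 600),
#' sodium-dominant adduct ratios, a ~10% reaction-failure rate, lognormal
#' per-(spot, compound) abundances divided by (mixture size)^q for
#' competitive ionization, a fixed set of matrix-background peaks shared
#' across spots, truncated-Gaussian baseline noise, a single multiplicative
#' ppm mass offset per spot, and a spiked reference compound in every spot.
#'
#' @param mz_range Length-2 numeric, m/z window (Da).
#' @param grid_step Uniform grid spacing (Da).
#' @param resolving_power m/Delta-m; peak FWHM = m/z / R.
#' @param adduct_fracs Named intensity fractions for the H, Na, K adducts
#'   (relative to the compound's abundance; Na-dominant by default).
#' @param abundance_meanlog,abundance_sdlog Lognormal per-(spot, compound)
#'   ion abundance (arbitrary intensity units).
#' @param efficiency_sdlog Lognormal spread of a fixed per-compound ionization
#'   efficiency multiplying its own adduct peaks (compound-to-compound
#'   ionization variability).
#' @param p_fail Per-compound reaction-failure probability; a failed compound
#'   emits no product peaks anywhere on the plate.
#' @param n_matrix_peaks,matrix_meanlog,matrix_sdlog Count and lognormal
#'   intensity of HCCA-like background peaks (positions uniform in range,
#'   fixed per plate).
#' @param noise_mu,noise_sd Baseline noise: intensity floor is
#'   `max(N(noise_mu, noise_sd), 0)` per grid point.
#' @param offset_ppm_sd Per-spot multiplicative mass offset (ppm, Gaussian).
#' @param competition_exponent Exponent q of the 1/n_present^q competitive
#'   ionization suppression.
#' @param p_complex Probability that a compound forms a detectable complex
#'   with a residual starting reagent; the complex appears as an extra
#'   sodiated peak at M + M_reagent whose intensity tracks the compound's
#'   abundance but not its own-ion efficiency.
#' @param complex_frac Intensity of the complex peak relative to abundance.
#' @param isotope_peaks Number of isotope-envelope peaks per adduct.
#' @param ref_mass Neutral monoisotopic mass (Da) of the spiked reference
#'   compound (a synthetic Ugi-like calibrant, read out at its sodiated m/z).
#' @param ref_intensity Intensity of the reference peak.
#' @param preset `"default"` or `"noiseless"`; the noiseless preset switches
#'   off baseline noise, matrix peaks, mass offsets, failures, complexes and
#'   all random spread so readout is exactly reproducible in the ideal limit.
#' @param ... Overrides applied after the preset.
#' @return A `sim_params` list.
#' @export
#' @examples
#' sim_params(preset = "noiseless", mz_range = c(400, 800))
sim_params <- function(mz_range = c(300, 1000), grid_step = 0.001,
                       resolving_power = 1.3e5,
                       adduct_fracs = c(H = 0.25, Na = 1, K = 0.4),
                       abundance_meanlog = log(80), abundance_sdlog = 0.4,
                       efficiency_sdlog = 0.6,
                       p_fail = 0.10,
                       n_matrix_peaks = 100, matrix_meanlog = log(50),
                       matrix_sdlog = 1,
                       noise_mu = 10, noise_sd = 2,
                       offset_ppm_sd = 2,
                       competition_exponent = 0.3,
                       p_complex = 0.5, complex_frac = 0.5,
                       isotope_peaks = 3L,
                       ref_mass = 420.2260, ref_intensity = 400,
                       preset = c("default", "noiseless"), ...) {
  preset <- match.arg(preset)
  p <- list(mz_range = mz_range, grid_step = grid_step,
            resolving_power = resolving_power, adduct_fracs = adduct_fracs,
            abundance_meanlog = abundance_meanlog,
            abundance_sdlog = abundance_sdlog,
            efficiency_sdlog = efficiency_sdlog, p_fail = p_fail,
            n_matrix_peaks = n_matrix_peaks, matrix_meanlog = matrix_meanlog,
            matrix_sdlog = matrix_sdlog, noise_mu = noise_mu,
            noise_sd = noise_sd, offset_ppm_sd = offset_ppm_sd,
            competition_exponent = competition_exponent,
            p_complex = p_complex, complex_frac = complex_frac,
            isotope_peaks = isotope_peaks, ref_mass = ref_mass,
            ref_intensity = ref_intensity, preset = preset)
  if (preset == "noiseless") {
    p <- modifyList(p, list(abundance_sdlog = 0, efficiency_sdlog = 0,
                            p_fail = 0, n_matrix_peaks = 0L, noise_mu = 0,
                            noise_sd = 0, offset_ppm_sd = 0, p_complex = 0))
  }
  p <- modifyList(p, list(...))
  stopifnot(length(p$mz_range) == 2L, p$mz_range[1] < p$mz_range[2],
            p$grid_step > 0, p$resolving_power > 0,
            p$p_fail >= 0, p$p_fail <= 1, p$p_complex >= 0, p$p_complex <= 1,
            p$noise_sd >= 0, p$offset_ppm_sd >= 0)
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> preset=", x$preset, ", m/z ", x$mz_range[1], "-",
      x$mz_range[2], " @ ", x$grid_step, " Da, R=", x$resolving_power,
      ", p_fail=", x$p_fail, ", noise=(", x$noise_mu, ",", x$noise_sd,
      "), offset_sd=", x$offset_ppm_sd, " ppm\n", sep = "")
  invisible(x)
}
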