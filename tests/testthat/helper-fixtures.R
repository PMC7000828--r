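# Shared fixtures, built in code. Heavier objects are memoised per session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

full_library <- function() memo("library", enumerate_library(read_reagents()))

# small Ugi library: 2 amines x 2 aldehydes x 3 acids x 2 isocyanides = 24
small_library <- function() {
  memo("small_library", {
    rg <- read_reagents()
    # aldehydes 3 and 4 (valeraldehyde, isovaleraldehyde) are exact isomers,
    # so the small library contains genuine mass collisions
    keep <- c(which(rg$role == "amine")[1:2], which(rg$role == "aldehyde")[3:4],
              which(rg$role == "acid")[c(1, 2, 9)],
              which(rg$role == "isocyanide")[1:2])
    enumerate_library(rg[keep, ])
  })
}

# fast simulation settings: narrow window, coarser grid
fast_sim <- function(...) {
  sim_params(mz_range = c(420, 850), grid_step = 0.005, ...)
}

# a small noisy simulated data plate with known truth (memoised)
toy_plate <- function() {
  memo("toy_plate", {
    lib <- full_library()
    set.seed(11)
    bits <- sample(0:1, 16 * 128, replace = TRUE)
    pm <- direct_encode(bits, 16L)
    attr(pm, "subset") <- select_subset(lib, 16L)
    plate <- simulate_plate(pm, lib, fast_sim(), seed = 11,
                            failure_mask = rep(FALSE, 16L))
    list(lib = lib, pm = pm, plate = plate, bits = bits)
  })
}

# calibrated, SNR-transformed spectral matrix of the toy plate
toy_smat <- function() {
  memo("toy_smat", {
    tp <- toy_plate()
    ref_mz <- adduct_mz(tp$plate$params$ref_mass, "Na")
    cal <- lapply(tp$plate$spectra, calibrate_offset, ref_mz = ref_mz)
    smat <- resample_to_grid(
      lapply(cal, `[[`, "spectrum"), tp$plate$grid,
      offsets_ppm = vapply(cal, `[[`, numeric(1), "offset_ppm"))
    snr_transform(smat)
  })
}

toy_codebook <- function() memo("toy_codebook",
                                build_codebook(16, 4, 8, 4, seed = 3))

# naive O(K^2) Hamming-distance oracle on dense words
naive_min_distance <- function(cb) {
  dense <- matrix(0L, cb$K, cb$n)
  for (i in seq_len(cb$K)) dense[i, cb$words[i, ]] <- 1L
  best <- cb$n + 1L
  for (i in seq_len(cb$K - 1L)) {
    for (j in (i + 1L):cb$K) {
      d <- sum(dense[i, ] != dense[j, ])
      if (d < best) best <- d
    }
  }
  best
}
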