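test_that("noiseless plates place every present compound's sodiated peak", {
  lib <- small_library()
  pm <- presence_matrix(rbind(c(1L, 0L, 1L), c(0L, 0L, 0L)), "direct")
  attr(pm, "subset") <- c(1L, 2L, 3L)
  p <- sim_params(preset = "noiseless", mz_range = c(420, 850),
                  grid_step = 0.005)
  plate <- simulate_plate(pm, lib, p, seed = 1)
  s1 <- plate$spectra[[1]]
  for (m in c(1L, 3L)) {
    mz_na <- adduct_mz(lib$M[m], "Na")
    fwhm <- mz_na / p$resolving_power
    idx <- abs(s1$mz - mz_na) <= fwhm
    expect_gt(max(s1$intensity[idx]), 0)
  }
  mz_absent <- adduct_mz(lib$M[2], "Na")
  expect_lt(max(s1$intensity[abs(s1$mz - mz_absent) <= 0.01]), 1e-6)
  # empty mixture: only the spiked reference remains
  s2 <- plate$spectra[[2]]
  ref_mz <- adduct_mz(p$ref_mass, "Na")
  expect_gt(max(s2$intensity[abs(s2$mz - ref_mz) <= 0.01]), 0)
  expect_identical(sum(s2$intensity[abs(s2$mz - ref_mz) > 1]), 0)
})

test_that("identical (matrix, params, seed) give identical spectra", {
  tp <- toy_plate()
  again <- simulate_plate(tp$pm, tp$lib, tp$plate$params, seed = 11,
                          failure_mask = rep(FALSE, 16L))
  expect_identical(again$spectra[[3]]$intensity,
                   tp$plate$spectra[[3]]$intensity)
  expect_identical(again$offsets_ppm, tp$plate$offsets_ppm)
})

test_that("simulated peak widths follow the m/R law", {
  lib <- small_library()
  pm <- presence_matrix(matrix(1L, 1, 1), "direct")
  attr(pm, "subset") <- 1L
  p <- sim_params(preset = "noiseless", mz_range = c(420, 850),
                  grid_step = 0.001)
  plate <- simulate_plate(pm, lib, p, seed = 2)
  s <- plate$spectra[[1]]
  mz_na <- adduct_mz(lib$M[1], "Na")
  win <- which(abs(s$mz - mz_na) < 0.05)
  apex <- win[which.max(s$intensity[win])]
  half <- s$intensity[apex] / 2
  above <- win[s$intensity[win] >= half]
  measured_fwhm <- s$mz[max(above)] - s$mz[min(above)]
  expect_equal(measured_fwhm, mz_na / p$resolving_power,
               tolerance = 2 * p$grid_step / (mz_na / p$resolving_power))
})

test_that("mean per-compound intensity is non-increasing in mixture size", {
  lib <- full_library()
  subset <- select_subset(lib, 16L)  # no mass-degenerate interference
  sizes <- c(1L, 4L, 16L)
  apexes <- vapply(sizes, function(k) {
    pm <- presence_matrix(matrix(c(rep(1L, k), rep(0L, 16 - k)), 1), "direct")
    attr(pm, "subset") <- subset
    p <- sim_params(preset = "noiseless", mz_range = c(420, 850),
                    grid_step = 0.005)
    plate <- simulate_plate(pm, lib, p, seed = 3)
    s <- plate$spectra[[1]]
    mz_na <- adduct_mz(lib$M[subset[1]], "Na")
    max(s$intensity[abs(s$mz - mz_na) < 0.02])
  }, numeric(1))
  expect_true(all(diff(apexes) < 0))
})

test_that("reaction failures are per-compound, plate-wide, binomially sized", {
  pm <- presence_matrix(matrix(1L, 3, 1500), "direct")
  mask <- inject_failures(pm, p_fail = 0.1, seed = 4)
  expect_identical(length(mask), 1500L)
  expect_lt(abs(sum(mask) - 150), 4 * sqrt(1500 * 0.1 * 0.9))
  expect_identical(inject_failures(pm, p_fail = 0, seed = 1),
                   rep(FALSE, 1500L))
  expect_identical(inject_failures(pm, p_fail = 1, seed = 1),
                   rep(TRUE, 1500L))
  # failed compounds emit no product peaks anywhere
  lib <- small_library()
  pm2 <- presence_matrix(matrix(1L, 2, 2), "direct")
  attr(pm2, "subset") <- c(1L, 2L)
  p <- sim_params(preset = "noiseless", mz_range = c(420, 850),
                  grid_step = 0.005)
  plate <- simulate_plate(pm2, lib, p, seed = 5,
                          failure_mask = c(TRUE, FALSE))
  for (s in plate$spectra) {
    expect_lt(max(s$intensity[abs(s$mz - adduct_mz(lib$M[1], "Na")) < 0.02]),
              1e-9)
    expect_gt(max(s$intensity[abs(s$mz - adduct_mz(lib$M[2], "Na")) < 0.02]),
              0)
  }
})

test_that("spiked reference lands at the offset-shifted m/z", {
  grid <- seq(420, 450, by = 0.001)
  empty <- mass_spectrum(grid, numeric(length(grid)))
  s <- spike_reference(empty, 420.226, intensity = 100, offset_ppm = 5)
  apex <- grid[which.max(s$intensity)]
  expected <- adduct_mz(420.226, "Na") * (1 + 5e-6)
  expect_lt(abs(apex - expected), 0.001)
  expect_identical(spike_reference(empty, 420.226, intensity = 0)$intensity,
                   empty$intensity)
  expect_error(spike_reference(empty, 900), "range")
})
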