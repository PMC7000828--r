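test_that("sigma-clipped background recovers noise moments despite peaks", {
  set.seed(5)
  noise <- rnorm(5000, 10, 2)
  bg <- estimate_background(noise)
  expect_equal(bg$mu, 10, tolerance = 0.05 * 10)
  expect_equal(bg$sigma, 2, tolerance = 0.05 * 2)
  # one huge peak barely moves the estimate
  spiked <- noise
  spiked[100:110] <- 5000
  bg2 <- estimate_background(spiked)
  expect_equal(bg2$mu, bg$mu, tolerance = 0.05 * bg$mu)
  expect_equal(bg2$sigma, bg$sigma, tolerance = 0.05 * bg$sigma)
  expect_error(estimate_background(rep(7, 500)), "degenerate")
  expect_error(estimate_background(rnorm(50)), "100")
})

test_that("SNR transform is the shift-and-scale relation and affine-invariant", {
  bg <- structure(list(mu = 10, sigma = 2, method = "fixed"),
                  class = "background_estimate")
  expect_identical(snr_transform(72, bg), 31)
  expect_identical(snr_transform(10, bg), 0)
  set.seed(6)
  x <- pmax(rnorm(2000, 10, 2), 0)
  x[700:704] <- x[700:704] + 60
  snr1 <- snr_transform(x)
  snr2 <- snr_transform(3.7 * x + 11)  # affine rescaling, re-estimated
  expect_equal(snr1, snr2, tolerance = 1e-9)
  expect_error(snr_transform(5, structure(list(mu = 0, sigma = 0),
                                          class = "background_estimate")),
               "sigma")
})

test_that("calibration removes an injected ppm offset and is idempotent", {
  grid <- seq(440, 460, by = 0.001)
  ref_mz <- adduct_mz(420.226, "Na")
  set.seed(7)
  base <- mass_spectrum(grid, pmax(rnorm(length(grid), 10, 2), 0))
  s <- spike_reference(base, 420.226, intensity = 300, offset_ppm = 5)
  cal <- calibrate_offset(s, ref_mz)
  expect_equal(cal$offset_ppm, 5, tolerance = 0.5)
  apex <- cal$spectrum$mz[which.max(cal$spectrum$intensity)]
  expect_lt(abs(apex - ref_mz), 0.0015)
  # idempotence: recalibrating changes the axis by < 1 grid step
  cal2 <- calibrate_offset(cal$spectrum, ref_mz)
  expect_lt(max(abs(cal2$spectrum$mz - cal$spectrum$mz)), 0.001)
  # calibrant absent -> flagged error, not a silent pass
  expect_error(calibrate_offset(base, ref_mz), "calibration failed")
})

test_that("resampling preserves apexes and aligns heterogeneous grids", {
  fine <- seq(499, 501, by = 0.0005)
  coarse <- seq(499, 501, by = 0.001)
  sigma <- 0.002
  g <- mass_spectrum(fine, 100 * exp(-(fine - 500)^2 / (2 * sigma^2)))
  smat <- resample_to_grid(list(g), coarse)
  expect_equal(max(smat$mat[1, ]), 100, tolerance = 0.01 * 100)
  # resampling conserves windowed signal of an isolated peak
  win_src <- abs(fine - 500) < 0.05
  win_dst <- abs(coarse - 500) < 0.05
  expect_equal(sum(smat$mat[1, win_dst]) * 0.001,
               sum(g$intensity[win_src]) * 0.0005, tolerance = 0.01)
  # a spectrum already on the grid passes through unchanged
  s2 <- mass_spectrum(coarse, seq_along(coarse) * 1.0)
  expect_identical(resample_to_grid(list(s2), coarse)$mat[1, ],
                   s2$intensity)
  # two different native grids end up on one shared grid
  both <- resample_to_grid(list(g, s2), coarse)
  expect_identical(dim(both$mat), c(2L, length(coarse)))
  expect_error(resample_to_grid(list(mass_spectrum(numeric(0),
                                                   numeric(0))), coarse),
               "empty")
})

test_that("peak_intensity returns the windowed per-spot maximum", {
  grid <- seq(500, 501, by = 0.001)
  m <- rbind(rep(0, length(grid)), rep(0, length(grid)))
  m[1, 501] <- 40                      # exactly at 500.5
  m[2, c(499, 503)] <- c(10, 25)       # two peaks in window -> larger
  smat <- spectral_matrix(grid, m)
  got <- peak_intensity(smat, 500.5, tol = 15)
  expect_identical(got, c(40, 25))
  expect_error(peak_intensity(smat, 900, tol = 15), "tolerance|grid")
})
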