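synthetic_smat <- function(n_spots, labels, informative = TRUE, seed = 1) {
  # grid-backed SNR matrix with one (or no) perfectly informative column
  set.seed(seed)
  grid <- seq(500, 501.27, by = 0.01)
  m <- matrix(rnorm(n_spots * length(grid)), n_spots)
  if (informative) m[, 40] <- labels * 20 + rnorm(n_spots, 0, 0.1)
  spectral_matrix(grid, m, snr = TRUE)
}

test_that("a perfectly informative feature yields held-out accuracy 1", {
  set.seed(20)
  labels <- matrix(rbinom(60, 1, 0.5), 60, 1)
  smat <- synthetic_smat(60, labels[, 1])
  lib <- small_library()
  for (method in c("logistic", "forest")) {
    cls <- train_classifiers(smat, labels, lib, subset = 1L, method = method,
                             seed = 2)
    expect_identical(unname(cls$heldout_accuracy), 1)
  }
})

test_that("label-shuffled training gives chance-level held-out accuracy", {
  set.seed(21)
  true_lab <- rbinom(120, 1, 0.5)
  shuffled <- matrix(sample(true_lab), 120, 1)
  smat <- synthetic_smat(120, true_lab)
  cls <- train_classifiers(smat, shuffled, small_library(), subset = 1L,
                           method = "logistic", seed = 3)
  expect_lt(abs(unname(cls$heldout_accuracy) - 0.5), 0.2)
})

test_that("constant training labels fall back to a flagged threshold model", {
  set.seed(22)
  labels <- cbind(rbinom(40, 1, 0.5), 1L)   # second compound always present
  lib <- small_library()
  pm <- presence_matrix(labels, "direct")
  attr(pm, "subset") <- c(1L, 2L)
  plate <- simulate_plate(pm, lib, fast_sim(), seed = 22,
                          failure_mask = c(FALSE, FALSE))
  smat <- snr_transform(resample_to_grid(plate$spectra, plate$grid))
  # tiny training class sizes trigger glmnet's small-sample warning
  cls <- suppressWarnings(
    train_classifiers(smat, pm, lib, c(1L, 2L), method = "logistic",
                      seed = 4))
  expect_identical(cls$models[[2]]$method, "threshold")
  expect_true(cls$models[[2]]$flagged)
  pred <- multi_peak_read(cls, smat)
  # the always-present compound is still read as mostly present
  expect_gt(mean(pred[, 2]), 0.9)
})

test_that("multi-peak readout is deterministic and grid-checked", {
  tp <- toy_plate(); smat <- toy_smat()
  cls <- train_classifiers(smat, tp$pm, tp$lib, attr(tp$pm, "subset"),
                           method = "logistic", seed = 5)
  p1 <- multi_peak_read(cls, smat)
  p2 <- multi_peak_read(cls, smat)
  expect_identical(unclass(p1), unclass(p2))
  other <- spectral_matrix(smat$grid + 1, smat$mat, snr = TRUE)
  expect_error(multi_peak_read(cls, other), "grid")
})

test_that("a suppressed compound with a reagent complex is rescued by
           multi-peak readout", {
  lib <- full_library()
  subset <- select_subset(lib, 8L)
  set.seed(23)
  pm <- presence_matrix(matrix(rbinom(120 * 8, 1, 0.5), 120, 8), "direct")
  attr(pm, "subset") <- subset
  eff <- rep(1, 8); eff[3] <- 0.02          # own adducts suppressed
  cmx <- rep(FALSE, 8); cmx[3] <- TRUE      # but a complex channel exists
  plate <- simulate_plate(pm, lib, fast_sim(), seed = 23,
                          failure_mask = rep(FALSE, 8),
                          efficiency = eff, complex_mask = cmx)
  smat <- snr_transform(resample_to_grid(plate$spectra, plate$grid))
  set.seed(23)
  train_idx <- sort(sample.int(120, 36))
  thr <- fit_thresholds(smat, pm[train_idx, , drop = FALSE], lib, subset,
                        train_idx = train_idx)
  single <- single_peak_read(smat, lib, subset, thr)
  cls <- train_classifiers(smat, pm, lib, subset, method = "logistic",
                           seed = 23)
  multi <- multi_peak_read(cls, smat)
  test_idx <- cls$test_idx
  acc_single <- mean(single[test_idx, 3] == pm[test_idx, 3])
  acc_multi <- mean(multi[test_idx, 3] == pm[test_idx, 3])
  expect_lt(acc_single, 0.8)   # own peak is unusable
  expect_gt(acc_multi, 0.9)    # complex channel carries the bit
  expect_gt(acc_multi, acc_single)
})

test_that("multi-peak aggregate error does not exceed single-peak on a
           noisy plate", {
  tp <- toy_plate(); smat <- toy_smat()
  subset <- attr(tp$pm, "subset")
  cls <- train_classifiers(smat, tp$pm, tp$lib, subset, method = "logistic",
                           seed = 6)
  multi <- multi_peak_read(cls, smat)
  thr <- fit_thresholds(smat, tp$pm[cls$train_idx, , drop = FALSE], tp$lib,
                        subset, train_idx = cls$train_idx)
  single <- single_peak_read(smat, tp$lib, subset, thr)
  test_idx <- cls$test_idx
  err_multi <- mean(multi[test_idx, ] != tp$pm[test_idx, ])
  err_single <- mean(single[test_idx, ] != tp$pm[test_idx, ])
  expect_lte(err_multi, err_single)
})
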