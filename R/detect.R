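#' Fit per-compound SNR detection thresholds
#'
#' For each compound in the subset, pools the sodiated-peak scores of the
#' labeled (training) spots and picks the ROC-optimal corner-distance
#' threshold. Compounds whose training labels are constant fall back to the
#' global threshold over all compounds and are flagged.
#'
#' @param smat SNR-transformed `spectral_matrix` (see [snr_transform()]).
#' @param truth Binary training labels, spots x compounds (rows must match
#'   `train_idx` subset of `smat`).
#' @param library A `ugi_library`.
#' @param subset Library product indices backing the compound columns.
#' @param train_idx Spot rows used for fitting (default: all rows of truth).
#' @param adduct Target adduct for the single readout peak.
#' @param tol Peak lookup half-window, ppm.
#' @return A `detection_thresholds`: list with `tau` (per-compound), `adduct`,
#'   `tol`, `use_snr`, `flagged`.
#' @export
fit_thresholds <- function(smat, truth, library, subset = seq_len(ncol(truth)),
                           train_idx = seq_len(nrow(smat$mat)),
                           adduct = "Na", tol = 15) {
  stopifnot(length(subset) == ncol(truth))
  scores <- compound_scores(smat, library, subset, adduct = adduct, tol = tol)
  sc_tr <- scores[train_idx, , drop = FALSE]
  if (nrow(sc_tr) != nrow(truth)) stop("truth rows must match train_idx")
  all_s <- as.vector(sc_tr); all_l <- as.vector(truth)
  global_tau <- optimal_threshold(roc_curve(all_s, all_l))$tau
  tau <- numeric(ncol(truth)); flagged <- logical(ncol(truth))
  for (m in seq_len(ncol(truth))) {
    lab <- truth[, m]
    if (length(unique(lab)) < 2L) {
      tau[m] <- global_tau; flagged[m] <- TRUE
    } else {
      tau[m] <- optimal_threshold(roc_curve(sc_tr[, m], lab))$tau
    }
  }
  structure(list(tau = tau, adduct = adduct, tol = tol, use_snr = smat$snr,
                 targets = adduct_mz(library$M[subset], adduct),
                 flagged = flagged),
            class = "detection_thresholds")
}

#' @export
print.detection_thresholds <- function(x, ...) {
  cat("<detection_thresholds> ", length(x$tau), " compounds, adduct ",
      x$adduct, ", tau in [", round(min(x$tau), 2), ", ",
      round(max(x$tau), 2), "]", if (any(x$flagged))
        paste0(", ", sum(x$flagged), " fallback"), "\n", sep = "")
  invisible(x)
}

# per-spot sodiated (or other adduct) apex scores for each compound column
compound_scores <- function(smat, library, subset, adduct = "Na", tol = 15) {
  targets <- adduct_mz(library$M[subset], adduct)
  out_of_grid <- targets < smat$grid[1] | targets > smat$grid[length(smat$grid)]
  if (any(out_of_grid)) {
    stop("compound m/z outside grid for subset index ",
         paste(which(out_of_grid), collapse = ", "))
  }
  vapply(targets, function(t) peak_intensity(smat, t, tol),
         numeric(nrow(smat$mat)))
}

#' Single-peak presence readout
#'
#' Declares compound `m` present in a spot when its target-adduct apex score
#' (SNR by default; raw intensity behind the `use_snr` flag) exceeds the
#' compound's threshold, and absent otherwise.
#'
#' @param smat A `spectral_matrix` (SNR-transformed when thresholds are SNR).
#' @param library A `ugi_library`.
#' @param subset Library product indices for the compound columns.
#' @param thresholds A [fit_thresholds()] object, or a single numeric
#'   threshold applied to every compound.
#' @param tol Peak half-window, ppm (from `thresholds` when given there).
#' @return A `presence_matrix` (mapping `"read"`).
#' @export
single_peak_read <- function(smat, library, subset, thresholds, tol = 15) {
  if (inherits(thresholds, "detection_thresholds")) {
    if (isTRUE(thresholds$use_snr) && !smat$snr) {
      stop("thresholds are SNR-based but matrix is raw intensity")
    }
    tau <- thresholds$tau; tol <- thresholds$tol; adduct <- thresholds$adduct
  } else {
    tau <- rep(as.numeric(thresholds), length(subset)); adduct <- "Na"
  }
  if (length(tau) != length(subset)) stop("thresholds do not cover subset")
  scores <- compound_scores(smat, library, subset, adduct = adduct, tol = tol)
  pred <- sweep(scores, 2L, tau, `>`) * 1L
  presence_matrix(pred, "read", subset = subset)
}

#' Validate a one-product-per-well library plate
#'
#' Global statistical analysis of a library plate where well `i` is expected
#' to contain exactly product `expected[i]`: computes the per-(well, product)
#' sodiated-peak SNR map, labels a pair positive when the product's mass is
#' within `mass_tol` ppm of the well's expected product mass (mass-degenerate
#' partners of the expected product count as expected, so their detection is
#' a TP and never an FP), builds the global ROC over all pairs and picks the
#' common corner-distance threshold tau.
#'
#' @param smat SNR-transformed `spectral_matrix`, one row per library well.
#' @param library A `ugi_library`.
#' @param expected Integer vector: the library product index expected in each
#'   well.
#' @param subset Product indices scored in each well (default: the expected
#'   products themselves, i.e. the plate's own library).
#' @param tol Peak lookup half-window, ppm.
#' @param mass_tol Mass-degeneracy tolerance, ppm.
#' @return A `library_validation`: `tau`, `TPR`, `FPR`, `detected_fraction`
#'   (wells whose expected product, or a degenerate partner, exceeds tau),
#'   `snr_map`, `roc`, `labels`.
#' @export
validate_library <- function(smat, library, expected,
                             subset = sort(unique(expected)),
                             tol = 15, mass_tol = 5) {
  if (anyNA(expected)) stop("every well needs an expected product")
  if (nrow(smat$mat) != length(expected)) {
    stop("one expected product per well required")
  }
  snr_map <- compound_scores(smat, library, subset, tol = tol)
  Mexp <- library$M[expected]
  Msub <- library$M[subset]
  # labels[w, j]: product subset[j] is (mass-)expected in well w
  labels <- abs(outer(Mexp, Msub, `-`)) /
    outer(Mexp, Msub, function(a, b) (a + b) / 2) * 1e6 <= mass_tol
  roc <- roc_curve(as.vector(snr_map), as.vector(labels))
  opt <- optimal_threshold(roc)
  detected <- vapply(seq_along(expected), function(w) {
    any(snr_map[w, labels[w, ]] > opt$tau)
  }, logical(1))
  structure(list(tau = opt$tau, TPR = opt$TPR, FPR = opt$FPR,
                 corner_distance = opt$corner_distance,
                 detected_fraction = mean(detected), detected = detected,
                 snr_map = snr_map, roc = roc, labels = labels),
            class = "library_validation")
}

#' @export
print.library_validation <- function(x, ...) {
  cat("<library_validation> tau=", round(x$tau, 2), ", TPR=",
      round(100 * x$TPR, 2), "%, FPR=", round(100 * x$FPR, 2),
      "%, detected ", round(100 * x$detected_fraction, 2), "% of wells\n",
      sep = "")
  invisible(x)
}

#' Drop features near the noise floor
#'
#' Keeps grid columns whose mean SNR is at least `floor` (default 3); if more
#' than `max_features` remain, keeps the top `max_features` by mean SNR.
#' May return an empty set for an all-noise matrix.
#'
#' @param smat SNR-transformed `spectral_matrix`.
#' @param max_features Cap on the number of retained columns.
#' @param floor Mean-SNR noise floor.
#' @return Integer vector of grid column indices (ascending).
#' @export
prune_features <- function(smat, max_features = 20000L, floor = 3) {
  stopifnot(max_features >= 1L)
  mu <- colMeans(smat$mat)
  idx <- which(mu >= floor)
  if (length(idx) > max_features) {
    idx <- idx[order(mu[idx], decreasing = TRUE)[seq_len(max_features)]]
    idx <- sort(idx)
  }
  idx
}

#' Rank features by AUROC informativeness
#'
#' Scores each feature column by `|AUROC - 0.5|` so that both positively and
#' negatively informative peaks (e.g. competitive-ionization suppression of
#' other compounds) rank high, and returns the top `k`.
#'
#' @param X Numeric matrix, spots x features.
#' @param labels Binary labels, both classes present.
#' @param k Number of features to keep.
#' @return Integer vector of column indices, best first.
#' @export
rank_features_auroc <- function(X, labels, k = 64L) {
  labels <- as.integer(labels)
  n_pos <- sum(labels); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  auc <- apply(X, 2L, function(col) {
    r <- rank(col)
    (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  })
  ord <- order(abs(auc - 0.5), decreasing = TRUE)
  ord[seq_len(min(k, length(ord)))]
}
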