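#' Train per-compound multi-peak classifiers
#'
#' Fits one supervised model per compound column on SNR-transformed spectra,
#' using a seeded random train/test split of the spots (default 30% train /
#' 70% test, the rest held out for metrics).
#'
#' Features per compound are spectral peaks, in two tiers:
#' \itemize{
#'   \item engineered apex features at the compound's own known peak
#'     positions — the H/Na/K adducts and their first isotope satellites
#'     (apex value within the ppm window, as in [peak_intensity()]);
#'   \item data-driven grid columns: candidates survive noise-floor pruning
#'     ([prune_features()]), then an AUROC informativeness screen that keeps
#'     only columns whose `|AUROC - 0.5|` on the training labels exceeds
#'     `auroc_z` times the Mann-Whitney null standard deviation (chance-level
#'     columns otherwise swamp the model at small training sizes), ranked by
#'     `|AUROC - 0.5|` so negatively informative peaks (competitive-
#'     ionization suppression) are kept too.
#' }
#' The two tiers together are capped at `n_logistic_features` (default 64)
#' for the logistic model; the forest gets the engineered tier plus all
#' pruned columns (at most `max_features`) and performs its own selection.
#' Logistic fits are ridge-regularized (fixed small lambda keeps the
#' estimate defined and deterministic when the split is separable). The
#' decision cutoff on the trained score is chosen by the same ROC
#' corner-distance criterion used for single-peak thresholds. A compound
#' whose training labels are constant falls back to a threshold detector and
#' is flagged.
#'
#' @param smat SNR-transformed `spectral_matrix`.
#' @param truth Binary ground-truth labels (spots x compounds); only training
#'   rows are used for fitting.
#' @param library,subset Library and product indices backing the columns.
#' @param method `"logistic"` or `"forest"`.
#' @param split Training fraction of spots.
#' @param seed Split / forest seed.
#' @param max_features Cap on pruned candidate columns (full-scale default 20000).
#' @param n_logistic_features Total feature cap for the logistic model.
#' @param n_trees Trees per forest.
#' @param ridge_lambda Fixed ridge penalty for the logistic fit.
#' @param auroc_z Significance multiple for the AUROC screen.
#' @param tol Apex window half-width, ppm.
#' @return A `compound_classifiers` list: per-compound models plus
#'   `train_idx`, `test_idx`, per-compound held-out accuracy, and metadata.
#' @export
train_classifiers <- function(smat, truth, library,
                              subset = seq_len(ncol(truth)),
                              method = c("logistic", "forest"),
                              split = 0.3, seed = 1L,
                              max_features = 20000L,
                              n_logistic_features = 64L, n_trees = 300L,
                              ridge_lambda = 1e-2, auroc_z = 4, tol = 15) {
  method <- match.arg(method)
  stopifnot(nrow(truth) == nrow(smat$mat))
  old <- get_rng_state(); on.exit(set_rng_state(old)); set.seed(seed)
  n_spots <- nrow(smat$mat)
  train_idx <- sort(sample.int(n_spots, max(2L, round(split * n_spots))))
  test_idx <- setdiff(seq_len(n_spots), train_idx)
  pruned <- prune_features(smat, max_features = max_features)

  apex_targets <- lapply(seq_along(subset), function(m) {
    M <- library$M[subset[m]]
    t <- c(vapply(c("H", "Na", "K"),
                  function(a) adduct_mz(M, a) + (0:2) * .C13_SHIFT,
                  numeric(3)))
    t[t >= smat$grid[1] & t <= smat$grid[length(smat$grid)]]
  })

  # single-peak thresholds are needed only for constant-label fallbacks
  global_thr <- NULL
  get_thr <- function() {
    if (is.null(global_thr)) {
      global_thr <<- fit_thresholds(smat, truth[train_idx, , drop = FALSE],
                                    library, subset, train_idx = train_idx,
                                    tol = tol)
    }
    global_thr
  }
  models <- vector("list", ncol(truth))
  for (m in seq_len(ncol(truth))) {
    lab <- truth[train_idx, m]
    if (length(unique(lab)) < 2L) {
      models[[m]] <- list(compound = m, method = "threshold",
                          tau = get_thr()$tau[m], flagged = TRUE)
      next
    }
    screened <- ranked_all <- integer(0)
    if (length(pruned)) {
      n1 <- sum(lab); n0 <- sum(lab == 0L)
      null_sd <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
      auc <- apply(smat$mat[train_idx, pruned, drop = FALSE], 2L,
                   function(col) auroc(col, lab))
      ord <- order(abs(auc - 0.5), decreasing = TRUE)
      ranked_all <- pruned[ord]
      screened <- pruned[ord[abs(auc[ord] - 0.5) > auroc_z * null_sd]]
    }
    if (method == "logistic") {
      n_apex <- length(apex_targets[[m]])
      grid_idx <- head(screened, max(0L, n_logistic_features - n_apex))
      # glmnet needs at least two columns in the design
      if (n_apex + length(grid_idx) < 2L) {
        grid_idx <- head(ranked_all, 2L - n_apex)
      }
    } else {
      grid_idx <- pruned
    }
    X <- classifier_features(smat, apex_targets[[m]], grid_idx, tol)
    if (method == "logistic") {
      fit <- glmnet::glmnet(X[train_idx, , drop = FALSE], factor(lab, 0:1),
                            family = "binomial", alpha = 0,
                            lambda = ridge_lambda, standardize = TRUE)
      score <- predict(fit, X[train_idx, , drop = FALSE], type = "link")[, 1]
    } else {
      df <- data.frame(y = lab, X[train_idx, , drop = FALSE])
      fit <- ranger::ranger(y ~ ., data = df, num.trees = n_trees,
                            min.node.size = 1, seed = seed + m,
                            num.threads = 1)
      score <- fit$predictions  # out-of-bag, avoids optimistic cutoffs
    }
    cutoff <- if (length(unique(score)) > 1L) {
      optimal_threshold(roc_curve(score, lab))$tau
    } else 0.5
    models[[m]] <- list(compound = m, method = method,
                        apex_targets = apex_targets[[m]],
                        grid_idx = grid_idx, fit = fit, cutoff = cutoff,
                        flagged = FALSE)
  }
  obj <- structure(list(models = models, method = method, subset = subset,
                        train_idx = train_idx, test_idx = test_idx,
                        grid = smat$grid, thresholds = global_thr, tol = tol,
                        seed = seed),
                   class = "compound_classifiers")
  if (length(test_idx)) {
    pred <- multi_peak_read(obj, smat)
    obj$heldout_accuracy <- colMeans(
      pred[test_idx, , drop = FALSE] == truth[test_idx, , drop = FALSE])
  }
  obj
}

# feature matrix: apex values at known target m/z plus raw grid columns
classifier_features <- function(smat, apex_targets, grid_idx, tol) {
  parts <- list()
  if (length(apex_targets)) {
    parts$apex <- vapply(apex_targets,
                         function(t) peak_intensity(smat, t, tol),
                         numeric(nrow(smat$mat)))
  }
  if (length(grid_idx)) parts$grid <- smat$mat[, grid_idx, drop = FALSE]
  X <- do.call(cbind, parts)
  colnames(X) <- paste0("F", seq_len(ncol(X)))
  X
}

#' @export
print.compound_classifiers <- function(x, ...) {
  cat("<compound_classifiers> ", length(x$models), " compounds, method=",
      x$method, ", ", length(x$train_idx), " train / ", length(x$test_idx),
      " test spots", sep = "")
  if (!is.null(x$heldout_accuracy)) {
    cat(", held-out accuracy ", round(100 * mean(x$heldout_accuracy), 2), "%",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Multi-peak presence readout
#'
#' Applies trained per-compound classifiers to every spot of a spectral
#' matrix (same grid as training). Deterministic given the trained models.
#'
#' @param models A [train_classifiers()] object.
#' @param smat SNR-transformed `spectral_matrix` on the training grid.
#' @return A `presence_matrix` (mapping `"read"`).
#' @export
multi_peak_read <- function(models, smat) {
  if (length(smat$grid) != length(models$grid) ||
      !isTRUE(all(smat$grid == models$grid))) {
    stop("spectral matrix grid does not match the training grid")
  }
  n_spots <- nrow(smat$mat)
  pred <- matrix(0L, n_spots, length(models$models))
  for (m in seq_along(models$models)) {
    mod <- models$models[[m]]
    if (mod$method == "threshold") {
      sc <- peak_intensity(smat, models$thresholds$targets[m],
                           models$thresholds$tol)
      pred[, m] <- as.integer(sc > mod$tau)
      next
    }
    X <- classifier_features(smat, mod$apex_targets, mod$grid_idx,
                             models$tol)
    score <- if (mod$method == "logistic") {
      predict(mod$fit, X, type = "link")[, 1]
    } else {
      predict(mod$fit, data = as.data.frame(X),
              num.threads = 1)$predictions
    }
    pred[, m] <- as.integer(score > mod$cutoff)
  }
  presence_matrix(pred, "read", subset = models$subset)
}
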