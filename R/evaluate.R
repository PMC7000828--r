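#' Score a recovered presence matrix against the truth
#'
#' Exact counting of readout errors: per-compound false positive and false
#' negative rates, the per-mixture error-count histogram, and the overall
#' bit (cell) accuracy `1 - errors / cells`.
#'
#' @param predicted,truth Binary matrices of identical shape.
#' @return A `read_report`: `accuracy`, `per_compound` (data frame with
#'   `FPR`, `FNR`, `errors`), `per_mixture_errors` (integer vector),
#'   `error_histogram` (table), `n_errors`.
#' @export
evaluate_read <- function(predicted, truth) {
  if (!all(dim(predicted) == dim(truth))) stop("shape mismatch")
  pred <- unclass_matrix(predicted); tru <- unclass_matrix(truth)
  err <- pred != tru
  fp <- colSums(err & tru == 0L); n0 <- colSums(tru == 0L)
  fn <- colSums(err & tru == 1L); n1 <- colSums(tru == 1L)
  per_compound <- data.frame(
    compound = seq_len(ncol(tru)),
    FPR = ifelse(n0 > 0, fp / n0, NA_real_),
    FNR = ifelse(n1 > 0, fn / n1, NA_real_),
    errors = fp + fn)
  per_mix <- as.integer(rowSums(err))
  structure(list(accuracy = 1 - sum(err) / length(err),
                 per_compound = per_compound,
                 per_mixture_errors = per_mix,
                 error_histogram = table(per_mix),
                 n_errors = as.integer(sum(err))),
            class = "read_report")
}

#' @export
print.read_report <- function(x, ...) {
  cat("<read_report> accuracy ", sprintf("%.4f", x$accuracy), " (",
      x$n_errors, " cell errors); mixtures fully correct: ",
      sum(x$per_mixture_errors == 0), "/", length(x$per_mixture_errors),
      "\n", sep = "")
  invisible(x)
}
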