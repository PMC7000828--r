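#' Presence matrix constructor
#'
#' An `N x M` binary matrix whose entry marks whether compound `m` (column) is
#' dispensed into mixture `n` (row), plus the metadata needed to invert the
#' mapping.
#'
#' @param x Binary matrix (rows = mixtures/spots, columns = compounds).
#' @param mapping `"direct"` or `"sparse"`.
#' @param pad_bits Number of trailing zero pad bits appended to the payload.
#' @param n_bits Payload length in bits before padding.
#' @param dim_image Optional image dimensions of the payload.
#' @param subset Optional library product indices backing the columns.
#' @param codebook_meta Optional list describing the codebook (n, w, K, seed).
#' @return A `presence_matrix`.
#' @export
presence_matrix <- function(x, mapping, pad_bits = 0L, n_bits = NULL,
                            dim_image = NULL, subset = NULL,
                            codebook_meta = NULL) {
  x <- as.matrix(x)
  if (!all(x %in% c(0L, 1L))) stop("presence matrix must be binary")
  storage.mode(x) <- "integer"
  structure(x, class = c("presence_matrix", "matrix"),
            mapping = mapping, pad_bits = as.integer(pad_bits),
            n_bits = n_bits, dim_image = dim_image, subset = subset,
            codebook_meta = codebook_meta)
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("<presence_matrix> ", nrow(x), " mixtures x ", ncol(x), " compounds, ",
      "mapping=", attr(x, "mapping"), ", ones=", sum(x),
      ", pad=", attr(x, "pad_bits"), " bits\n", sep = "")
  invisible(x)
}

#' Direct bit-to-compound encoding
#'
#' Each bit is mapped to the presence (1) or absence (0) of a single compound
#' in a single mixture: the payload is reshaped row-major into an
#' `N x M` matrix with `N = ceiling(length(bits)/M)` rows; within a row, bit
#' `i` drives compound `i` (1-based). Trailing pad bits are zero and their
#' count is recorded for exact inversion.
#'
#' @param bits Integer 0/1 vector (non-empty).
#' @param M Compounds per mixture (>= 1).
#' @return A `presence_matrix` with mapping `"direct"`.
#' @export
#' @examples
#' pm <- direct_encode(bits_from_string("11001000000101001000000000000000"), 32)
#' which(pm[1, ] == 1)   # compounds 1, 2, 5, 12, 14, 17
direct_encode <- function(bits, M) {
  stopifnot(M >= 1L)
  if (length(bits) == 0L) stop("empty bit vector")
  if (!all(bits %in% c(0L, 1L))) stop("bits must be 0/1")
  n <- length(bits)
  N <- ceiling(n / M)
  pad <- N * M - n
  mat <- matrix(c(as.integer(bits), integer(pad)), nrow = N, ncol = M,
                byrow = TRUE)
  presence_matrix(mat, "direct", pad_bits = pad, n_bits = n,
                  dim_image = attr(bits, "dim_image"))
}

#' Invert the direct mapping
#'
#' Reshapes the matrix back into the stored bit vector, stripping the recorded
#' pad bits. `direct_decode(direct_encode(b, M))` is the identity.
#'
#' @param matrix A `presence_matrix` (or plain binary matrix plus `n_bits`).
#' @param n_bits Payload length; defaults to the recorded metadata.
#' @return Integer bit vector (with `dim_image` attribute when recorded).
#' @export
direct_decode <- function(matrix, n_bits = attr(matrix, "n_bits")) {
  if (is.null(n_bits)) {
    pad <- attr(matrix, "pad_bits")
    if (is.null(pad)) stop("pad metadata missing; pass n_bits")
    n_bits <- length(matrix) - pad
  }
  bits <- as.integer(t(matrix))[seq_len(n_bits)]
  attr(bits, "dim_image") <- attr(matrix, "dim_image")
  bits
}
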