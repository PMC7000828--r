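#' Sparse constant-weight encoding
#'
#' Maps each `data_bits`-bit block of the payload (first bit most significant)
#' onto the corresponding codeword of a constant-weight codebook, one block
#' per mixture row, so exactly `w` of the `n` compounds are present in every
#' mixture. The payload is zero-padded to a whole number of blocks; the pad
#' count is recorded.
#'
#' @param bits Integer 0/1 vector.
#' @param codebook A [build_codebook()] codebook with integer `data_bits`.
#' @return A `presence_matrix` with mapping `"sparse"`.
#' @export
#' @examples
#' cb <- build_codebook(16, 4, 8, 2, seed = 1)
#' sparse_encode(rep(0L, 6), cb)   # 2 rows of weight 4
sparse_encode <- function(bits, codebook) {
  b <- codebook$data_bits
  if (b != round(b)) stop("codebook data_bits is not an integer")
  b <- as.integer(b)
  if (length(bits) == 0L) stop("empty bit vector")
  if (!all(bits %in% c(0L, 1L))) stop("bits must be 0/1")
  n_bits <- length(bits)
  N <- ceiling(n_bits / b)
  pad <- N * b - n_bits
  blocks <- matrix(c(as.integer(bits), integer(pad)), nrow = N, ncol = b,
                   byrow = TRUE)
  values <- as.integer(blocks %*% 2^((b - 1):0))  # MSB first
  if (any(values >= codebook$K)) stop("block value exceeds codebook size K")
  mat <- matrix(0L, N, codebook$n)
  mat[cbind(rep(seq_len(N), each = codebook$w),
            as.integer(t(codebook$words[values + 1L, , drop = FALSE])))] <- 1L
  presence_matrix(mat, "sparse", pad_bits = pad, n_bits = n_bits,
                  dim_image = attr(bits, "dim_image"),
                  codebook_meta = list(n = codebook$n, w = codebook$w,
                                       K = codebook$K, seed = codebook$seed))
}

#' Nearest-codeword decoding of observed mixtures
#'
#' Matches every observed row (any weight: rows need not be valid codewords)
#' to the codeword at minimum Hamming distance and converts it back to its
#' data bits. Ties are resolved to the smallest data value and flagged as
#' ambiguous. Always decodes; the per-row distance reports how far each
#' observation was from a valid mixture.
#'
#' @param observed Binary matrix with `n` columns (a read-back
#'   `presence_matrix` or any 0/1 matrix).
#' @param codebook The codebook used to encode.
#' @param n_bits Payload length to return; defaults to the `n_bits` metadata
#'   on `observed`, else all `N * data_bits` bits.
#' @return List: `bits` (decoded payload), `values` (per-row data values,
#'   0-based), `distance` (per-row Hamming distance to the chosen codeword)
#'   and `ambiguous` (per-row tie flag).
#' @export
sparse_decode <- function(observed, codebook, n_bits = NULL) {
  obs <- as.matrix(observed)
  storage.mode(obs) <- "integer"
  if (ncol(obs) != codebook$n) stop("row length must equal code length n")
  res <- cpp_nearest_codeword(codebook$words, codebook$n, obs)
  b <- as.integer(codebook$data_bits)
  block_bits <- t(vapply(res$value, function(v) {
    as.integer(intToBits(v))[b:1]  # MSB first
  }, integer(b)))
  bits <- as.integer(t(block_bits))
  if (is.null(n_bits)) n_bits <- attr(observed, "n_bits")
  if (!is.null(n_bits)) bits <- bits[seq_len(n_bits)]
  attr(bits, "dim_image") <- attr(observed, "dim_image")
  list(bits = bits, values = res$value, distance = res$distance,
       ambiguous = res$ambiguous)
}

#' Symmetric corruption of binary words
#'
#' Flips positions of a binary vector (or each row of a matrix)
#' symmetrically: 0 -> 1 and 1 -> 0 are equally likely to be hit. Either a
#' per-position flip probability `p` or an exact flip count `k` per
#' word/row may be given. Seeded and reproducible.
#'
#' @param x Binary vector or matrix (rows are words).
#' @param p Per-position flip probability in `[0, 1]`.
#' @param k Exact number of flips per word (0..n).
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @return Object of the same shape as `x`.
#' @export
corrupt <- function(x, p = NULL, k = NULL, seed = NULL) {
  if (is.null(p) == is.null(k)) stop("give exactly one of p or k")
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old)); set.seed(seed)
  }
  flip1 <- function(v) {
    n <- length(v)
    idx <- if (!is.null(k)) {
      stopifnot(k >= 0, k <= n)
      if (k == 0) integer(0) else sample.int(n, k)
    } else {
      stopifnot(p >= 0, p <= 1)
      which(runif(n) < p)
    }
    v[idx] <- 1L - v[idx]
    v
  }
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, flip1))
    dimnames(out) <- dimnames(x)
    out
  } else flip1(as.integer(x))
}

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible()
}

#' Simulate the symmetric-corruption read channel
#'
#' For each corruption rate and replicate: draw a fresh random payload of
#' `n_bits` bits, sparse-encode it, flip every matrix cell independently with
#' the given probability (symmetric corruption), decode by nearest codeword,
#' and record the realized raw compound-error rate (fraction of matrix cells
#' flipped) and the decoded bit-error rate.
#'
#' @param n_bits Payload size in bits.
#' @param codebook Codebook for the sparse mapping.
#' @param rates Numeric vector of corruption rates in `[0, 1]`.
#' @param reps Replicates per rate.
#' @param seed Integer seed.
#' @return A `channel_result` data frame: `rate`, `rep`, `raw_error`
#'   (realized pre-decoding compound-error rate), `decoded_ber`, `seed`.
#' @export
#' @examples
#' cb <- build_codebook(16, 4, 16, 4, seed = 1)
#' simulate_channel(64, cb, rates = c(0, 0.05), reps = 3, seed = 7)
simulate_channel <- function(n_bits, codebook, rates, reps = 20L, seed = 1L) {
  stopifnot(all(rates >= 0), all(rates <= 1), reps >= 1)
  old <- get_rng_state(); on.exit(set_rng_state(old)); set.seed(seed)
  out <- expand.grid(rep = seq_len(reps), rate = rates)[, 2:1]
  out$raw_error <- NA_real_
  out$decoded_ber <- NA_real_
  for (i in seq_len(nrow(out))) {
    bits <- sample(0:1, n_bits, replace = TRUE)
    pm <- sparse_encode(bits, codebook)
    obs <- corrupt(unclass_matrix(pm), p = out$rate[i])
    dec <- sparse_decode(obs, codebook, n_bits = n_bits)
    out$raw_error[i] <- mean(obs != pm)
    out$decoded_ber[i] <- mean(dec$bits != bits)
  }
  out$seed <- seed
  class(out) <- c("channel_result", "data.frame")
  out
}

unclass_matrix <- function(pm) {
  m <- unclass(pm)
  attributes(m) <- list(dim = dim(pm))
  m
}

#' @export
print.channel_result <- function(x, ...) {
  agg <- aggregate(cbind(raw_error, decoded_ber) ~ rate, data = x, mean)
  cat("<channel_result> ", length(unique(x$rate)), " rates x ",
      max(x$rep), " reps\n", sep = "")
  print(agg, ...)
  invisible(x)
}
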