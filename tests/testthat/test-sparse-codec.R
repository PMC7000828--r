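test_that("sparse encoding maps blocks to constant-weight rows", {
  cb <- toy_codebook()  # n=16, w=4, K=8 (3 data bits)
  pm <- sparse_encode(rep(0L, 6), cb)
  expect_identical(nrow(pm), 2L)
  expect_true(all(rowSums(pm) == cb$w))
  expect_identical(which(pm[1, ] == 1L), sort(cb$words[1, ]))  # value 0
  # a 6-bit codebook encodes 1600 bits padded to 267 rows
  cb6 <- build_codebook(64, 8, 2^6, 4, seed = 2)
  pm267 <- sparse_encode(sample(0:1, 1600, replace = TRUE), cb6)
  expect_identical(nrow(pm267), 267L)
  expect_identical(attr(pm267, "pad_bits"), 2L)
  # non-power-of-two codebooks cannot define a whole-bit block size
  odd <- toy_codebook()
  odd$K <- 6L; odd$data_bits <- log2(6); odd$words <- odd$words[1:6, ]
  expect_error(sparse_encode(rep(0L, 12), odd), "integer")
})

test_that("sparse decode inverts encode exactly without corruption", {
  cb <- toy_codebook()
  set.seed(6)
  bits <- sample(0:1, 90, replace = TRUE)
  pm <- sparse_encode(bits, cb)
  dec <- sparse_decode(pm, cb)
  expect_identical(dec$bits, as.integer(bits))
  expect_true(all(dec$distance == 0L))
  expect_false(any(dec$ambiguous))
})

test_that("corruption within the correction radius always decodes exactly", {
  cb <- toy_codebook()
  r <- correction_radius(cb$d_achieved)
  expect_true(r >= 1)
  # exhaustive over all codewords and all flip sets of size r
  combos <- utils::combn(cb$n, r)
  for (v in seq_len(cb$K) - 1L) {
    row <- integer(cb$n); row[cb$words[v + 1L, ]] <- 1L
    obs <- matrix(row, ncol(combos), cb$n, byrow = TRUE)
    for (j in seq_len(ncol(combos))) {
      obs[j, combos[, j]] <- 1L - obs[j, combos[, j]]
    }
    dec <- sparse_decode(obs, cb)
    expect_true(all(dec$values == v))
    expect_true(all(dec$distance == r))
  }
})

test_that("ties decode to the smallest value with an ambiguity flag", {
  words <- matrix(c(1L, 2L, 3L, 4L), 2, byrow = TRUE)  # d = 4
  cb <- build_codebook(4, 2, 2, 2, seed = 1, words = words)
  obs <- matrix(c(1L, 0L, 1L, 0L), 1)  # distance 2 from both
  dec <- sparse_decode(obs, cb)
  expect_identical(dec$values, 0L)
  expect_true(dec$ambiguous[1])
})

test_that("symmetric corruption is seeded and respects both modes", {
  x <- rep(c(0L, 1L), 50)
  expect_identical(corrupt(x, k = 0, seed = 1), x)
  expect_identical(corrupt(x, k = length(x), seed = 1), 1L - x)
  a <- corrupt(x, p = 0.3, seed = 42)
  expect_identical(corrupt(x, p = 0.3, seed = 42), a)
  expect_identical(sum(corrupt(x, k = 7, seed = 5) != x), 7L)
  # p = 0.5 flip count within 4 sigma of n/2
  n <- 1e4
  y <- corrupt(integer(n), p = 0.5, seed = 9)
  expect_lt(abs(sum(y) - n / 2), 4 * sqrt(n * 0.25))
  # matrix mode corrupts each row independently
  m <- matrix(0L, 4, 50)
  cm <- corrupt(m, k = 3, seed = 2)
  expect_identical(unname(rowSums(cm)), rep(3, 4))
})

test_that("channel simulation: zero rate is exact, BER grows with rate", {
  cb <- build_codebook(32, 6, 64, 6, seed = 3)
  res <- simulate_channel(120, cb, rates = c(0, 0.05, 0.3), reps = 4,
                          seed = 17)
  expect_s3_class(res, "channel_result")
  expect_true(all(res$decoded_ber[res$rate == 0] == 0))
  expect_true(all(res$raw_error[res$rate == 0] == 0))
  agg <- tapply(res$decoded_ber, res$rate, mean)
  expect_true(agg[["0"]] <= agg[["0.3"]])
  # reproducible under the same seed
  res2 <- simulate_channel(120, cb, rates = c(0, 0.05, 0.3), reps = 4,
                           seed = 17)
  expect_identical(res$decoded_ber, res2$decoded_ber)
})

test_that("capacity bookkeeping: log2 C(512, 32) is about 169", {
  log2_states <- lchoose(512, 32) / log(2)
  expect_equal(round(log2_states), 169)
  expect_equal(log2_states, 168.9, tolerance = 1e-3)
})
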