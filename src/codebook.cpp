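// Bit-packed kernels for constant-weight codebooks: greedy seeded
// construction, exact all-pairs minimum Hamming distance, and
// nearest-codeword decoding. Words are packed 64 positions per uint64_t so a
// pairwise distance is a handful of XOR+popcount operations; the all-pairs
// scan is blocked for cache locality (paper scale is 2^16 words of length
// 512, i.e. ~2^31 pairs).
#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <vector>
using namespace Rcpp;

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
#endif
}

// pack 1-based position lists (K x w) into K words of `nw` uint64 each
static std::vector<uint64_t> pack_positions(const IntegerMatrix& pos, int n) {
  const int K = pos.nrow(), w = pos.ncol(), nw = (n + 63) / 64;
  std::vector<uint64_t> words((size_t)K * nw, 0u);
  for (int i = 0; i < K; ++i) {
    for (int j = 0; j < w; ++j) {
      int p = pos(i, j) - 1;
      if (p < 0 || p >= n) stop("position out of range");
      words[(size_t)i * nw + p / 64] |= (uint64_t)1 << (p % 64);
    }
  }
  return words;
}

static inline int dist_words(const uint64_t* a, const uint64_t* b, int nw) {
  int d = 0;
  for (int t = 0; t < nw; ++t) d += popcount64(a[t] ^ b[t]);
  return d;
}

// [[Rcpp::export]]
int cpp_min_distance(IntegerMatrix positions, int n) {
  const int K = positions.nrow(), nw = (n + 63) / 64;
  if (K < 2) stop("need at least two codewords");
  std::vector<uint64_t> words = pack_positions(positions, n);
  const int B = 256;  // block size (words); a block pair stays in L1/L2
  int best = n + 1;
  for (int bi = 0; bi < K; bi += B) {
    int ei = std::min(bi + B, K);
    for (int bj = bi; bj < K; bj += B) {
      int ej = std::min(bj + B, K);
      for (int i = bi; i < ei; ++i) {
        const uint64_t* wi = &words[(size_t)i * nw];
        int j0 = (bj == bi) ? i + 1 : bj;
        for (int j = j0; j < ej; ++j) {
          int d = dist_words(wi, &words[(size_t)j * nw], nw);
          if (d < best) best = d;
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return best;
}

// sample w distinct positions in [0, n) by partial Fisher-Yates
static void sample_word(std::vector<int>& pool, int n, int w,
                        std::mt19937_64& rng, std::vector<int>& out) {
  for (int i = 0; i < n; ++i) pool[i] = i;
  for (int j = 0; j < w; ++j) {
    std::uniform_int_distribution<int> u(j, n - 1);
    std::swap(pool[j], pool[u(rng)]);
    out[j] = pool[j];
  }
}

// Greedy seeded construction with rejection/replacement: draw random weight-w
// words, keep one only if its distance to every accepted word is >= d_min,
// else redraw (up to max_tries per slot). Returns 1-based positions and the
// achieved (exact) minimum pairwise distance among accepted words.
// [[Rcpp::export]]
List cpp_build_codebook(int n, int w, int K, int d_min, double seed,
                        int max_tries) {
  const int nw = (n + 63) / 64;
  std::mt19937_64 rng((uint64_t)seed);
  std::vector<uint64_t> words((size_t)K * nw, 0u);
  IntegerMatrix positions(K, w);
  std::vector<int> pool(n), draw(w);
  std::vector<uint64_t> cand(nw);
  int achieved = n + 1;  // min over accepted pairs
  for (int i = 0; i < K; ++i) {
    bool ok = false;
    int best_reject = -1;
    for (int t = 0; t < max_tries && !ok; ++t) {
      sample_word(pool, n, w, rng, draw);
      std::fill(cand.begin(), cand.end(), 0u);
      for (int j = 0; j < w; ++j) cand[draw[j] / 64] |= (uint64_t)1 << (draw[j] % 64);
      int dmin_i = n + 1;
      for (int k = 0; k < i; ++k) {
        int d = dist_words(cand.data(), &words[(size_t)k * nw], nw);
        if (d < dmin_i) dmin_i = d;
        if (dmin_i < d_min) break;
      }
      if (dmin_i >= d_min) {
        ok = true;
        if (i > 0 && dmin_i < achieved) achieved = dmin_i;
        std::copy(cand.begin(), cand.end(), words.begin() + (size_t)i * nw);
        std::sort(draw.begin(), draw.end());
        for (int j = 0; j < w; ++j) positions(i, j) = draw[j] + 1;
      } else if (dmin_i > best_reject) best_reject = dmin_i;
    }
    if (!ok) {
      return List::create(_["ok"] = false, _["filled"] = i,
                          _["best_rejected_distance"] = best_reject);
    }
    if (i % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["ok"] = true, _["positions"] = positions,
                      _["achieved"] = achieved > n ? NA_INTEGER : achieved);
}

// Nearest-codeword decoding: for each observed dense 0/1 row, the codeword at
// minimum Hamming distance; ties resolved to the smallest data value with an
// ambiguity flag.
// [[Rcpp::export]]
List cpp_nearest_codeword(IntegerMatrix positions, int n,
                          IntegerMatrix observed) {
  const int K = positions.nrow(), nw = (n + 63) / 64, N = observed.nrow();
  if (observed.ncol() != n) stop("row length must equal code length n");
  std::vector<uint64_t> words = pack_positions(positions, n);
  IntegerVector value(N), dist(N);
  LogicalVector ambiguous(N);
  std::vector<uint64_t> row(nw);
  for (int r = 0; r < N; ++r) {
    std::fill(row.begin(), row.end(), 0u);
    for (int c = 0; c < n; ++c) {
      int v = observed(r, c);
      if (v != 0 && v != 1) stop("observed matrix must be binary");
      if (v) row[c / 64] |= (uint64_t)1 << (c % 64);
    }
    int best = n + 1, best_k = 0;
    bool tie = false;
    for (int k = 0; k < K; ++k) {
      int d = dist_words(row.data(), &words[(size_t)k * nw], nw);
      if (d < best) { best = d; best_k = k; tie = false; }
      else if (d == best) tie = true;
    }
    value[r] = best_k;  // 0-based data value
    dist[r] = best;
    ambiguous[r] = tie;
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["value"] = value, _["distance"] = dist,
                      _["ambiguous"] = ambiguous);
}
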