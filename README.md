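# ugimem — molecular data storage in Ugi product mixtures

`ugimem` is an R package for scientists exploring non-genomic molecular data
storage: it implements, end to end in software, a codec that writes digital
data into presence/absence mixtures of four-component Ugi reaction products
and reads it back from MALDI FT-ICR mass spectra.

A combinatorial Ugi library built from an amine, aldehyde, carboxylic acid
and isocyanide panel (5 × 5 × 12 × 5 = 1500 products here, each the sum of
its reagent formulas minus H2O) supplies the alphabet. A payload becomes an
N × M binary **presence matrix** p, one row per plate spot, one column per
compound, either

- **directly** — bit *i* of a row drives compound *i* (M bits per spot), or
- **sparsely** — every 16-bit block selects one of K = 2^16 codewords of a
  constant-weight code (n = 512 compounds, exactly w = 32 present). With
  minimum pairwise Hamming distance d ≥ 36, nearest-codeword decoding is
  guaranteed exact with up to ⌊(d−1)/2⌋ = 17 of 512 compound calls wrong
  per mixture.

Reading uses per-spot calibration against a spiked reference, resampling to
a common m/z grid, SNR normalization SNR = (I − μ)/σ with sigma-clipped
background moments, and presence calls by either a ROC-optimal threshold on
the sodiated peak (τ minimizing √(FPR² + (1−TPR)²)) or per-compound
supervised classifiers (ridge logistic on up to 64 spectral peaks, or
random forests with 300 trees) that exploit isotopes, alternative adducts
and reagent-complex side channels. A fully seeded plate simulator (adducts,
isotope envelopes, matrix background, competitive ionization, reaction
failures, per-spot mass offsets) makes every stage testable without
instrument data.

## Worked example

```r
library(ugimem)

lib <- enumerate_library(read_reagents())   # the packaged 1500-product library
lib$M[1]                                    # 485.3254 Da (monoisotopic)
adduct_mz(lib$M[1], "Na")                   # 508.3146 ([M+Na]+)

set.seed(1)
img <- matrix(rbinom(64 * 64, 1, 0.5), 64, 64)   # a 4096-bit payload
cfg <- run_config(img, mapping = "direct", n_compounds = 32,
                  sim = sim_params(mz_range = c(420, 850), grid_step = 0.002),
                  detector = "threshold", library = lib, seed = 5)
rt <- roundtrip(cfg)        # write -> simulate spectra -> read -> decode
rt$report
#> <read_report> accuracy 0.9968 (13 cell errors); mixtures fully correct: 115/128
rt$bit_accuracy
#> [1] 0.9968262
```

The report says 99.7% of the 4096 presence calls were read back correctly
with single sodiated-peak thresholds on a noisy simulated plate; with
`detector = "logistic"` the multi-peak models use correlated spectral
features and match or beat that, and with
`sim_params(preset = "noiseless", ...)` recovery is bit-exact. For the
sparse mapping:

```r
cb <- build_codebook(n = 512, w = 32, K = 2^16, d_min = 36, seed = 1)
cb$d_achieved                # 38: exact minimum distance over all ~2^31 pairs
correction_radius(cb$d_achieved)   # 18 guaranteed-correctable errors per mixture
res <- simulate_channel(1600, cb, rates = c(0.033, 0.066), reps = 5, seed = 1)
#   raw compound-error rates of 3.3-6.6% decode to bit-error rates near zero
```

A command-line interface wraps the same pipelines:

```sh
Rscript inst/cli/ugimem.R channel-sim --bits 1600 --rates 0,0.02,0.05 --reps 20
Rscript inst/cli/ugimem.R roundtrip --payload img.png --noise off
```

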