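---
title: "Storing digital data in Ugi product mixtures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Storing digital data in Ugi product mixtures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ugimem` implements a complete software codec for molecular data storage in
mixtures of four-component Ugi reaction products: writing bits as
presence/absence patterns of small molecules spotted on a MALDI plate,
simulating the FT-ICR mass-spectrometric readout of such a plate, and
recovering the bits from spectra. This vignette explains the underlying
models, the tunable parameters and their defaults, the design decisions that
were genuinely open, and what the synthetic experiments do and do not
demonstrate.

## The chemistry layer

The Ugi reaction condenses an amine, an aldehyde, a carboxylic acid and an
isocyanide into a single bis-amide product plus water. Consequently the
product's molecular formula is the elementwise sum of the four reagent
formulas minus H2O, and a library built from $n_1 \times n_2 \times n_3
\times n_4$ reagents contains $\prod n_i$ enumerable products. The packaged
reagent table (5 amines, 5 aldehydes, 12 acids, 5 isocyanides) generates the
1500-product library used throughout; with 10 reagents per role the same
machinery enumerates 10,000 products. Enumeration order is frozen — amine
slowest, then aldehyde, acid, isocyanide fastest — so a library index is a
reproducible name for a molecule.

Monoisotopic masses are sums over a pinned table of monoisotopic atomic
masses (CIAAW values), so results are identical across machines. Readout
works on singly charged cation adducts: $[M+X]^+$ at $M + m_X - m_e$ for
$X \in \{\mathrm{H}, \mathrm{Na}, \mathrm{K}\}$. The electron mass is
subtracted by default because FT-ICR mass accuracy (sub-ppm) resolves it; a
flag disables this for coarse matching. Isotope envelopes use a
carbon-binomial approximation: only $^{13}$C substitutions are modelled,
with peak $k$ at $+k \times 1.00335$ Da and abundance
$\binom{n_C}{k} (p/(1-p))^k$ relative to the monoisotopic peak
($p = 0.0107$). Ugi products from these reagents contain no elements with
large A+2 isotopes other than sulfur (two acids), so the approximation is
adequate for readout purposes; full isotopologue convolution is out of
scope.

Several library members are exact isomers (e.g. two of the packaged acids
share C15H21NO4, and two aldehydes share C5H10O), so the library genuinely
contains mass-degenerate products. `mass_collisions()` partitions the
library into indistinguishable groups at a ppm tolerance;
`select_subset()` picks data-plate subsets that avoid such collisions,
because a single-peak readout cannot separate exact isomers (multi-peak
models can, via correlated side channels — see below).

## Writing: presence matrices, plates, transfer lists

A payload (a bit vector or a bilevel image flattened row-major, white = 0)
becomes an $N \times M$ binary presence matrix. Two mappings are
implemented:

* **Direct**: bit $i$ of a row drives compound $i$; $N =
  \lceil |b| / M \rceil$ rows, trailing pad bits are zeros whose count is
  recorded. Decoding is a reshape.
* **Sparse**: each 16-bit block (generally, $\log_2 K$ bits) selects one of
  $K$ codewords of a constant-weight code: length $n$, exactly $w$ ones per
  word. The default full-scale geometry is $n = 512$, $w = 32$,
  $K = 2^{16}$, minimum pairwise Hamming distance $d_{\min} \ge 36$. Since
  $\log_2 \binom{512}{32} \approx 169$, valid mixtures are a vanishing
  fraction of possible ones, and observed rows can be rounded to the nearest
  valid codeword: up to $\lfloor (d_{\min}-1)/2 \rfloor = 17$ of the 512
  presence calls per mixture (3.3%) can be wrong with recovery still
  guaranteed.

The codebook construction was an open design point: no published recipe
fixes how $2^{16}$ weight-32 words at distance 36 are obtained. We use
seeded random constant-weight sampling with greedy rejection: a candidate is
kept only if its distance to every accepted word is at least $d_{\min}$.
Two random weight-32 words of length 512 overlap in $\approx 2$ positions
on average (distance $\approx 60$), so rejections are rare and the achieved
minimum distance is typically 38–42. Verification is exact: all
$\binom{K}{2} \approx 2^{31}$ pairwise distances are computed with
bit-packed words and hardware population counts (compiled code), which
takes on the order of a minute or two on one CPU. The codebook interface
accepts externally constructed word sets, so structured codes can be
substituted. Ties in nearest-codeword decoding go to the smallest data
value and are flagged as ambiguous, because a silent arbitrary choice would
be untestable.

Physically, each presence-matrix "1" is one 2.5 nL acoustic droplet from
the compound's library well to the spot, plus 30 nL of MALDI matrix per
spot; spots merge above ~200 nL, capping direct mixtures at 68 compounds
per spot on a 1536-spot (32 × 48) plate. `write_transfer_list()` enforces
the budget and emits the handler-style CSV.

## The plate simulator

No instrument data ships with the package, so the simulator is the bridge
that makes every downstream stage testable. For each spot it renders a
profile spectrum on a uniform m/z grid:

* **Peaks.** Each present, non-failed compound contributes Gaussian peaks at
  its H/Na/K adduct m/z with FWHM $= m/R$ ($R = 1.3 \times 10^5$ by
  default), carbon-binomial isotope satellites, adduct intensity ratios
  Na-dominant (H 0.25, Na 1, K 0.4 by default), a lognormal per-(spot,
  compound) abundance (median 80, log-sd 0.4), a fixed per-compound
  ionization efficiency (log-sd 0.6), and division by
  $n_\text{present}^{0.3}$ for competitive ionization.
* **Reaction failure** is a library-level Bernoulli event (default 10%): a
  failed well emits no product peaks anywhere, matching how a failed
  synthesis behaves under repeated dispensing. Data plates are simulated
  without failures by default because their subsets are drawn from
  validated wells; library-validation simulations keep the 10% rate.
* **Reagent complexes.** Half of the compounds (default) carry a sodiated
  complex with their residual aldehyde at $M + M_\text{ald} + m_{Na} -
  m_e$, with intensity tracking the compound's abundance but not its
  own-adduct efficiency. This emulates the documented phenomenon that
  information-bearing side channels exist even when a compound's own
  adducts ionize poorly — the effect that makes multi-peak readout
  worthwhile. The frequency and strength of such channels are free
  parameters of the simulator, not measured constants; they were chosen so
  that correlated side-channels are common, consistent with reports that
  learned multi-peak models reduce raw read errors severalfold.
* **Background.** A fixed per-plate set of matrix peaks (positions uniform,
  lognormal intensities) shared across spots, plus a truncated-Gaussian
  baseline (mean 10, sd 2).
* **Mass error.** One multiplicative ppm offset per spot (Gaussian, sd 2
  ppm) — exactly what a single spiked calibrant can correct. Higher-order
  mass error is out of scope. Every spot is spiked with a reference
  compound (neutral mass 420.226 Da, a synthetic Ugi-like calibrant mass)
  read at its sodiated m/z.

Everything is driven by one seed; identical (matrix, params, seed) produce
identical spectra. The `noiseless` preset switches off all randomness and
background so ideal-limit identities (exact recovery) can be asserted.

Grids default to 0.001 Da over m/z 300–1000, matching the sub-mDa peak
width regime of FT-ICR. The packaged tests and examples use narrower
windows (e.g. 420–850 Da) and 0.002–0.005 Da steps so suites run in
minutes; these are the package's own working scales and do not change any
model.

What the simulator does *not* model: laser-shot statistics, detector
transients, true HCCA cluster chemistry, ion suppression beyond the
power-law, inter-spot carryover. Passing synthetic tests therefore
demonstrates the correctness of the codec and readout machinery under the
stated statistical structure, not instrument-grade performance on real
plates.

## Reading: calibration, SNR, detection

Reading proceeds spectrum by spectrum: find the calibrant apex within a ppm
window (an absent calibrant is a flagged error, not a silent pass), divide
the m/z axis by the implied offset, resample all spots onto the common grid
by linear interpolation, and normalize each spot to signal-to-noise ratios
$\mathrm{SNR} = (I - \mu)/\sigma$. The background moments $\mu, \sigma$
come from iterative 3$\sigma$ clipping (clip above $\mu + 3\sigma$,
re-estimate, at most 10 iterations) — a deterministic, peak-robust
estimator chosen because the reference background definition is not fully
specified; the method tag is stored so median/MAD variants can be swapped
in. SNR is invariant under affine intensity rescaling, which is the point:
it makes thresholds transferable across spots.

**Single-peak detection.** A compound is called present when the apex SNR
within ±15 ppm of its sodiated m/z exceeds a threshold. Thresholds come
from ROC analysis: candidate thresholds are midpoints between sorted unique
scores, counts are exact, and the chosen $\tau$ minimizes the distance to
the (0,1) ROC corner, $\sqrt{\mathrm{FPR}^2 + (1-\mathrm{TPR})^2}$ (ties
to the larger threshold, favouring fewer false positives). Library
validation uses one global $\tau$ over all (well, product) pairs — with the
rule that products mass-degenerate with a well's expected product count as
expected there — while data plates fit one $\tau$ per compound on the
labeled training fraction.

**Multi-peak detection.** One model per compound, logistic or random
forest, trained on a seeded 30/70 train/test split of spots. Features are
spectral peaks: (i) engineered apex features at the compound's own known
adduct/isotope positions, and (ii) grid columns that survive a noise-floor
prune (mean SNR ≥ 3, at most 20,000 columns) and an AUROC screen. The
screen keeps columns whose $|\mathrm{AUROC} - 0.5|$ exceeds four
Mann–Whitney null standard deviations and ranks them by that score, so both
positively and negatively informative peaks (suppression effects) qualify.
This significance screen matters at small training sizes: with a few dozen
labeled spots, plain top-$k$ AUROC ranking admits chance-level columns that
swamp the model. Logistic models are capped at 64 features and fitted with
a small fixed ridge penalty (the split is often separable, where
unpenalized maximum likelihood does not exist; a fixed penalty keeps fits
deterministic). Forests use 300 trees of unlimited depth on all pruned
columns and select features themselves. The decision cutoff on a model's
score is chosen by the same ROC corner rule as single-peak thresholds
(out-of-bag scores for forests), not a fixed 0.5. A compound with constant
training labels falls back to its single-peak threshold and is flagged.

Classifier inputs are SNR values by default (scale-free across spots); raw
intensities are available behind a flag and are what the noiseless pipeline
uses, since a noise-free background has no defined SNR.

## Numerical choices and degenerate inputs

* Formula subtraction below zero, unknown elements, role mismatches, empty
  reagent groups, over-capacity plates and over-budget spots are all hard
  errors.
* ROC requires both classes; single-class labels are errors, not silent
  0/1 rates.
* A constant spectrum has no background estimate (degenerate error);
  calibration accepts any positive apex when the background is degenerate,
  which is the noiseless limit.
* `peak_intensity` returns the windowed maximum, so with no peak in the
  window it reports background level and with two peaks the larger —
  documented contract rather than error.
* Single-word codebooks report distance $2w$ by convention; distances of
  equal-weight words are always even, and `d_min` must be even.
* Missing pad metadata on decode is an error; pad bits are zeros and are
  stripped exactly.

## Scales used by the packaged experiments

The acceptance-style experiments use: the full 1500-product library; the
full-scale codebook ($2^{16}$ words, built and exactly verified in a few
minutes); a 1600-bit payload in 100 sparse mixtures for channel
simulations; and a 64 × 64 = 4096-bit image on a 128-spot, 32-compound
direct plate (m/z 420–850, 2 mDa grid) for end-to-end round trips, with
five paired seeds for the single- vs multi-peak comparison. These sizes
are the package's chosen working scales: large enough to exercise every
code path and the statistical claims, small enough to run on a laptop.

## Known limitations

* Plate-specific empirical numbers from real experiments (overall
  accuracies of specific stored images, the specific validated fraction of
  a synthesized library, a particular global $\tau$) depend on instrument
  data that is not distributed and are not reproduced here; the package
  asserts the properties and mechanisms instead.
* The carbon-binomial isotope model under-represents sulfur-containing
  acids' A+2 peaks.
* Sparse decoding is hard-decision nearest-codeword; soft decoding from
  intensities is out of scope.
* The simulator's interference parameters are plausibility choices, not
  fitted constants; conclusions that depend on their exact values (e.g.
  the precise size of the multi-peak advantage) should be read
  qualitatively.
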