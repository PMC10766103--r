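---
title: "Bispectral energy feature maps and multi-map classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bispectral energy feature maps and multi-map classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`bisqus` characterizes tissue from raw ultrasound radiofrequency (RF)
frames — the beamformed echo signal before envelope detection and display
processing. Conventional B-mode images discard phase and high-frequency
content that is informative about sub-resolution microstructure. The package
works directly on the RF signal through *higher-order spectral analysis*:
the third-order cumulant and its 2-D Fourier transform, the bispectrum,
which is blind to Gaussian backgrounds and responds specifically to phase
coupling between frequency components (for example the second harmonic
generated by nonlinear scattering media).

The pipeline has four stages:

1. **Phantom simulation** (`simulate_frame`, `simulate_dataset`) — labeled
   synthetic RF frames with class-dependent bispectral structure, so the
   entire downstream chain is testable without clinical data.
2. **Higher-order spectral engine** (`estimate_c3`,
   `bispectrum_indirect`, `principal_domain`, `subdivide_bands`,
   `region_energy`, `segment_features`) — per-segment band energies of the
   bispectrum.
3. **Feature maps** (`build_feature_maps`, `pairwise_stats`,
   `bmode_from_rf`) — per-frame images BS_S1/BS_S2/BS_S3/BS_A plus
   comparison statistics.
4. **Classifier** (`net_config`, `train_msnet`, `predict`,
   `evaluate_model`) — a weight-sharing multi-branch CNN with gated
   feature-map attention and a cosine-similarity constraint loss.

# The higher-order spectral engine

## Third-order cumulant

For a segment $x(n)$, $n = 1, \dots, N$ (default $N = 256$ samples), the
third-order cumulant at lags $(k, l)$ is estimated as the sample average

$$C_3(k, l) = \frac{1}{N} \sum_n x(n)\, x(n + k)\, x(n + l),$$

summed over every $n$ for which the three indices fall inside the segment.
Choices made here:

* **Biased ($1/N$) normalization.** The defining sum is written without an
  explicit expectation; we use the standard biased indirect-method estimate,
  which has smaller variance at the short segment lengths used here and
  makes the all-zero segment map exactly to an all-zero lattice.
* **Mean subtraction on by default** (`demean = TRUE`). Cumulants are
  defined for zero-mean processes; a `demean = FALSE` flag exists so unit
  tests can compare against literal hand sums.
* **Real input.** RF samples are real, so the conjugate in the defining
  triple product is a no-op; inputs are treated as real throughout.
* **Lag extent** `max_lag = 63` for 256-sample segments (`nfft = 128`),
  i.e. a quarter of the segment — the usual compromise between bifrequency
  resolution and estimator variance. Both are configurable; the desk-scale
  experiment setting uses `max_lag = 31`, `nfft = 64`.
* **No lag window by default**; an optional Parzen taper
  (`lag_window = "parzen"`) is available for variance reduction.

The estimator is implemented in C++ (exploiting the exchange symmetry
$C_3(k,l) = C_3(l,k)$, so only half the lattice is computed) because it is
evaluated thousands of times per frame.

## Bispectrum and its principal domain

The bispectrum is the 2-D Fourier transform of the lag lattice,

$$\mathrm{BS}(f_1, f_2) = \sum_k \sum_l C_3(k, l)\,
  e^{-j 2\pi f_1 k}\, e^{-j 2\pi f_2 l},$$

evaluated on an `nfft` × `nfft` grid via a zero-padded 2-D FFT (exact, not
approximate: the padding places lag $k$ at index $k \bmod \mathrm{nfft}$,
so the FFT reproduces the double sum to rounding error; the test suite pins
this against a literal double-sum oracle at $10^{-9}$). Axes are fftshifted
to normalized frequencies in $[-\tfrac12, \tfrac12)$ cycles/sample.

For a real signal the bispectrum has twelve symmetry regions; all
information lives in the principal domain
$S_0 = \{0 \le f_2 \le f_1,\ f_1 + f_2 \le \tfrac12\}$. A quadratically
phase-coupled triple — components at $f_1$, $f_2$ and $f_1 + f_2$ with
$\varphi_3 = \varphi_1 + \varphi_2$ — produces a peak at $(f_1, f_2)$
inside this triangle, which is what the band energies pick up.

## Frequency subdivision and band energies

$[0, \tfrac12]$ of the split axis is cut into three equal bands with edges
at $\tfrac16$ and $\tfrac13$; intersecting with $S_0$ gives $S_1$ (low
band), $S_2$ (mid) and $S_3$ (high). Numerical conventions:

* Bands are half-open $[\mathrm{lo}, \mathrm{hi})$ except the last, closed
  at $\tfrac12$, so boundary bins are assigned unambiguously and
  $S_1, S_2, S_3$ partition $S_0$ exactly.
* **Split axis.** The horizontal ($f_1$) axis is the default; `split_axis =
  "f2"` is available. For sources whose band conventions are described
  ambiguously, both produce a valid partition; the default follows the
  horizontal-direction reading. On the $S_0$ triangle the $f_1$ split is
  the less degenerate choice ($f_2$ only reaches $\tfrac14$).
* **Energy** is $\sum |\mathrm{BS}|^2$ over the masked bins
  (`energy_mode = "power"`); `"magnitude"` ($\sum |\mathrm{BS}|$) is
  provided since "energy" is used loosely in parts of the field.
* `E_S0` is computed as `E_S1 + E_S2 + E_S3` — the same summands, so the
  partition identity holds *exactly*, not merely to tolerance.
* Whether practitioners average sub-block bispectra or use one estimate per
  segment varies; this package uses a single 256-sample estimate per
  segment (the direct block-averaged estimator `bispectrum_direct` exists
  as an independent cross-check of peak locations, not as the feature
  path).

# Feature maps

Segments tile each frame with an axial sliding window (`window = 256`,
`hop = 64` by default; one map column per scanline). Row $r$, column $c$ of
each map is the band energy of the segment starting at sample
$(r-1)\cdot\mathrm{hop} + 1$ on line $c$; incomplete trailing windows are
dropped, giving $\lfloor (n_\mathrm{samples} - \mathrm{window}) /
\mathrm{hop} \rfloor + 1$ rows. The raw maps satisfy
`BS_S1 + BS_S2 + BS_S3 == BS_A` elementwise by construction.

**Image normalization.** Raw band energies are heavy-tailed: a handful of
strongly coupled segments dominate, and plain min–max scaling to 8 bits
produces nearly black images (on the built-in phantoms the mean pixel value
is about 7/255, and image statistics carry almost no class information).
The default is therefore logarithmic compression, $\log_{10}(1 + E)$,
before min–max scaling — the same argument that makes B-mode display
log-compressed. `mode = "linear"` is retained as an option. Constant maps
map to all-zero images (degenerate-range rule), and both modes are
monotone, so pixel ordering is preserved.

**Comparison statistics.** `pairwise_stats` quantifies how much independent
information the four maps carry: full 4×4 mutual-information and RMSE
matrices over the 8-bit images, per-map gray histograms, and each map's
average MI/RMSE versus the other three. MI is computed in bits from a
64-bin joint histogram of the 8-bit images; published MI values from other
binning conventions are not comparable and are not treated as reproduction
targets. The MI diagonal equals the per-map histogram entropy, the RMSE
diagonal is zero, and both matrices are symmetric — all property-tested.

**B-mode stand-in.** `bmode_from_rf` is a plain reference reconstruction —
per-line analytic-signal envelope (FFT half-spectrum method), log
compression over a 60 dB dynamic range, min–max to 8 bits. It exists so a
grayscale-image baseline can be formed; it is not any vendor's processing
chain.

# The synthetic phantom

Per scanline, a Poisson number of point scatterers (expected
`scatterer_rate` per 256 samples) at uniform axial positions with
zero-mean Gaussian amplitudes is convolved with a Gaussian-enveloped pulse
(`f0_norm = 0.125`, i.e. a 5 MHz probe at 40 MHz sampling — keeping the
second harmonic well inside Nyquist; fractional −6 dB bandwidth 0.6). The
frame is normalized to unit mean power, passed through the memoryless
quadratic $y = s + \beta s^2$, and white Gaussian noise is added at
`snr_db` relative to the unit reference power (so with scatterers disabled
the frame variance is exactly $10^{-\mathrm{snr}/10}$ — a calibration the
tests check to 5%).

The quadratic term is the deliberate minimal nonlinearity: it creates
exactly the second-harmonic phase coupling that the bispectrum detects, so
class pairs differing in $\beta$ differ systematically in high-band energy
BS_S3. The built-in presets are fixed study conditions, not tuning knobs:
benign $\beta = 0.05$, rate 4; malignant $\beta = 0.3$, rate 12 — a
learnable but not trivial separation (standardized BS_S3 difference ≈ 9
over 20+20 frames at the desk scale).

What the phantom does *not* emulate: full-wave propagation, beamforming,
attenuation/TGC, depth-dependent focusing, or any real tumor geometry
(there is no lesion ROI — frames are statistically homogeneous). Passing
end-to-end tests therefore demonstrates that the pipeline's machinery
works and that bispectral band energies are learnable class evidence under
the stated generative model; it says nothing about clinical performance.

Determinism: `simulate_frame` is a pure function of `(params, seed)` using
a private, restorable RNG; dataset-level per-frame seeds derive from the
master seed as `(master * 1000003 + index) mod (2^31 - 1)`.

# The classifier

## Architecture

Each of the $K = 4$ map images is preprocessed (bilinear resize to
256×256, center crop to 224×224 — rows/columns 17..240 — scaled to
$[0,1]$, replicated to 3 channels) and routed through **one shared
backbone**; global average pooling of the last convolutional features
yields one $M$-vector $h_k$ per map. Weight sharing is what makes the
four-branch model light: the parameter count drops by exactly
$(K-1)\times$ the backbone size, and with the pinned dimensions
(ResNet-50 feature extractor, 23,508,032 parameters; attention width
$L = 256$ at $M = 2048$, bias-free; 2-way head) the shared model keeps
24,560,962 / 95,085,058 = 25.83% of the four-independent-backbone budget.

Only the desk-scale `tinycnn` backbone (four 3×3 stride-2 convolution +
ReLU blocks, channels 16/32/64/128, $M = 128$) has a native
forward/backward implementation (im2col convolutions in C++); ResNet-50,
ResNet-101 and VGG-19 are registered with closed-form parameter arithmetic
for the accounting functions, and unimplemented backbone names raise an
error rather than silently substituting.

## Gated feature-map attention

The fused descriptor is $z = \sum_k a_k h_k$ with
$a = \mathrm{softmax}(s)$ and gate scores

$$s_k = w^\top\!\left(\tanh(V h_k) \odot \sigma(U h_k)\right),$$

$V, U \in \mathbb{R}^{L \times M}$. The sigmoid gate tempers the
near-linear regime of tanh. Softmax guarantees $a_k > 0$ and
$\sum_k a_k = 1$, so fusion never changes the feature dimension, and the
weights are directly interpretable as per-map importance coefficients
(`importance_report`). Properties tested: simplex over 1000 random trials,
singleton identity, uniform weights for identical inputs, permutation
equivariance of $a$ with invariance of $z$. $V$, $U$ and $w$ are bias-free
by default (`attention_bias = TRUE` adds biases; this shifts the parameter
ratio by under 0.01 percentage points).

## Losses

**Classification loss** is mean binary cross-entropy over the batch with
$p$ the positive-class (malignant) probability. One source formulation
labels $p$ as "the probability of a negative prediction", which
contradicts the accompanying $y \log p$ term; we treat that as a
notational slip and implement standard BCE, with a `literal_negative` flag
for the strict-literal reading. Probabilities outside $(0,1)$ are clamped
at $10^{-7}$ with a warning.

**Similarity constraint (SM).** Embeddings are the L2-normalized $h_k$.
Per map type $j$, the prototype $c_j$ is the re-normalized batch mean of
that type's embeddings, and

$$P(j \mid x) = \frac{\exp(\cos(f_x, c_j)/\tau)}
  {\sum_{j'} \exp(\cos(f_x, c_{j'})/\tau)}, \qquad
\mathrm{Loss_{sm}} = -\sum_x \log P(t(x) \mid x)
  - \sum_x \sum_{j \ne t(x)} \log(1 - P(j \mid x)),$$

with temperature $\tau = 0.1$. This is the "positive concentration,
negative separation" objective: same-type embeddings are pulled toward
their prototype, other types pushed away. Design points:

* The exact probability model behind the published formulation is not
  reproducible from its citation alone; the temperature-scaled prototype
  softmax above matches the stated form and goal and is the package's own
  choice.
* **Stop-gradient prototypes.** In the backward pass the prototypes are
  treated as constants. This is the common convention for prototype
  losses, avoids the near-cancellation that makes full prototype gradients
  ill-conditioned in small batches, and is verified in the gradient tests
  (attention/head gradients match finite differences at $10^{-9}$; the
  backbone-path residual under SM is exactly the stop-gradient term).
* **Reduction.** `sm_loss` itself is the defining *sum* over instances
  (its closed form for $n$ identical embeddings is
  $-n \log \frac1K - n(K-1)\log(1 - \frac1K)$, tested exactly). Inside
  training batches the per-instance *mean* is used so the effective weight
  of the constraint does not scale with batch size.
* **Combination.** $\mathrm{total} = \mathrm{Loss_{att}} + \lambda\,
  \mathrm{Loss_{sm}}$ with $\lambda = 0.1$ — the combination rule and
  weight are package choices (the source is silent); $\lambda$ and $\tau$
  are both exposed in `net_config`.

## Training

Adam (batch size 8) under cosine annealing from 0.002 to $10^{-4}$:
$\mathrm{lr}(t) = \mathrm{lr_{final}} + (\mathrm{lr_{init}} -
\mathrm{lr_{final}})(1 + \cos(\pi t / T))/2$ over the epoch horizon $T$.
"Stop when the validation loss is stable" is operationalized as patience:
training halts `patience` epochs after the best validation loss, and the
best-validation checkpoint is returned. Training is seeded and
deterministic: identical data, config and seed reproduce the history
bit-for-bit. Augmentation is the stated resize + center crop; an optional
horizontal flip exists in concept but is off and not part of any shipped
experiment. The decision threshold for confusion-matrix metrics is 0.5
(no operating point is published); AUC uses the rank (pairwise
concordance) estimator with midrank tie handling, cross-checked against an
independent ROC implementation in the tests.

# Problem sizes used in the shipped experiments

The package's experiment setting (`synthetic_cohort`) uses 1024×32 frames,
window 256, hop 128, `max_lag = 31`, `nfft = 64` — 7×32 maps per frame —
with 20 training and 10 test frames per class, 10 epochs. These sizes were
chosen once as the desk-scale condition under which a full
simulate → extract → train → evaluate cycle runs in minutes on one CPU
while the class separation remains non-trivial; the spectral-engine
defaults (`window = 256`, `max_lag = 63`, `nfft = 128`) remain the
recommended analysis setting for real frames. Under the shipped setting
the full method (sharing + attention + SM) reaches held-out AUC ≥ 0.9,
and the backbone-only ablation is run on the same split for comparison in
`scripts/acceptance.R`.

# Known limitations

* The phantom's homogeneity means per-map spatial structure carries no
  lesion geometry; attention weights learned on phantoms should not be
  read as clinically meaningful importance coefficients.
* MI values depend on the binning convention; only within-package
  comparisons are meaningful.
* `tinycnn` is deliberately small; it demonstrates the training machinery,
  not state-of-the-art capacity. Large zoo backbones are parameter-counted
  but not runnable here.
* The RF container is this package's own dialect (raw float32 +
  JSON sidecar); no community standard exists for raw RF frames.
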