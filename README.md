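# bisqus

Bispectral energy feature maps and multi-map deep classification for
ultrasound radiofrequency (RF) signals.

## What this package is for

Raw RF frames — the beamformed echo signal before envelope detection and
display processing — carry phase and high-frequency information that
B-mode images discard. `bisqus` turns that information into classifier
input via **higher-order spectral analysis** and is aimed at quantitative
ultrasound researchers who want a reproducible, fully synthetic-testable
implementation of the whole chain:

1. **Third-order cumulant and bispectrum of RF segments.** For a segment
   $x(n)$, $n = 1..N$,

   $$C_3(k, l) = \tfrac{1}{N} \textstyle\sum_n x(n)\,x(n+k)\,x(n+l),
   \qquad
   \mathrm{BS}(f_1, f_2) = \sum_k \sum_l C_3(k, l)\,
   e^{-j2\pi f_1 k} e^{-j2\pi f_2 l}.$$

   The bispectrum vanishes for Gaussian processes and peaks at
   quadratically phase-coupled bifrequency pairs — e.g. the second
   harmonic generated by nonlinear scattering.

2. **Frequency-subdivided band energies.** On the principal domain
   $S_0 = \{0 \le f_2 \le f_1,\ f_1 + f_2 \le 1/2\}$, the split axis is
   cut into three equal bands giving regions $S_1$ (low), $S_2$ (mid),
   $S_3$ (high); the four energies $E_{S_1}, E_{S_2}, E_{S_3}, E_{S_0}$
   (with $E_{S_1} + E_{S_2} + E_{S_3} = E_{S_0}$ exactly) computed over a
   sliding window tile each frame into four feature maps
   **BS_S1, BS_S2, BS_S3, BS_A**.

3. **A four-branch weight-sharing classifier.** All maps pass through one
   shared CNN backbone; gated attention
   $a = \mathrm{softmax}_k\, w^\top(\tanh(Vh_k) \odot \sigma(Uh_k))$
   fuses the pooled features $z = \sum_k a_k h_k$, a cosine-similarity
   constraint loss concentrates same-map-type embeddings around
   prototypes, and training follows Adam with cosine annealing
   (0.002 → 1e-4, batch 8). Weight sharing keeps **25.83%** of the
   parameter budget of four independent ResNet-50 branches.

4. **Evaluation**: confusion-matrix metrics (accuracy, sensitivity,
   specificity, PPV, NPV) and rank-based ROC/AUC.

A seeded nonlinear phantom simulator (point scatterers → Gaussian pulse →
memoryless quadratic distortion → calibrated noise) provides labeled
synthetic RF data whose classes differ in bispectral band energy, so every
stage — including end-to-end training — is testable without clinical data.

## Worked example

```r
library(bisqus)

params <- phantom_preset("malignant", n_samples = 1024, n_lines = 32)
frame  <- simulate_frame(params, seed = 7)
frame
#> <rf_frame 'sim_seed7'> 1024 samples x 32 lines, fs = 40 MHz, f0 = 5 MHz, label = malignant

hos  <- hos_config(window = 256, max_lag = 31, nfft = 64)
set  <- build_feature_maps(frame, map_geometry(window = 256, hop = 128), hos)
set
#> <feature_map_set 'sim_seed7'> 4 maps of 7 x 32 (window 256, hop 128), label = malignant

round(segment_features(frame$samples[1:256, 1], hos), 2)
#>     E_S1     E_S2     E_S3     E_S0
#> 11262.17   596.64     5.53 11864.34

pairwise_stats(set)
#> <map_stats_report>
#>   average MI vs other maps (bits):
#> BS_S1 BS_S2 BS_S3  BS_A
#> 4.027 3.719 3.532 4.056
#>   average RMSE vs other maps:
#>  BS_S1  BS_S2  BS_S3   BS_A
#> 14.474 15.340 33.035 14.096
```

The segment energies say most bispectral power of this segment sits in the
low band ($E_{S_1}$), with the partition identity
$E_{S_1}+E_{S_2}+E_{S_3}=E_{S_0}$ holding exactly. In the map statistics,
BS_S3's high average RMSE against the other maps marks the high-frequency
band as the most distinctive — that distinctiveness is exactly what the
malignant preset's stronger nonlinearity injects.

Parameter accounting for the full-scale architecture, and the
confusion-matrix arithmetic:

```r
cfg <- net_config("resnet50", K = 4, L = 256)
count_parameters(cfg)                                            # 24560962
count_parameters(net_config("resnet50", share_weights = FALSE))  # 95085058
shared_ratio(cfg)                                                # 25.83052

compute_metrics(confusion_counts(TP = 38, FN = 2, TN = 26, FP = 14))
#> <metrics_report>
#>   accuracy    80.00%
#>   sensitivity 95.00%
#>   specificity 65.00%
#>   PPV         73.08%
#>   NPV         92.86%
#>   counts: TP=38 FP=14 TN=26 FN=2
```

Training end to end on synthetic cohorts (a few minutes on one CPU):

```r
train <- synthetic_cohort(20, seed = 0)              # 20 frames per class
test  <- synthetic_cohort(10, seed = 0, offset = 500)
fit   <- train_msnet(train, train, net_config("tinycnn"),
                     train_config(max_epochs = 10, patience = 10, seed = 0))
pr    <- predict(fit, test)
roc_auc(pr$score, pr$label)$auc
importance_report(fit, test)   # mean attention weight per map
```

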