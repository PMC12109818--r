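# stentropy

Stockwell entropy + common spatial patterns (CSP) for multichannel EEG
emotion recognition, in R.

Emotional state leaves band- and channel-specific traces in EEG, but the
signal is non-stationary.  This package implements a feature-extraction
chain built for that setting: each 3-s epoch is decomposed with the
**Stockwell (S-)transform**

$$ S(\tau, f) = \int x(t)\, w(\tau - t)\, e^{-j 2 \pi f t}\, dt, $$

whose Gaussian window $w$ narrows as $f$ grows (fine time resolution in
the Gamma band, fine frequency resolution in Delta).  Coefficients are
grouped into six bands (full 0.1–46 Hz, Delta, Theta, Alpha, Beta,
Gamma 30–46 Hz) and each band series is converted to **Stockwell
entropy**: sliding windows of $k$ samples mapped through the Gaussian
differential entropy $\tfrac12 \log(2\pi e \sigma^2)$, giving a local
log-variance profile per channel and band.  **CSP** then solves the
generalized eigenproblem $C_a w = \lambda (C_a + C_b) w$ on the class
covariances of these entropy sequences and keeps the 4 + 4 most extreme
eigenvectors; per epoch the normalized log-variances of the 8 projected
components form the feature vector (24 features for three classes,
one-vs-rest).  An RBF-SVM (C = 20, "scale" gamma) or a random forest
(256 trees) is evaluated with stratified 5-fold cross-validation or a
stratified 80/20 holdout, with the CSP filters refitted inside every
training fold so they never see test data.

A synthetic module generates the full study environment — pure tones,
0–46 Hz chirps, amplitude ramps, and randomized 3-class, 62-channel,
200 Hz EEG emulations with band-limited class effects — so everything is
reproducible without any external recordings.  A simulation-study module
quantifies when Stockwell entropy is a *stable* feature: its standard
deviation across a pure tone's epoch collapses once the entropy window
spans a full signal cycle, which is why the Gamma band yields the most
reliable features at 200 Hz.

## Worked example

```r
library(stentropy)

# 24-channel synthetic dataset: Gamma-band variance x6 on 8 class-specific
# channels, 20 epochs per class
spec <- emotiveEEGSpec(nChannels = 24, nEpochsPerClass = 20,
                       effectGain = 6, seed = 1)
eps  <- makeEmotiveDataset(spec)
labs <- vapply(eps, epochLabel, numeric(1))

bs <- epochBandSeries(eps)   # S-transform + band grouping (the slow stage)

evaluateTask(bs, labs, band = "gamma", k = 20, task = c(1, -1),
             classifier = classifierSpec("svm_rbf"), seed = 1)
#> CVReport [svm_rbf]: task 1 vs -1, band gamma, k=20
#>   accuracy 1.000 +/- 0.000 over 5 fold(s): 1.000 1.000 1.000 1.000 1.000

evaluateTask(bs, labs, band = "delta", k = 20, task = c(1, -1),
             classifier = classifierSpec("svm_rbf"), seed = 1)
#> CVReport [svm_rbf]: task 1 vs -1, band delta, k=20
#>   accuracy 0.350 +/- 0.105 over 5 fold(s): 0.500 0.250 0.375 0.375 0.250
```

The class effect lives in the Gamma band, and the pipeline recovers it
there perfectly while the Delta band — which carries no class signal —
stays at chance.

The stability study behind that band ordering:

```r
buildStdGrid(frequencies = c(1, 8, 31, 45), windows = c(5, 20))
#>    band frequency std_w5 std_w20
#> 1 delta         1 16.630 13.6781
#> 2 alpha         8 11.372  1.8784
#> 3 gamma        31  2.507  0.2438
#> 4 gamma        45  0.929  0.0421
```

The entropy of a 1 Hz tone fluctuates wildly (std ≈ 16.6 at k = 5,
dB-style scale), while 41–45 Hz tones stay below 1 at every window
width: high-frequency Stockwell entropy is a stable, classification-
friendly feature.

A thin CLI wraps the same functions
(`Rscript inst/cli/stentropy.R synth|extract|classify|simstudy ...`).

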