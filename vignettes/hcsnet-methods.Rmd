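---
title: "Decoding lower-limb movements from surface EMG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding lower-limb movements from surface EMG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Surface electromyography (sEMG) measured over the leg muscles carries
information about an upcoming movement some tens to hundreds of
milliseconds before the limb moves. A human–robot interface for
rehabilitation exoskeletons can exploit this to predict whether the
wearer is about to stand, sit, or walk, using only the sEMG of the
unaffected leg of a hemiplegic patient. This package implements such a
decoder as a fused classifier:

* **hand-crafted features** — cheap, interpretable amplitude and
  spectral statistics with decades of use in myoelectric control;
* **learned channel-synergy features** — a compact recurrent/
  convolutional network that can pick up patterns the fixed features
  miss, in particular the coordination *across* muscles;
* **channel-attention fusion** — a learned gate that weights the two
  information sources per feature group before a linear softmax
  classifier.

The two single-source approaches fail in complementary ways: fixed
features generalize but saturate, deep networks overfit the very small
per-patient datasets typical of rehabilitation settings. Fusing them is
the core design idea.

# Signal path

1. **Acquisition model.** Trials are 12 s long at 1500 Hz with a go-cue
   at 4 s and 3 s of movement; five muscles of one leg are recorded
   (C = 5).
2. **Filtering.** A 50 Hz second-order IIR notch (quality factor
   Q = 30) removes mains interference and a 4th-order Butterworth
   band-pass keeps 10–450 Hz, the band where sEMG carries information.
   Both are applied forward–backward (zero phase), so windows are not
   shifted by group delay; the squared magnitude response makes the
   effective attenuation twice the design value in dB. The original
   acquisition description names only the center/edge frequencies;
   orders, the notch bandwidth and the zero-phase realization are this
   package's defaults, and all are configurable.
3. **Segmentation.** Only the first second after the cue is modelled
   (`onset_s = 4`, `keep_duration_s = 1`), sliced by protocol time, not
   by EMG onset detection. Sample ranges are half-open and 0-based:
   samples `[6000, 7500)` at 1500 Hz. Sliding windows of 300 samples
   with a 150-sample step (50 %) yield 9 windows per trial; both
   parameters are exposed and swept by `window_sweep()`.

# Hand-crafted features

Per channel and window of length $N$: MAV $= \frac1N\sum|x_i|$, SSI
$= \sum x_i^2$, WL $= \sum|x_{i+1}-x_i|$, RMS $= \sqrt{SSI/N}$, ZC and
SSC (threshold-gated sign/slope change counts, thresholds default 0
because no dead-band is specified for this montage), and a 6th-order
autoregressive model fitted by Yule–Walker on biased autocovariances
via Levinson–Durbin (deterministic, always stable, no demeaning since
the band-passed signal is zero-mean). Spectral features come from a
one-sided rectangular-window periodogram $P_j = |X_j|^2/N$ with the DC
bin included: MNP (mean of $P$), PKF (argmax bin) and MDF (first bin
reaching half the cumulative power). Ties in PKF/MDF break toward the
lowest frequency bin. No Welch averaging is used: the plain
periodogram is deterministic and exact for on-bin test sinusoids,
which keeps the feature contract testable.

One notational wrinkle: "7 time-domain features" that include a
6-vector of AR coefficients cannot produce a $7C$-dimensional block.
The default keeps all six coefficients ($F_{td} \in \mathbb{R}^{12C}$,
so 60 + 15 features for C = 5); `ar_scalar_mode` collapses the AR
block to its first coefficient to reproduce the $7C$ layout. Neither
convention is asserted to be the original authors' intent.

# Learned features

`build_mcsnet()` composes three stages, matching the
temporal → temporal-frequency → cross-channel synergy narrative:

1. **LSTM, channel by channel.** Each channel's window is framed into
   non-overlapping 15-sample steps (a 300-sample window becomes a
   20-step sequence of 15-vectors) and passed through a single shared
   LSTM (hidden size 16). Framing is a computational device: it
   shortens backpropagation through time ~20× on CPU while the
   recurrence still spans the whole window.
2. **Two temporal convolutions.** Kernel length 5 along the step axis,
   16 then 32 filters, each followed by ELU and average pooling
   (pool sizes 2 and 3). No batch normalization: with standardized
   inputs and these depths training is stable without it, and the
   model stays strictly deterministic per seed.
3. **Depthwise convolution across channels.** Per feature map, a
   filter spanning all C channels with multiplier 2 combines the
   per-muscle maps into synergy features; ELU, then global average
   pooling over time yields a 64-dimensional learned vector
   (`cnn2_filters × depthwise_multiplier`).

No layer sizes are prescribed by the source architecture description;
every size above is a package default chosen to balance capacity
against single-CPU training time, and each is exposed in
`mcsnet_config()`. The extractor applies no input normalization of its
own — that is deliberately the training pipeline's job (per-channel
z-scoring with training-split statistics), and a test documents that
scaling the input changes the output.

# Fusion and classification

The fused vector is the concatenation
$F_{fusion} = [F_{td}, F_{fd}, F_{learning}]$ (60 + 15 + 64 = 139 by
default). The channel-attention gate computes, per attention channel
$g$,

$$w_g = \sigma\big(\mathrm{MLP}(\mathrm{avg}_g) + \mathrm{MLP}(\mathrm{max}_g)\big),$$

with one shared two-layer MLP (bottleneck = groups / 4, ELU inside)
and multiplies every element of group $g$ by $w_g$. Two glosses were
needed where the formula is underdetermined on a flat vector:

* **What is a "channel"?** Default grouping: each sEMG channel's
  time-domain block, each sEMG channel's frequency-domain block, and
  each learned feature map — 5 + 5 + 64 = 74 groups. This keeps the
  average/max pooling non-degenerate while preserving per-muscle
  semantics. `flat_attention` treats every element as its own channel,
  in which case pooling degenerates to the identity.
* **The weighting operation.** A literal matrix multiplication of the
  weight vector with the feature vector is shape-inconsistent;
  the standard channel-attention reading — broadcast element-wise
  gating, which preserves the layout — is implemented.

A linear layer + softmax produces per-class probabilities; argmax ties
break toward the lowest class index.

**Training.** Adam at default hyperparameters (lr $10^{-3}$,
$\beta = (0.9, 0.999)$) minimizes categorical cross-entropy weighted
per class by inverse training proportion with the majority class at
weight 1 (on balanced data all weights are 1 and the loss reduces to
the unweighted one). Hand-crafted features enter the graph as
constants — gradients flow through the learned extractor, the
attention MLP and the head only, as a single end-to-end loss. After
every epoch the validation loss is computed and the weights of the
best epoch are kept (validation stopping); `patience`/`min_delta`
optionally stop a plateaued run early, without affecting which weights
are returned. All randomness (initialization, shuffling, dropout)
derives from one seed, so histories are exactly reproducible.

# Synthetic data

No public recordings exist for this acquisition protocol, so the
package ships a generator whose defaults *are* the study conditions:
10 subjects, 3 session blocks of 10 trials, 10 trials per class per
subject with standing/walking interleaved first and all sitting trials
last, 12 s trials at 1500 Hz, cue at 4 s, 5 channels.

The signal model per channel is amplitude-modulated bandlimited
Gaussian noise — the standard surrogate for interference-pattern
sEMG:

$$s_c(t) = g_c\,\mathrm{env}_c(t - t_{cue} - \delta)\,n_c(t) + \varepsilon_c(t) + m \sin(2\pi \cdot 50 t + \varphi),$$

with $n_c$ unit-variance noise band-limited to 20–450 Hz, class-specific
envelopes (standing: ramp-hold weighted toward knee extensors;
sitting: decaying activation weighted toward the posterior chain;
walking: ~1 Hz alternating bursts between antagonist groups), per-subject
log-normal channel gains $g_c$, onset jitter $\delta$, and a common-mode
50 Hz mains term so the notch stage is genuinely exercised. Baseline
noise is $\sigma = 0.05$ and mains amplitude $0.2$ against envelope
peaks of order 1; the source study does not characterize its subjects'
amplitudes or SNR, so these defaults were chosen once for testability,
not fidelity, and are documented rather than tuned.

What the generator does *not* emulate: motor-unit action potentials,
electrode shift, fatigue, paretic-limb signals, or any calibrated
microvolt scale. Passing tests on this surrogate therefore demonstrate
that the pipeline's machinery is correct and that the expected
qualitative orderings hold (within-subject above cross-subject,
accuracy growing with window length); they do not certify accuracy
levels on real patients.

# Evaluation protocols

* **Within-subject:** per subject, a stratified 70/30 split at the
  *trial* level (21/9 trials of 9 windows each), so windows of one
  trial never straddle the boundary; a stratified 4-fold assignment of
  the training trials is exposed for model selection. The
  validation-stopping set for the fused model is a trial-grouped 20 %
  of the training trials — using the test 30 % for stopping would
  leak.
* **Cross-subject:** five seeded repeats of a disjoint 7-train /
  3-test subject partition. The original design uses the held-out
  subjects as both stopping and reporting set; the default here avoids
  that leakage by carving the stopping set from the training subjects,
  and `paper_protocol = TRUE` reproduces the literal design.
* Accuracy is per window (`--vote trial`-style majority voting is
  deliberately out of scope); reports carry per-unit accuracies,
  confusion matrices and every seed used.
* Baselines (LDA, RBF-SVM, KNN, random forest) consume the same
  standardized hand-crafted features. Their hyperparameters are not
  specified by the source; defaults are C = 1, $\gamma = 1/d$ on
  standardized features, K = 5, 100 trees, all exposed.

# Numerical choices and degenerate inputs

* Filters per channel, independently; channel permutation commutes
  with filtering (tested).
* Zero-variance windows return all-zero AR coefficients; zero-power
  spectra return MNP = PKF = MDF = 0.
* Features with zero training variance get unit scale in the
  z-scoring (no division by zero).
* KNN vote ties are resolved under a stored seed so evaluation
  reports are byte-reproducible.
* The problem sizes used in the shipped tests and the acceptance
  script — the full 10-subject default dataset, training capped at
  100 epochs with patience 10 and `min_delta` $10^{-3}$ — were chosen
  so a complete within- plus cross-subject comparison runs on a single
  CPU in minutes; validation stopping typically ends training well
  before the cap.

# Known limitations

* The learned extractor is intentionally small; it is not a faithful
  reproduction of any published network's hyperparameters.
* The synthetic classes are more separable than real patient data;
  absolute accuracies here should not be compared with clinical
  results.
* GoogleNet/ResNet-style image-network comparators and real device
  integration are out of scope.
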