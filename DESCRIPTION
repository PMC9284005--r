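Package: hcsnet
Title: Lower-Limb Movement Prediction from Surface EMG by Fusing
    Hand-Crafted and Channel-Synergy Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding lower-limb movements (standing, sitting,
    walking) from multi-channel surface electromyography (sEMG), built
    around a fused classifier that combines classical time- and
    frequency-domain EMG features (MAV, SSI, WL, RMS, ZC, SSC, 6th-order
    AR coefficients, MNP, PKF, MDF) with features learned by a compact
    LSTM / convolutional / depthwise-convolutional network, merged
    through a channel-attention gate. Includes a synthetic multi-subject
    sEMG generator with class-specific per-muscle activation envelopes,
    zero-phase notch and band-pass preprocessing, sliding-window
    segmentation, classical baselines (LDA, RBF-SVM, KNN, random
    forest), and within-subject and cross-subject evaluation protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    data.table,
    e1071,
    jsonlite,
    MASS,
    randomForest,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
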