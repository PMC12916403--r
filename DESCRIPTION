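Package: ppg2ecg
Title: PPG-to-ECG Translation with a Pretext-Pretrained Wasserstein GAN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-modal translation of photoplethysmogram (PPG)
    signals into single-lead electrocardiogram (ECG) waveforms. Provides a
    synthetic paired PPG/ECG cohort simulator with ground-truth R peaks, the
    full preprocessing chain (alignment, cubic-spline resampling, zero-phase
    band-pass and median filtering, overlapped segmentation, invertible
    person-specific min-max normalization), six self-supervised signal
    transformation pretext tasks, a 1-D UNet generator with a Transformer
    bottleneck and a Transformer critic trained under the Wasserstein
    objective with gradient penalty, leave-one-subject-out evaluation (RMSE,
    discrete Frechet distance, Pearson correlation, heart-rate MAE via
    Pan-Tompkins and systolic-peak detection), kernel and energy two-sample
    tests on critic embeddings, and an atrial-fibrillation downstream
    harness with baseline-fluctuation spectral analysis. Includes a small
    reverse-mode automatic differentiation engine supporting differentiation
    through gradients, used to train all models on CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
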