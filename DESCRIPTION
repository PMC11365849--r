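Package: msanomaly
Title: Self-Supervised Anomaly Classification for Maxillary Sinus Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Residual-guided self-supervised learning for classifying normal
    versus anomalous maxillary-sinus (MS) volumes in 3D MRI. A 3D convolutional
    autoencoder is trained on normal MS volumes only (unsupervised anomaly
    detection); its voxel-wise reconstruction residuals on an unlabelled pool
    serve as pseudo segmentation masks for pretraining a skip-connected
    encoder-decoder, whose encoder is then fine-tuned as a normal-vs-anomalous
    classifier. Includes a synthetic sinus-phantom generator with ground-truth
    lesion masks, NIfTI preprocessing (centroid crop, laterality flip, min-max
    normalization, patient-grouped cross-validation splits), the network
    builders and training loops (with a small reverse-mode autodiff over
    hand-written 3D convolution kernels), AUROC/AUPRC/F1 evaluation with
    fold-aggregated confidence intervals, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
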