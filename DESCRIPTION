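Package: bowaves
Title: Bag-of-Waves Classification of Long-Term Single-Channel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Interpretable classification of long-term single-channel EEG
    recordings via bag-of-waves features. Learns per-class waveform
    dictionaries with shift-invariant k-means under cosine-similarity
    assignment, encodes recording segments as waveform occurrence counts
    with TFIDF weighting, and classifies individuals with regularized
    logistic regression under a leave-one-individual-out protocol with
    nested cross-validation, including factorized strain-then-genotype
    prediction. Provides corrected resampled t confidence intervals,
    merged ROC/AUC summaries, linear-model Shapley values and average
    class-signed Shapley values for waveform interpretation, Welch
    spectra of learned waveforms, and a synthetic EEG cohort generator
    with planted waveforms for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
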