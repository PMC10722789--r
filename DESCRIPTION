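Package: dyadscreen
Title: Caregiver-Child Interaction Screening Analysis for Autism Spectrum Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing micro-coded caregiver-child free-play sessions as a
    screening instrument for autism spectrum disorder (ASD). Reads and validates
    second-resolution behavioral annotations, rasterizes them to 1-s frames, segments
    attributed interaction episodes, and computes five interaction indicators (SIC, IT,
    RSC, GIS, CIS). Preprocesses simultaneously recorded child EEG (zero-phase bandpass
    and notch filtering, peripheral-channel exclusion, bad-channel interpolation, epoch
    rejection, blink regression, mastoid re-referencing) and computes one-sided FFT power
    spectral density with theta (4-7 Hz) and alpha (8-13 Hz) band summaries. Provides the
    statistical machinery for group comparisons (ANOVA and sex-adjusted linear models),
    partial Pearson correlations, Bonferroni adjustment, and ROC screening accuracy with
    Youden-optimal cutoffs, plus a calibrated latent-trait generator that simulates dyadic
    interaction event streams and multichannel EEG with matched group-level structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    pROC,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
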