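Package: stutterPCA
Title: Stuttered-Speech Disfluency Recognition via One-Third-Octave
    Spectral Analysis and PCA Residual-Distance Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for recognising three stuttering disfluencies (blocks,
    syllable repetitions, sound-initial prolongations) against fluent
    speech from short mono recordings.  A psychoacoustic front-end turns a
    4-second 22,050 Hz utterance into a 171 x 21 matrix of A-weighted
    one-third-octave band levels (512-point FFT frames, ~23 ms).  A
    per-utterance principal component analysis on the band correlation
    matrix, with joint Kaiser-Guttman / cumulative-variance component
    selection, yields a 171-long vector of reconstruction residual
    distances (a Q/SPE-style statistic) used as the classification
    feature.  A 5 x 5 Kohonen self-organising map provides the baseline
    feature extractor, and a 171-8-4 multilayer perceptron trained with
    BFGS under cross-entropy performs the four-class recognition.  A
    seeded synthetic-speech generator emulates the acoustic signatures of
    each class so the whole chain is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'frontend.R'
    'mlp.R'
    'pca.R'
    'pipeline.R'
    'som.R'
    'stutterPCA-package.R'
    'synthesize.R'
    'utils.R'
    'wav.R'
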