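Package: pdvoice
Title: Telephone-Quality Sustained-Vowel Dysphonia Analysis for Parkinson's Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify vocal impairment from telephone-quality
    sustained vowel /a/ phonations and to differentiate people with
    Parkinson's disease from controls. Provides a synthetic phonation
    generator with known jitter, shimmer and aspiration-noise ground truth
    and a standard-telephone-network channel model; automated quality
    screening and most-stationary 2 s segment selection; a sawtooth-inspired
    spectral-matching fundamental-frequency estimator on a 10 ms grid with
    cycle-level period and amplitude extraction; a 304-measure dysphonia
    battery in 13 families (jitter and shimmer variants, HNR/NHR, glottis
    quotient, GNE, VFER, EMD excitation ratios, MFCCs, normative F0
    comparisons, wavelet contour statistics, PPE, DFA, RPDE); margin-based
    feature ranking (Gram-Schmidt orthogonalization, ReliefF, SIMBA) with
    cross-validated vote aggregation and a principal-component alternative;
    and a balanced-training / unbalanced-held-out evaluation protocol with
    radial-basis-function support vector machines, random forests and
    AdaBoost.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    randomForest,
    rpart,
    signal,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
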