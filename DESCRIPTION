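Package: segmint
Title: Soft-Clustering Segmentation of Older Public-Assistance Recipients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments older public-assistance recipients from categorical
    welfare-office records by probabilistic latent semantic analysis (PLSA),
    a soft-clustering method fitted with the EM algorithm. Provides a
    calibrated synthetic roster generator with a known latent-segment ground
    truth, one-hot co-occurrence encoding of the 13 categorical variables,
    multi-restart EM fitting, AIC/BIC model-number selection with
    cluster-size screening, affiliation-probability cluster profiles,
    Table-1-style descriptive summaries with median income/pension banding,
    and the mixed-methods concordance joint display. Analyses are stratified
    by sex throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
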