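Package: pairswim
Title: Burst-and-Coast and Recurrent Probabilistic Models of Pairwise Fish Swimming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative models of pairwise social interactions in fish confined
    to a circular tank, and the observable suite used to validate them. Provides
    an asynchronous analytical burst-and-coast simulator with configurable wall
    and social interaction kernels, a probabilistic recurrent (LSTM) interaction
    model with a diagonal-Gaussian acceleration head trained by maximum
    likelihood, trajectory preprocessing (inactivity and tracking-leap filters,
    gap interpolation, decimation, normalization), a nine-observable validation
    methodology (six probability density functions, three temporal correlation
    functions) and Hellinger-distance scoring of one model dataset against a
    reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
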