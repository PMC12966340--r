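Package: prevcommon
Title: Unsupervised Species Commonness Classification and Prevalence Priors from Occurrence Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts raw species occurrence records into commonness classes
    (rare, fairly common, very common) and prevalence probabilities suitable
    as priors for Bayesian ecological niche models. Six aggregative features
    (abundance, intra- and inter-dataset abundance, spatial extent,
    observation frequency and high-observation frequency) are computed per
    species over a set of area polygons, a grid resolution and a time frame.
    Three parallel unsupervised models -- a multi-K K-means sweep selected by
    a chi-squared cluster-size uniformity criterion, an X-means-style sweep
    selected by the Bayesian Information Criterion, and a variational
    autoencoder scored by reconstruction probability -- are classified via
    quartile-based centroid labelling and combined into a majority ensemble.
    Includes an agreement harness (accuracy, Cohen's kappa, leave-one-out
    feature sensitivity) and a synthetic occurrence-data generator with
    planted commonness tiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
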