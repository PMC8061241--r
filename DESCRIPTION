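Package: distressnet
Title: Data-Driven Subtyping of Psychological Distress via Semi-Parametric Symptom Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters respondents of ordinal symptom questionnaires (such as the
    ten-item Kessler Psychological Distress Scale) by their per-person
    covariation around item grand means using k-means, then estimates a
    semi-parametric Gaussian-copula (nonparanormal) partial-correlation
    network within each cluster via an EBIC-tuned graphical lasso, and
    compares clusters on node centrality (strength, closeness, betweenness),
    network density and connectivity, including pairwise Kolmogorov-Smirnov
    tests of centrality distributions. Ships a latent-Gaussian threshold
    simulator of cluster-structured Likert data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
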