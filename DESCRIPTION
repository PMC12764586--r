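Package: hictad
Title: Topologically Associating Domain Calling from Hi-C Contact Maps via
    Graph Embedding and Density Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls topologically associating domains (TADs) from
    single-chromosome Hi-C contact matrices. The contact map is split into
    overlapping sub-matrices, smoothed with a Gaussian filter, converted to a
    weighted graph, embedded with the closed-form NetMF factorization of the
    DeepWalk matrix, and clustered with HDBSCAN; overlapping calls in the
    sub-matrix overlap regions are reconciled with a TAD-quality score.
    Includes evaluation statistics (measure of concordance, adjusted R-squared
    of contact variance by domain, boundary signal profiles, recovery rate,
    split/merge event classification) and a synthetic Hi-C generator with
    known ground-truth domains for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
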