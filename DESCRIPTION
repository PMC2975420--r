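Package: airnet
Title: Asynchronous Inference of Gene Regulatory Networks from Expression Data
Version: 0.1.0
Authors@R:
    person("AIRnet", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers signed, undirected gene regulatory networks from
    unsynchronized expression samples (e.g. microarrays) by discretizing each
    gene's profile with exact 1-D k-means, tallying change-correlation votes
    over all pairs of samples, and pruning the resulting weighted graph with a
    thresholded Kruskal procedure. Includes DREAM-style evaluation against
    gold-standard edge lists (AUROC/AUPR with empirical random-network
    p-values and a combined log-transformed score), differential comparison of
    two inferred networks, a synthetic-study simulator with known ground
    truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
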