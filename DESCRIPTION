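Package: focs
Title: Fast Optimized Community Significance Scoring for Networks
Version: 1.0.0
Authors@R:
    person("FOCS", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Statistical significance scoring for individual, already-optimized
    communities in unipartite and bipartite networks. Implements the
    community-conditional hypergeometric null model, a stochastic continuity
    correction that yields exactly uniform discrete p-values under the null,
    the minimum-order-statistic significance score, and the iterative
    worst-node scoring algorithm (FOCS). Includes configuration-model and
    planted-partition network generators, a null-calibration and power
    simulation harness, and a command-line interface for scoring community
    membership files against edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
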