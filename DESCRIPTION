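Package: silocate
Title: Source Localisation for Susceptible-Infected Spreading on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates synchronous Susceptible-Infected (SI) spreading on
    complex networks, places a budget of observer nodes by betweenness
    centrality, greedy coverage, path-covering or at random, and estimates
    the epidemic source from observer arrival times with five localisation
    algorithms (LPTV, TRBS, Pearson correlation, GMLA, EPL). Includes a
    benchmarking layer computing precision and the credible set size
    CSS_alpha over repeated realisations, generators for Barabasi-Albert
    and Erdos-Renyi graphs, and an edge-list reader for empirical networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
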