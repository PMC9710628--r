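Package: litnetext
Title: Literature-Driven Extension of Causal Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extends discrete causal and dynamic network models of intracellular
    signaling with events extracted from the literature by machine reading.
    Distinct extracted events are assembled into a weighted undirected event
    collaboration graph whose nodes are scored by an occurrence frequency class
    and whose edges are scored by co-occurrence frequency class and a weighted
    inverse-frequency metric. The graph is filtered, partitioned into
    communities by weighted-modularity (Louvain) optimization, and clusters are
    selected for model extension by literature support (best average pair
    scores) or by model support (node overlap with the baseline model plus
    return paths). Includes BioRECIPES-style model table I/O, a synthetic
    reading-output generator with planted co-occurrence communities for
    benchmarking, and precision/recall evaluation against a gold-standard
    model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
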