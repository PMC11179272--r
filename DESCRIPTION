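Package: pathminer
Title: Chemical-Structure-Based Mining of Enzymatic Bypass Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrobiosynthetic pathway prediction from count-vector chemistry.
    Molecules are featurized as integer count vectors over atom classes and
    bond types, known enzymatic reactions become additive delta vectors, and
    candidate multi-step pathways between a source and a target compound are
    found by exact integer enumeration of delta combinations, ordered into
    step sequences with matched (known or putative) intermediates, and ranked
    by average Tanimoto similarity against the known reactions they mimic.
    Includes a packaged demonstration knowledge base around the
    arylacetaldoxime bypass from L-DOPA to 3,4-dihydroxyphenylacetaldehyde,
    monoisotopic and nominal m/z utilities for MS-based intermediate
    identification, double-bond E/Z isomer counting, and enzyme-screening
    helpers (ortholog thresholding, neighbor-joining phylogeny, Kyte-Doolittle
    hydropathy scanning and N-terminal truncation design for P450s).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
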