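Package: densepack
Title: Optimal Packing of DNA-Protein Binding Sites into Dense Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs nucleotide sequences of a fixed length that contain as
    many DNA-protein binding sites as possible, allowing sites to overlap and
    to appear on either strand. The packing task is reduced to an Orienteering
    Problem over an overlap graph with an integer shift metric and solved as
    an integer linear program (Miller-Tucker-Zemlin formulation) through the
    GLPK solver. Extensions cover enumeration of distinct optimal sequences,
    diversity-driven reweighting of the objective to balance binding-site
    usage, fixed promoter elements with start windows and spacer constraints
    (e.g. bacterial -35/-10 sigma factor sites), and upstream/downstream
    positional biases. Includes a greedy merge baseline, brute-force
    reference searches for validation, and seeded generators of random
    binding-site collections.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    seqinr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan
VignetteBuilder: knitr
SystemRequirements: GLPK (the glpsol executable on the PATH)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
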