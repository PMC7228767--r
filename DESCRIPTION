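Package: retconn
Title: Connectomic Analysis of Annotated EM Skeletons in the Retinal Inner
    Plexiform Layer
Version: 0.1.0
Authors@R:
    person("Maintainer", "retconn", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative connectomics of manually traced neurite
    skeletons from serial block-face electron microscopy volumes of retina.
    Reads and writes Knossos/webKnossos NML skeleton files with synapse
    annotations encoded in node comments; fits the ON and OFF starburst
    amacrine cell (SAC/ChAT) dendritic planes and normalizes positions to
    IPL depth; builds typed synapse tables with input/output tallies,
    convergence and dyad statistics; computes nearest-neighbour synapse
    distances, stratification-depth profiles and a depth-based ON cone
    bipolar subtype classifier; and generates seeded synthetic skeleton
    volumes with ground truth for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
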