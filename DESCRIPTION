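Package: linkerhist
Title: Identification of Linker Histones Among GH1-Domain Proteins and
    Population Genetics of Their Genes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to identify true linker histones (H1) among
    GH1-domain-containing proteins using structural criteria (tripartite
    NTD-GH1-CTD partition, conserved basic DNA-binding sites in the
    globular domain, lysine-rich C-terminal tail with evenly distributed
    positive charge), and to quantify within-species diversity and
    selection at the corresponding genes (nucleotide diversity by site
    class, Watterson's theta, Tajima's D, SNP/indel density, and a
    maximum-likelihood HKA likelihood-ratio test).  Includes
    neighbor-joining tree construction, distance-based variant
    nomenclature, synthetic-data generators (planted proteomes, neutral
    coalescent samples, Poisson HKA counts) so every stage is testable
    without external data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
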