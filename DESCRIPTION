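Package: ddcaccess
Title: Hierarchical Access to Data Encoded on Reconfigurable DNA Domino-Array Carriers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models a molecular data-management system in which messages are
    stored as biotin/streptavidin label patterns on reconfigurable DNA origami
    domino-array carriers and released by conformational transformation.
    Provides a text codec with address-bit scrambling and blank-column spacing,
    a geometric carrier model with OFF/ON/intermediate conformations,
    admin (polymerase, one-to-many) and user (strand-set, one-to-one) key
    semantics with scaffold-breakpoint key-space enumeration and k-mer
    cross-hybridization screening, a stochastic streptavidin-binding readout
    simulator with localization noise, an observation-side decoder
    (conformation classification, lattice registration, bit calling), and
    yield statistics including the experimental yield M/N and the theoretical
    correct-information yield p * q^n.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
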