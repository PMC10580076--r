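Package: gatekit
Title: Golden Gate Assembly Simulation and Construct Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: In-silico toolkit for Golden Gate cloning with type IIS
    restriction enzymes (SapI, BsaI). Simulates digestion of circular and
    linear DNA into sticky-ended fragments, predicts the unique circular
    ligation product of a one-pot digestion-ligation reaction including
    multiplexed reactions, implements a slot-based construct builder over a
    parts registry with annotated GenBank output, designs enzyme-tailed
    primer pairs and annealed-oligo duplexes for new entry clones, plans
    domestication (silent removal of internal recognition sites), and
    generates deterministic synthetic fixture kits. Ships a command-line
    entry point over the same functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
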