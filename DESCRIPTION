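Package: pvalbid
Title: Gene-Identity Assignment and Allergen Nomenclature for Fish
    Parvalbumins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies teleost parvalbumin protein sequences into the
    three ancient parvalbumin lineages (Alpha, Oncomodulin, Beta-2) and
    the ten ancestral gene families (pvalb1 to pvalb10) using diagnostic
    residues on a 109-position canonical frame, pairwise percent
    identity against a curated reference panel, and synteny context.
    Includes a translated-similarity locus finder for genomic scaffolds,
    sliding-window detection of hybrid (recombinant) genes, gene-naming
    conventions for tandem and whole-genome-duplication copies and
    pseudogenes, a WHO/IUIS allergen-code parser with isoallergen and
    variant identity thresholds, and seeded synthetic-data generators
    for benchmarking every component.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
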