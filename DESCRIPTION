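Package: chaperscreen
Title: Co-Enrichment Screening of Tandem-Affinity Purifications for
    Dedicated Ribosomal Protein Chaperones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for label-free affinity-purification mass
    spectrometry screens that look for proteins specifically co-enriched
    with individual bait proteins, as used to discover dedicated chaperones
    of ribosomal proteins. Implements per-purification relative-intensity
    normalization with zero replacement, group-ordered heat-map matrices,
    per-bait enrichment against an outlier-excluded panel mean with
    candidate ranking, a bait-excluded normalization for split-tag
    purification comparisons, and a two-way (per-purification and
    per-amplicon) background normalization of qRT-PCR starting
    concentrations used to call co-translational chaperone-mRNA
    association. Seeded synthetic-data generators with planted ground
    truth exercise every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
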