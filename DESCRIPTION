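Package: neogfs
Title: Gene Family Size Evolution and Relative Neocortex Expansion in Mammals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative-genomics pipeline relating per-species gene family
    sizes to mammalian brain phenotypes, in particular the neocortex ratio
    (neocortex volume over rest-of-brain volume). Provides phenotype index
    computation, per-family Pearson associations with Monte-Carlo permutation
    nulls and a Z-score distribution-shift test, confound-corrected
    phylogenetically independent contrasts with correlations forced through
    the origin, annotation-density-adjusted resampling enrichment over
    GO-style terms, a developmental expression contrast around full cortical
    maturation, and seeded synthetic-data generators with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
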