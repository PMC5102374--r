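Package: euplotia
Title: Character Evolution, Biogeography and Morphospecies Identification
    in the Ciliate Genus Euplotes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parsimony ancestral-state reconstruction on rooted, possibly
    multifurcating phylogenies (Hartigan/Fitch set operations and Sankoff
    dynamic programming with arbitrary cost matrices), enumeration of
    most-parsimonious reconstructions, and min-max counting of character
    change events, specific transitions and independent origins.  Applies
    the machinery to the SSU rRNA phylogeny of the hypotrich ciliate genus
    Euplotes: evolution of the dorsal argyrome type and frontoventral
    cirral pattern, salinity-class biogeography (freshwater, brackish,
    marine, hypersaline habitats) and polar-invasion counting, a
    trait-range identification key for Euplotes morphospecies, an
    alignment end-trimming rule, and seeded simulators (Yule trees,
    Markov-evolved categorical characters with known true histories,
    specimen measurements) so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    phangorn,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
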