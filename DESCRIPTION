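Package: radploid
Title: Subgenome SNP Classification and Hybridization Detection for
    Allopolyploid RAD-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the origin of allopolyploid taxa from
    restriction-site-associated DNA (RAD) sequencing data.  Builds a
    concatenated pseudo-reference from one diploid parent's consensus RAD
    loci, classifies every SNP of an allotetraploid relative to two putative
    diploid parents into interspecific (cat 1/2), post-origin derived
    (cat 3/4), homeologous (cat 5) and uncategorised classes, estimates the
    admixture proportion gamma for (parent, hybrid, parent, outgroup)
    quartets from polarized site patterns with significance filtering and
    gamma-range event classification, and collapses polyploid allele calls
    to a diploid consensus for genetic-structure input.  A synthetic
    allopolyploid RAD-data generator with ground-truth site categories and
    quartet admixture proportions makes every stage testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
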