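Package: polydonor
Title: Genome-Donor Identification for Allopolyploids from Multi-Allelic
    SSR Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify the diploid genome donors of an allotetraploid
    species from co-dominant SSR (microsatellite) genotypes. Provides EST-SSR
    mining (perfect and imperfect tandem repeats with motif-family
    canonicalization), marker-quality classification, reference-anchored
    partitioning of tetraploid PCR products into homoeologous sub-genomes,
    multi-allelic diversity statistics (gene diversity, observed
    heterozygosity, polymorphic information content, rarefied allelic
    richness), Nei's DA genetic distance, neighbor-joining trees with locus
    bootstrap support, principal coordinate analysis, a donor-call report,
    and a seeded population simulator that generates selfing diploid and
    amphidiploid genotype tables with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
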