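Package: karyodelim
Title: Species Delimitation from Combined Karyotypes and DNA Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delimiting cryptic species by the combined analysis of
    chromosomal and mitochondrial markers. Summarizes haploid chromosome
    counts and marker-bivalent structures per putative taxon, clusters COI
    barcodes into haplogroups by p-distance, detects fixed diagnostic
    substitutions, tests for species-like stable karyotype-haplogroup
    combinations in sympatry with a G-statistic permutation test, applies
    fixed-difference criteria in allopatry, and emits species, subspecies
    and synonymy verdicts. Includes a seeded generator of synthetic
    cryptic-species-complex datasets (with optional mitochondrial
    introgression) so the whole pipeline runs at desk scale, and a
    transcription of the karyotyped-sample table of a Polyommatus ripartii
    complex study as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
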