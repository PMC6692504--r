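Package: matsys
Title: Mating Compatibility Systems of Budding Yeasts from Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies budding-yeast genome assemblies into seven
    mating-compatibility systems (HET, 3LOC, FF1, FF2, PHC, PHN, NOMAT)
    from their MAT-gene content, the repeat structure around MAT-like
    loci, and genomic context (telomeres, rDNA, contig coverage), then
    reconstructs ancestral states on a species phylogeny by parsimony and
    counts evolutionary transitions between systems and independent
    origins of mating-type switching. Includes a six-frame translated
    homology search, detectors for inverted/direct repeats, telomeric
    tandem arrays and assembler-collapsed repeat contigs, a synthetic
    genome generator that plants each of the seven configurations with
    ground-truth annotations, and transcribed per-clade phylogenetic
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
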