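Package: mitoprofile
Title: Characterisation of Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for the molecular characterisation of
    vertebrate mitochondrial genomes, built around the analyses commonly
    reported for newly sequenced mitogenomes: base composition and AT/GC
    strand skews per genomic partition, CpG-island scanning, molecular
    weight, codon usage of the 13 protein-coding genes under the vertebrate
    mitochondrial code with RSCU, effective number of codons (ENc), codon
    bias index (CBI) and GC3s, detection of simple sequence repeats, tandem
    arrays, short inverted repeats, palindromes and stem-loop hairpins,
    annotation of the control region (ETAS, central conserved and CSB
    domains with their conserved elements), variant calling and diversity
    statistics (pi, haplotype diversity, conservation index) from multiple
    alignments of conspecific mitogenomes, haplotype networks, and
    distance-based phylogenetics (p and TN93 distances, neighbour joining
    with bootstrap supports). A deterministic synthetic mitogenome and
    haplotype simulator with recorded ground truth makes every stage
    testable without external sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    rtracklayer
Config/testthat/edition: 3
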