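Package: hybdiag
Title: Diagnostic-Locus Detection and Classification of Natural Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-locus molecular diagnosis of natural hybridization in
    polyploid, apomictic plant complexes. Detects fixed nucleotide
    substitutions and fixed indels between two parental taxa from aligned
    population samples of IUPAC-coded consensus sequences, scores putative
    hybrids for chromatogram additivity at those diagnostic sites, phases
    heterozygous genotypes into haplotype pairs by parsimony anchoring to
    parental references, classifies individuals as parental, F1 or
    backcross, assigns the maternal parent from chloroplast haplotypes,
    assesses clonality (apomictic single origin), builds median-joining
    haplotype networks with fifth-state indel coding, and infers ploidy
    from flow-cytometry fluorescence streams against an internal standard.
    Includes a seeded synthetic-data generator emulating the full study
    design and a bundled diagnostic-site dataset for the Cotoneaster
    dielsianus x C. glaucophyllus hybrid system.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
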