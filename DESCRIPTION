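Package: orscan
Title: Olfactory Receptor Repertoire Annotation from Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates olfactory receptor (OR) gene repertoires in fish genome
    assemblies: translated six-frame homology search of OR protein queries with
    Karlin-Altschul E-value filtering, single-exon gene-model construction and
    three-way classification (functional, partial, pseudogene), transmembrane
    and N-glycosylation sequon annotation, chromosomal cluster and tandem
    duplication analysis, ZOOPS expectation-maximization motif discovery, and
    neighbor-joining group classification against labelled references. Ships a
    synthetic-genome simulator with planted ground truth so every stage can be
    benchmarked without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
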