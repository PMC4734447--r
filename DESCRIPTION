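Package: GenomicTaxonomy
Title: Whole-Genome Taxonomy and Phylogenomics for Prokaryote Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-based taxonomy and phylogenomics for prokaryote genome
    sets. Implements fragment-based average nucleotide identity (ANI),
    reciprocal-best-hit average amino acid identity (AAI), Karlin
    dinucleotide relative-abundance signatures and the delta distance,
    in-silico DNA-DNA hybridization estimates, 16S rRNA and multi-locus
    (MLSA) marker identity, Markov clustering (MCL) of the all-vs-all
    protein similarity graph into homolog groups with core/pan/orphan
    partitioning, and concatenated single-copy-core phylogenomic
    reconstruction (progressive alignment, codon back-translation,
    Tajima-Nei distances, neighbor-joining, bootstrap supports).
    Includes a seeded genome-evolution simulator producing synthetic
    genome/proteome sets with known divergence for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    Matrix,
    igraph,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'GenomicTaxonomy-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'seqio.R'
    'alignkern.R'
    'aaicalc.R'
    'accessors.R'
    'anicalc.R'
    'ddhest.R'
    'dinucsig.R'
    'classify.R'
    'phylogeny.R'
    'markers.R'
    'pangenome.R'
    'simgen.R'
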