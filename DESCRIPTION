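Package: homanno
Title: Homology-Based Gene Annotation from Spliced Protein Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds non-redundant protein-coding gene models for a genome from
    spliced protein-to-genome alignments (miniprot-style GFF3). Alignment chains
    are filtered by identity, clustered into strand-aware loci, and assembled
    into pseudo-transcripts with an exact transcript-to-genome coordinate map.
    Candidate open reading frames are scored with a self-trained frame-periodic
    hexamer Markov log-odds model, projected back to genome coordinates,
    split where a locus harbours several genes, filtered, deduplicated and
    written as GFF3 together with CDS and protein FASTA. Also provides
    gene-model summary statistics, base-level sensitivity/specificity/F1
    evaluation between annotations, and a synthetic-fixture generator that
    plants multi-exon genes (GT-AG introns) in simulated genomes and emits
    matching homolog proteins and miniprot-like alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
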