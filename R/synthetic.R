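# Synthetic fixture generation: genomes with planted multi-exon genes
# (GT-AG introns, codon-usage-biased CDS), divergence-mutated homolog
# proteins, and miniprot-like alignment GFF3 derived from the truth — so the
# whole pipeline is testable with no external data.

# Vertebrate-like codon usage (relative weights per sense codon). Sampling
# codons from this table gives planted CDS a hexamer composition clearly
# distinct from the GC-matched iid intergenic background, which is what the
# coding-potential model keys on.
.CODON_USAGE <- c(
  TTT = 17.6, TTC = 20.3, TTA =  7.7, TTG = 12.9,
  CTT = 13.2, CTC = 19.6, CTA =  7.2, CTG = 39.6,
  ATT = 16.0, ATC = 20.8, ATA =  7.5, ATG = 22.0,
  GTT = 11.0, GTC = 14.5, GTA =  7.1, GTG = 28.1,
  TCT = 15.2, TCC = 17.7, TCA = 12.2, TCG =  4.4,
  CCT = 17.5, CCC = 19.8, CCA = 16.9, CCG =  6.9,
  ACT = 13.1, ACC = 18.9, ACA = 15.1, ACG =  6.1,
  GCT = 18.4, GCC = 27.7, GCA = 15.8, GCG =  7.4,
  TAT = 12.2, TAC = 15.3, CAT = 10.9, CAC = 15.1,
  CAA = 12.3, CAG = 34.2, AAT = 17.0, AAC = 19.1,
  AAA = 24.4, AAG = 31.9, GAT = 21.8, GAC = 25.1,
  GAA = 29.0, GAG = 39.6, TGT = 10.6, TGC = 12.6,
  TGG = 13.2, CGT =  4.5, CGC = 10.4, CGA =  6.2,
  CGG = 11.4, AGT = 12.1, AGC = 19.5, AGA = 12.2,
  AGG = 12.0, GGT = 10.8, GGC = 22.2, GGA = 16.5,
  GGG = 16.5)

.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Specification of a synthetic annotation fixture
#'
#' Defaults emulate a compact vertebrate-like genome: 4-8 exons per gene of
#' 100-300 bp, introns of 60-500 bp, at least 1 kb of intergenic spacing,
#' genome GC 0.41. All randomness flows from the single `seed`.
#'
#' @param n_contigs number of contigs.
#' @param contig_length length of each contig (bp).
#' @param n_genes total genes planted across contigs.
#' @param exons_per_gene integer range `c(min, max)`.
#' @param exon_length bp range `c(min, max)` per exon.
#' @param intron_length bp range `c(min, max)` per intron.
#' @param intergenic_min minimum spacing between genes and to contig ends (bp).
#' @param gc genome background GC fraction.
#' @param protein_divergence per-site substitution rate for homolog proteins.
#' @param alignment_identity_noise sd of Gaussian noise on reported identity.
#' @param seed integer seed driving all randomness.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_contigs = 2L, contig_length = 200000L,
                           n_genes = 20L, exons_per_gene = c(4L, 8L),
                           exon_length = c(100L, 300L),
                           intron_length = c(60L, 500L),
                           intergenic_min = 1000L, gc = 0.41,
                           protein_divergence = 0,
                           alignment_identity_noise = 0.01, seed = 1L) {
  stopifnot(n_contigs >= 1L, contig_length > 0L, n_genes >= 1L,
            length(exons_per_gene) == 2L, exons_per_gene[1L] >= 1L,
            exons_per_gene[2L] >= exons_per_gene[1L],
            length(exon_length) == 2L, exon_length[1L] >= 10L,
            exon_length[2L] >= exon_length[1L],
            length(intron_length) == 2L, intron_length[1L] >= 10L,
            intron_length[2L] >= intron_length[1L],
            intergenic_min >= 0L, gc > 0, gc < 1,
            protein_divergence >= 0, protein_divergence < 1,
            alignment_identity_noise >= 0)
  structure(list(n_contigs = as.integer(n_contigs),
                 contig_length = as.integer(contig_length),
                 n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_length = as.integer(exon_length),
                 intron_length = as.integer(intron_length),
                 intergenic_min = as.integer(intergenic_min),
                 gc = gc, protein_divergence = protein_divergence,
                 alignment_identity_noise = alignment_identity_noise,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

runif_int <- function(n, lo, hi) {
  if (lo == hi) rep(as.integer(lo), n) else
    as.integer(lo) + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

random_background <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a genome with planted genes, plus truth annotation and proteins
#'
#' Each planted gene has an ATG start, a stop-codon end, an internal-stop-free
#' CDS drawn codon-by-codon from a fixed usage-biased table, and introns
#' beginning GT / ending AG. Strands are assigned randomly; genes are placed
#' left to right with at least `intergenic_min` spacing. Deterministic given
#' the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `genome` (named character), `genes` (truth, list of
#'   [gene_model()]), `proteins` (named character, stop stripped) and `spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  contig_names <- sprintf("ctg%02d", seq_len(spec$n_contigs))
  genome <- stats::setNames(
    vapply(contig_names, function(nm) random_background(spec$contig_length, spec$gc), ""),
    contig_names)

  genes <- list()
  proteins <- character()
  ctg <- 1L
  cursor <- 0L
  for (gi in seq_len(spec$n_genes)) {
    n_ex <- runif_int(1L, spec$exons_per_gene[1L], spec$exons_per_gene[2L])
    ex_len <- runif_int(n_ex, spec$exon_length[1L], spec$exon_length[2L])
    rem <- sum(ex_len) %% 3L
    ex_len[n_ex] <- ex_len[n_ex] - rem          # CDS length a multiple of 3
    in_len <- if (n_ex > 1L) runif_int(n_ex - 1L, spec$intron_length[1L],
                                       spec$intron_length[2L]) else integer()
    span <- sum(ex_len) + sum(in_len)
    gap <- spec$intergenic_min + runif_int(1L, 0L, max(1L, spec$intergenic_min))
    placed <- FALSE
    while (!placed) {
      gstart <- cursor + gap + 1L
      if (gstart + span - 1L + spec$intergenic_min <= spec$contig_length) {
        placed <- TRUE
      } else if (ctg < spec$n_contigs) {
        ctg <- ctg + 1L
        cursor <- 0L
      } else {
        stop("synthetic spec unsatisfiable: contig capacity exhausted after ",
             gi - 1L, " of ", spec$n_genes, " genes (", spec$n_contigs, " x ",
             spec$contig_length, " bp); enlarge contigs or reduce genes")
      }
    }
    strand <- sample(c("+", "-"), 1L)
    ncod <- sum(ex_len) %/% 3L
    body <- sample(names(.CODON_USAGE), ncod - 2L, replace = TRUE,
                   prob = .CODON_USAGE)
    stop_codon <- sample(.STOP_CODONS, 1L)
    cds <- paste(c("ATG", body, stop_codon), collapse = "")

    # interleave exon chunks of the CDS with GT..AG introns
    ex_end <- cumsum(ex_len)
    ex_start <- ex_end - ex_len + 1L
    pieces <- character(2L * n_ex - 1L)
    pieces[seq(1L, 2L * n_ex - 1L, by = 2L)] <-
      substring(cds, ex_start, ex_end)
    if (n_ex > 1L) {
      pieces[seq(2L, 2L * n_ex - 2L, by = 2L)] <- vapply(in_len, function(l)
        paste0("GT", random_background(l - 4L, spec$gc), "AG"), "")
    }
    construct <- paste(pieces, collapse = "")
    stopifnot(nchar(construct) == span)

    ins <- if (strand == "+") construct else reverse_complement(construct)
    cn <- contig_names[ctg]
    substr(genome[[cn]], gstart, gstart + span - 1L) <- ins

    # construct coordinates -> genome coordinates
    con_start <- integer(n_ex); pos <- 1L
    for (i in seq_len(n_ex)) {
      con_start[i] <- pos
      pos <- pos + ex_len[i] + if (i < n_ex) in_len[i] else 0L
    }
    con_end <- con_start + ex_len - 1L
    gend <- gstart + span - 1L
    if (strand == "+") {
      gs <- gstart + con_start - 1L
      ge <- gstart + con_end - 1L
    } else {
      gs <- gend - con_end + 1L
      ge <- gend - con_start + 1L
    }
    gid <- sprintf("g%d", gi)
    tm <- transcript_model(transcript_id = paste0(gid, ".t1"), gene_id = gid,
                           seqid = cn, strand = strand,
                           cds = data.frame(start = gs, end = ge))
    genes[[length(genes) + 1L]] <- gene_model(gid, list(tm))
    pep <- peptide_of(cds)
    stopifnot(!grepl("*", pep, fixed = TRUE))
    proteins[[paste0(gid, "_prot")]] <- pep
    cursor <- gend
  }
  list(genome = genome, genes = sort_genes(genes), proteins = proteins,
       spec = spec)
}

#' Mutate truth proteins into divergent homologs
#'
#' Each site is substituted with probability `divergence` by a uniformly
#' random different residue; the realized identity of each sequence is
#' returned (and recorded in FASTA headers by [simulate_fixtures()]).
#'
#' @param proteins named character vector of truth proteins.
#' @param divergence per-site substitution probability in [0, 1).
#' @param seed seed for the mutation stream.
#' @return list with `proteins` (named character) and `identity` (named
#'   numeric, realized per-sequence identity).
#' @export
mutate_proteins <- function(proteins, divergence = 0, seed = 1L) {
  stopifnot(divergence >= 0, divergence < 1)
  set.seed(seed)
  out <- character(length(proteins))
  idv <- numeric(length(proteins))
  for (i in seq_along(proteins)) {
    aa <- strsplit(proteins[[i]], "", fixed = TRUE)[[1L]]
    hit <- stats::runif(length(aa)) < divergence
    if (any(hit)) {
      aa[hit] <- vapply(aa[hit], function(a)
        sample(setdiff(.AA_ALPHABET, a), 1L), "")
    }
    out[i] <- paste(aa, collapse = "")
    idv[i] <- 1 - sum(hit) / length(aa)
  }
  names(out) <- names(proteins)
  names(idv) <- names(proteins)
  list(proteins = out, identity = idv)
}

#' Simulate miniprot-like alignments of homologs back to the truth loci
#'
#' Emits one mRNA record per truth transcript with CDS children at the truth
#' coordinates and `Identity = realized identity + Gaussian(0, noise)`,
#' clamped to [0, 1] — the format [parse_alignment_gff3()] consumes.
#'
#' @param genes truth gene models from [generate_genome()].
#' @param identities named numeric vector (by `<gene_id>_prot`) of realized
#'   homolog identities; defaults to 1 for every gene.
#' @param noise sd of the Gaussian identity noise.
#' @param seed seed for the noise stream.
#' @param path when given, the GFF3 text is written there.
#' @return character vector of GFF3 lines (invisibly when `path` is given).
#' @export
simulate_alignments <- function(genes, identities = NULL, noise = 0,
                                seed = 1L, path = NULL) {
  set.seed(seed)
  lines <- "##gff-version 3"
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    tm <- g$transcripts[[1L]]
    prot <- paste0(g$gene_id, "_prot")
    ident <- if (is.null(identities)) 1 else {
      if (!prot %in% names(identities))
        stop("no identity recorded for ", prot)
      identities[[prot]]
    }
    ident <- min(1, max(0, ident + if (noise > 0) stats::rnorm(1L, 0, noise) else 0))
    mid <- sprintf("MP%06d", i)
    plen <- sum(interval_width(tm$cds)) %/% 3L - 1L
    lines <- c(lines, paste(g$seqid, "miniprot", "mRNA", min(tm$cds$start),
                            max(tm$cds$end), ".", g$strand, ".",
                            sprintf("ID=%s;Identity=%.4f;Target=%s 1 %d",
                                    mid, ident, prot, plen),
                            sep = "\t"))
    for (j in seq_len(nrow(tm$cds))) {
      lines <- c(lines, paste(g$seqid, "miniprot", "CDS", tm$cds$start[j],
                              tm$cds$end[j], ".", g$strand, tm$cds$phase[j],
                              paste0("Parent=", mid),
                              sep = "\t"))
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Generate and write a complete synthetic fixture set
#'
#' Runs [generate_genome()], [mutate_proteins()] and [simulate_alignments()]
#' under seeds derived from the spec's seed and writes
#' `<prefix>.genome.fa`, `<prefix>.truth.gff3`, `<prefix>.truth.pep.fa`,
#' `<prefix>.homologs.pep.fa` (headers carry the realized identity),
#' `<prefix>.aln.gff3` and `<prefix>.spec.json`.
#'
#' @param spec a [synthetic_spec()].
#' @param out_prefix output path prefix.
#' @return invisibly, a list with the in-memory objects and file paths.
#' @export
simulate_fixtures <- function(spec, out_prefix) {
  truth <- generate_genome(spec)
  mut <- mutate_proteins(truth$proteins, spec$protein_divergence,
                         seed = spec$seed + 1L)
  paths <- list(genome = paste0(out_prefix, ".genome.fa"),
                truth_gff3 = paste0(out_prefix, ".truth.gff3"),
                truth_pep = paste0(out_prefix, ".truth.pep.fa"),
                homolog_pep = paste0(out_prefix, ".homologs.pep.fa"),
                aln_gff3 = paste0(out_prefix, ".aln.gff3"),
                spec_json = paste0(out_prefix, ".spec.json"))
  write_fasta(truth$genome, paths$genome)
  write_gff3(truth$genes, paths$truth_gff3, source = "synthetic")
  write_fasta(truth$proteins, paths$truth_pep)
  hom <- mut$proteins
  names(hom) <- sprintf("%s identity=%.4f", names(hom), mut$identity)
  write_fasta(hom, paths$homolog_pep)
  simulate_alignments(truth$genes, mut$identity,
                      noise = spec$alignment_identity_noise,
                      seed = spec$seed + 2L, path = paths$aln_gff3)
  jsonlite::write_json(unclass(spec), paths$spec_json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(truth, list(homologs = mut, paths = paths)))
}
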