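# Shared builders and independent oracles for the test suite.
# All fixtures are constructed in code; nothing is read from disk except
# files the tests themselves write to tempdir().

make_tm <- function(seqid, strand, starts, ends, tid = "t1", gid = "g1",
                    score = NA_real_, phases = NULL) {
  cds <- data.frame(start = starts, end = ends)
  if (!is.null(phases)) cds$phase <- phases
  transcript_model(tid, gid, seqid, strand, cds, score = score)
}

make_gene <- function(seqid, strand, starts, ends, gid = "g1", tid = NULL,
                      score = NA_real_) {
  if (is.null(tid)) tid <- paste0(gid, ".t1")
  gene_model(gid, list(make_tm(seqid, strand, starts, ends, tid, gid, score)))
}

mk_chain <- function(seqid, strand, starts, ends, identity = 1,
                     query_id = "protA") {
  alignment_chain(query_id, seqid, strand,
                  data.frame(start = starts, end = ends), identity)
}

# A pseudo-transcript over explicit blocks of a supplied genome, without
# going through clustering (members empty unless given).
make_pt <- function(genome, seqid, strand, starts, ends, pt_id = "pt1",
                    members = list()) {
  locus <- structure(list(seqid = seqid, strand = strand, members = members,
                          merged_blocks = data.frame(start = starts, end = ends)),
                     class = "locus")
  build_pseudotranscript(locus, genome, pt_id)
}

# Pseudo-transcript wrapping a plain sequence 1:1 on the plus strand.
wrap_pt <- function(seq, pt_id = "pt1") {
  g <- c(chrW = seq)
  make_pt(g, "chrW", "+", 1L, nchar(seq), pt_id)
}

random_dna <- function(n, gc = 0.41) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Random pseudo-transcript over a random contig: 1-5 disjoint blocks,
# random strand. Returns list(pt, genome).
random_pt <- function(contig_len = 2000L) {
  n_blocks <- sample(1:5, 1)
  cuts <- sort(sample(seq_len(contig_len - 1L), 2L * n_blocks))
  starts <- cuts[seq(1, 2 * n_blocks, by = 2)]
  ends <- cuts[seq(2, 2 * n_blocks, by = 2)]
  genome <- c(ctgR = random_dna(contig_len))
  pt <- make_pt(genome, "ctgR", sample(c("+", "-"), 1), starts, ends)
  list(pt = pt, genome = genome)
}

# Coding-like sequence: codons sampled from the package's usage table.
gen_coding_seq <- function(n_codons) {
  paste(sample(names(homanno:::.CODON_USAGE), n_codons, replace = TRUE,
               prob = homanno:::.CODON_USAGE), collapse = "")
}

# Complete ORF (ATG ... stop) with a usage-biased body.
gen_orf <- function(n_body_codons) {
  paste0("ATG", gen_coding_seq(n_body_codons), sample(c("TAA", "TAG", "TGA"), 1))
}

# Independent brute-force base-level evaluation oracle: materializes per-base
# boolean arrays per (contig, strand).
brute_force_eval <- function(pred, ref, contig_lengths) {
  mask <- function(genes) {
    m <- list()
    for (ctg in names(contig_lengths)) {
      for (st in c("+", "-")) {
        m[[paste(ctg, st)]] <- logical(contig_lengths[[ctg]])
      }
    }
    for (g in genes) for (tm in g$transcripts) {
      key <- paste(tm$seqid, tm$strand)
      for (i in seq_len(nrow(tm$cds))) {
        m[[key]][tm$cds$start[i]:tm$cds$end[i]] <- TRUE
      }
    }
    m
  }
  mp <- mask(pred); mr <- mask(ref)
  tp <- 0L; np <- 0L; nr <- 0L
  for (key in names(mp)) {
    tp <- tp + sum(mp[[key]] & mr[[key]])
    np <- np + sum(mp[[key]])
    nr <- nr + sum(mr[[key]])
  }
  list(tp_bases = tp, pred_bases = np, ref_bases = nr,
       sensitivity = if (nr > 0) tp / nr else NA_real_,
       specificity = if (np > 0) tp / np else NA_real_)
}

# Random annotation over one contig: genes with 1-3 CDS segments at random
# positions (overlaps between genes allowed; the oracle handles them).
random_annotation <- function(contig = "ctgE", contig_len = 100000L,
                              n_genes = 8L) {
  genes <- list()
  for (i in seq_len(n_genes)) {
    n_seg <- sample(1:3, 1)
    pos <- sort(sample(seq_len(contig_len - 10L), 2L * n_seg))
    starts <- pos[seq(1, 2 * n_seg, by = 2)]
    ends <- pos[seq(2, 2 * n_seg, by = 2)]
    # enforce a 1 bp gap between segments of one transcript
    ok <- n_seg == 1 || all(starts[-1] > ends[-n_seg] + 1)
    if (!ok) { n_seg <- 1L; starts <- starts[1]; ends <- ends[1] }
    genes[[i]] <- make_gene(contig, sample(c("+", "-"), 1), starts, ends,
                            gid = paste0("rg", i))
  }
  genes
}

# Small ready-made fixture files for pipeline tests, built once per run.
fixture_env <- new.env()
small_fixture <- function() {
  if (!is.null(fixture_env$fx)) return(fixture_env$fx)
  spec <- synthetic_spec(n_genes = 12L, n_contigs = 1L,
                         contig_length = 150000L, seed = 1L)
  prefix <- file.path(tempdir(), "homanno-small-fx")
  fx <- simulate_fixtures(spec, prefix)
  fixture_env$fx <- fx
  fx
}

# Analytic conditional probabilities of an order-2, frame-periodic view of
# the independent-codon generator (contexts indexed with the immediately
# preceding base as the least significant digit).
analytic_order2_truth <- function() {
  usage <- homanno:::.CODON_USAGE / sum(homanno:::.CODON_USAGE)
  b <- c("A", "C", "G", "T")
  p3 <- array(0, c(4, 4, 4))  # [b1, b2, b3]
  for (cod in names(usage)) {
    i <- match(substr(cod, 1, 1), b); j <- match(substr(cod, 2, 2), b)
    k <- match(substr(cod, 3, 3), b)
    p3[i, j, k] <- p3[i, j, k] + usage[[cod]]
  }
  truth <- array(0, c(4, 16, 3))  # [base, ctx, frame]
  pb1 <- apply(p3, 1, sum)
  for (ctx in 0:15) truth[, ctx + 1, 1] <- pb1              # frame 0: P(b1)
  for (b1 in 0:3) {
    pb2_b1 <- apply(p3[b1 + 1, , , drop = FALSE], 2, sum)
    pb2_b1 <- pb2_b1 / sum(pb2_b1)
    for (prev3 in 0:3) truth[, b1 + 4 * prev3 + 1, 2] <- pb2_b1   # frame 1
  }
  for (b1 in 0:3) for (b2 in 0:3) {
    pb3 <- p3[b1 + 1, b2 + 1, ]
    truth[, b2 + 4 * b1 + 1, 3] <- pb3 / sum(pb3)           # frame 2
  }
  truth
}
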