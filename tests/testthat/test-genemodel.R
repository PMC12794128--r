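# ORF projection, locus splitting, filtering, deduplication and the
# end-to-end pipeline contracts.

test_that("project_orf produces correct CDS intervals and phases across a junction", {
  g <- c(chr = "ATGAAAGCCGGGCCCTAA")
  # blocks of 7 + 11 nt; ORF covers the first 15 transcript positions
  pt <- make_pt(g, "chr", "+", c(1, 8), c(7, 18))
  orf <- homanno:::orf_new("pt1", 1, 15, "complete", substr(pt$sequence, 1, 15))
  tm <- project_orf(pt, orf)
  expect_equal(nrow(tm$cds), 2)
  expect_equal(sum(tm$cds$end - tm$cds$start + 1), 15)
  expect_equal(tm$cds$phase, c(0L, 2L))  # (3 - 7 mod 3) mod 3 = 2

  # single-block complete ORF: one CDS, phase 0
  pt2 <- make_pt(c(chr = "ATGAAATAA"), "chr", "+", 1, 9)
  orf2 <- homanno:::orf_new("pt1", 1, 9, "complete", "ATGAAATAA")
  tm2 <- project_orf(pt2, orf2)
  expect_equal(nrow(tm2$cds), 1)
  expect_equal(tm2$cds$phase, 0L)
})

test_that("projection round-trips: genome re-extraction translates to the ORF peptide", {
  set.seed(1)
  for (rep in 1:100) {
    n_ex <- sample(1:4, 1)
    cds <- gen_orf(sample(40:80, 1))
    # split the CDS across n_ex exons with random introns
    cuts <- if (n_ex > 1) sort(sample(seq_len(nchar(cds) - 1), n_ex - 1)) else integer()
    bounds <- c(0, cuts, nchar(cds))
    pieces <- substring(cds, bounds[-length(bounds)] + 1, bounds[-1])
    introns <- replicate(max(0, n_ex - 1), paste0("GT", random_dna(sample(30:80, 1)), "AG"))
    construct <- paste(as.vector(rbind(pieces, c(introns, "")))[seq_len(2 * n_ex - 1)],
                       collapse = "")
    strand <- sample(c("+", "-"), 1)
    flank5 <- random_dna(50); flank3 <- random_dna(50)
    contig <- paste0(flank5,
                     if (strand == "+") construct else reverse_complement(construct),
                     flank3)
    genome <- c(ctg = contig)
    # exon coordinates in construct space
    con_start <- integer(n_ex); pos <- 1L
    lens <- nchar(pieces)
    ilens <- if (n_ex > 1) nchar(introns) else integer()
    for (i in seq_len(n_ex)) {
      con_start[i] <- pos
      pos <- pos + lens[i] + if (i < n_ex) ilens[i] else 0L
    }
    con_end <- con_start + lens - 1L
    span <- nchar(construct)
    if (strand == "+") {
      gs <- 50L + con_start; ge <- 50L + con_end
    } else {
      gs <- 50L + (span - con_end) + 1L; ge <- 50L + (span - con_start) + 1L
    }
    pt <- make_pt(genome, "ctg", strand, sort(gs), ge[order(gs)])
    orfs <- enumerate_orfs(pt, min_len_aa = 30, allow_partial = FALSE)
    # locate the planted ORF among candidates
    planted <- Filter(function(o) o$nt == cds, orfs)
    expect_true(length(planted) >= 1)
    tm <- project_orf(pt, planted[[1]])
    re <- extract_spliced_sequence(genome, tm$cds, tm$strand, seqid = "ctg")
    expect_equal(as.character(translate_cds(re)), paste0(planted[[1]]$peptide, "*"))
  }
})

test_that("split_locus yields one gene per retained ORF with disjoint genomic spans", {
  set.seed(2)
  orf1 <- gen_orf(110); orf2 <- gen_orf(140)
  seq <- paste0(random_dna(30), orf1, random_dna(90), orf2, random_dna(30))
  pt <- wrap_pt(seq)
  orfs <- enumerate_orfs(pt, min_len_aa = 100, allow_partial = FALSE)
  m <- structure(list(order = 5L, pseudocount = 1, zero_information = TRUE,
                      n_training = 0L), class = "markov_coding_model")
  sel <- select_orfs(pt, refine_orf_starts(m, pt, orfs, refine = FALSE),
                     min_score = 0, min_len_aa = 100)
  expect_length(sel, 2)
  genes <- split_locus(pt, sel)
  expect_length(genes, 2)
  expect_true(genes[[1]]$end < genes[[2]]$start)
  expect_equal(vapply(genes, `[[`, "", "gene_id"), c("pt1.g1", "pt1.g2"))
  expect_length(split_locus(pt, list()), 0)
})

test_that("filter_models drops short or low-scoring genes and logs the criterion", {
  ok <- make_gene("c", "+", 1, 309, gid = "good", score = 5)       # 102 codons -> 101 aa
  short <- make_gene("c", "+", 1000, 1299, gid = "short", score = 5)  # 99 aa
  low <- make_gene("c", "+", 2000, 2309, gid = "low", score = -2.5)
  res <- filter_models(list(ok, short, low), min_orf_aa = 100, min_score = 0)
  expect_equal(vapply(res$models, `[[`, "", "gene_id"), "good")
  expect_equal(res$rejected$gene_id, c("short", "low"))
  expect_equal(res$rejected$criterion, c("length", "score"))
})

test_that("deduplicate collapses identical chains, resolves overlaps by score, renames sequentially", {
  a <- make_gene("c", "+", c(100, 400), c(249, 549), gid = "a", score = 10)
  a$transcripts[[1]]$source_proteins <- "p1"
  b <- make_gene("c", "+", c(100, 400), c(249, 549), gid = "b", score = 10)
  b$transcripts[[1]]$source_proteins <- "p2"
  out <- deduplicate(list(a, b))
  expect_length(out, 1)
  expect_equal(out[[1]]$transcripts[[1]]$source_proteins, c("p1", "p2"))
  expect_equal(out[[1]]$gene_id, "gene-1")

  # overlapping distinct chains: higher score survives
  hi <- make_gene("c", "+", 100, 399, gid = "hi", score = 50)
  lo <- make_gene("c", "+", 250, 549, gid = "lo", score = 30)
  out2 <- deduplicate(list(lo, hi))
  expect_length(out2, 1)
  expect_equal(out2[[1]]$transcripts[[1]]$score, 50)

  # disjoint models are all kept, sorted and renamed by position
  d1 <- make_gene("c", "+", 5000, 5299, gid = "x", score = 1)
  d2 <- make_gene("c", "+", 100, 399, gid = "y", score = 1)
  out3 <- deduplicate(list(d1, d2), id_prefix = "EB")
  expect_equal(vapply(out3, `[[`, "", "gene_id"), c("EBgene-1", "EBgene-2"))
  expect_equal(out3[[1]]$start, 100L)

  # opposite strands never conflict
  p <- make_gene("c", "+", 100, 399, gid = "p", score = 1)
  q <- make_gene("c", "-", 100, 399, gid = "q", score = 1)
  expect_length(deduplicate(list(p, q)), 2)
})

test_that("pipeline errors on alignment contigs absent from the genome", {
  fx <- small_fixture()
  chains <- parse_alignment_gff3(fx$paths$aln_gff3)
  chains[[1]]$seqid <- "chrZ"
  expect_error(run_pipeline(fx$paths$genome, chains, quiet = TRUE), "chrZ")
})

test_that("an empty post-filter chain set warns and returns empty but valid outputs", {
  fx <- small_fixture()
  tmp <- tempfile()
  chains <- parse_alignment_gff3(fx$paths$aln_gff3)
  chains <- lapply(chains, function(ch) { ch$identity <- 0.5; ch })
  expect_warning(
    res <- run_pipeline(fx$paths$genome, chains,
                        pipeline_config(min_identity = 0.9),
                        out_prefix = tmp, quiet = TRUE),
    "no alignment chains")
  expect_length(res$genes, 0)
  expect_length(read_gff3(paste0(tmp, ".gff3")), 0)
})

test_that("the pipeline recovers every planted gene exactly on the small fixture", {
  fx <- small_fixture()
  res <- suppressWarnings(run_pipeline(fx$paths$genome, fx$paths$aln_gff3,
                                       pipeline_config(), quiet = TRUE))
  expect_length(res$genes, length(fx$genes))
  ev <- base_level_eval(res$genes, fx$genes)
  expect_gte(ev$sensitivity, 0.99)
  expect_gte(ev$specificity, 0.99)
  # every output protein matches its planted truth protein
  truth_peps <- sort(unname(fx$proteins))
  expect_equal(sort(unname(res$proteins)), truth_peps)
})

test_that("gene count is non-increasing in min_identity and in min_orf_aa", {
  spec <- synthetic_spec(n_genes = 15L, n_contigs = 1L, contig_length = 200000L,
                         protein_divergence = 0.12, seed = 2L)
  prefix <- tempfile()
  fx <- simulate_fixtures(spec, prefix)
  n_id <- vapply(c(0.5, 0.85, 0.95), function(thr)
    length(suppressWarnings(run_pipeline(fx$paths$genome, fx$paths$aln_gff3,
                    pipeline_config(min_identity = thr), quiet = TRUE))$genes),
    integer(1))
  expect_true(all(diff(n_id) <= 0))
  n_len <- vapply(c(50L, 150L, 250L), function(aa)
    length(suppressWarnings(run_pipeline(fx$paths$genome, fx$paths$aln_gff3,
                    pipeline_config(min_orf_aa = aa), quiet = TRUE))$genes),
    integer(1))
  expect_true(all(diff(n_len) <= 0))
})
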