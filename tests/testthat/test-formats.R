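# Gene-model containers, GFF3 IO, spliced extraction and translation.

test_that("translate_cds follows the standard code, flags internal stops, rejects bad lengths", {
  expect_equal(as.character(translate_cds("ATGTAA")), "M*")
  expect_false(attr(translate_cds("ATGTAA"), "internal_stop"))
  expect_equal(as.character(translate_cds("ATGGCC")), "MA")
  p <- translate_cds("ATGTAAGCC")
  expect_equal(as.character(p), "M*A")
  expect_true(attr(p, "internal_stop"))
  expect_error(translate_cds("ATGA"), "multiple of 3")
  # non-ACGT codons translate to X (soft-masked / ambiguous genomes)
  expect_equal(as.character(translate_cds("ATGNNN")), "MX")
  expect_equal(as.character(translate_cds("atggcc")), "MA")
})

test_that("extract_spliced_sequence concatenates in genomic order and reverse-complements whole", {
  g <- c(chr1 = "AAAGGGTTT", chr2 = "ATGAAATAA")
  iv <- data.frame(start = 4, end = 6)
  expect_equal(extract_spliced_sequence(g, iv, "+", seqid = "chr1"), "GGG")
  expect_equal(extract_spliced_sequence(g, iv, "-", seqid = "chr1"), "CCC")
  iv2 <- data.frame(start = c(1, 7), end = c(3, 9))
  expect_equal(extract_spliced_sequence(g, iv2, "+", seqid = "chr2"), "ATGTAA")
  # minus extraction equals reverse complement of plus extraction
  expect_equal(extract_spliced_sequence(g, iv2, "-", seqid = "chr2"),
               reverse_complement("ATGTAA"))
  expect_error(extract_spliced_sequence(g, data.frame(start = 5, end = 12),
                                        "+", seqid = "chr1"),
               "beyond end")
})

test_that("a minimal GFF3 reads back into one gene with one CDS", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t300\t.\t+\t.\tID=geneX",
               "chr1\tsrc\tmRNA\t100\t300\t.\t+\t.\tID=tX;Parent=geneX",
               "chr1\tsrc\tCDS\t100\t300\t.\t+\t0\tID=cX;Parent=tX"), path)
  genes <- read_gff3(path)
  expect_length(genes, 1)
  expect_equal(genes[[1]]$gene_id, "geneX")
  expect_length(genes[[1]]$transcripts, 1)
  expect_equal(cds_length(genes[[1]]$transcripts[[1]]), 201L)
})

test_that("orphan CDS and malformed attributes are errors naming the culprit", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t300\t.\t+\t.\tID=geneX",
               "chr1\tsrc\tmRNA\t100\t300\t.\t+\t.\tID=tX;Parent=geneX",
               "chr1\tsrc\tCDS\t100\t300\t.\t+\t0\tID=orphan1;Parent=missing"), path)
  expect_error(read_gff3(path), "orphan1")

  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t300\t.\t+\t.\tID geneX"), path)
  expect_error(read_gff3(path), "line 2")

  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t300\t.\t+\t."), path)
  expect_error(read_gff3(path), "9 tab-separated")
})

test_that("write -> read round trip preserves coordinates, strands, phases and IDs", {
  g1 <- gene_model("gA", list(
    make_tm("chr1", "+", c(100, 400), c(249, 549), tid = "gA.t1", gid = "gA"),
    make_tm("chr1", "+", c(100, 500), c(249, 550), tid = "gA.t2", gid = "gA")))
  g2 <- make_gene("chr2", "-", c(900, 1500), c(1100, 1600), gid = "gB")
  path <- tempfile(fileext = ".gff3")
  write_gff3(list(g2, g1), path)
  back <- read_gff3(path)
  expect_length(back, 2)
  # deterministic (seqid, start, gene_id) order
  expect_equal(vapply(back, `[[`, "", "gene_id"), c("gA", "gB"))
  orig <- sort_list <- list(g1, g2)
  for (i in 1:2) {
    a <- orig[[i]]; b <- back[[i]]
    expect_equal(length(a$transcripts), length(b$transcripts))
    for (j in seq_along(a$transcripts)) {
      expect_equal(a$transcripts[[j]]$cds, b$transcripts[[j]]$cds)
      expect_equal(a$transcripts[[j]]$transcript_id, b$transcripts[[j]]$transcript_id)
      expect_equal(a$transcripts[[j]]$strand, b$transcripts[[j]]$strand)
    }
  }
  # second write of the re-read annotation is byte-identical
  path2 <- tempfile(fileext = ".gff3")
  write_gff3(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("writing an empty annotation yields a header-only file", {
  path <- tempfile(fileext = ".gff3")
  write_gff3(list(), path)
  expect_identical(readLines(path), "##gff-version 3")
  expect_length(read_gff3(path), 0)
})

test_that("longest_isoform keeps the longest (tie: lexicographically smallest id) and is idempotent", {
  g <- gene_model("gA", list(
    make_tm("chr1", "+", 100, 549, tid = "long", gid = "gA"),    # 450 nt
    make_tm("chr1", "+", 100, 399, tid = "short", gid = "gA")))  # 300 nt
  out <- longest_isoform(list(g))
  expect_length(out[[1]]$transcripts, 1)
  expect_equal(out[[1]]$transcripts[[1]]$transcript_id, "long")

  tie <- gene_model("gB", list(
    make_tm("chr1", "+", 100, 399, tid = "tB", gid = "gB"),
    make_tm("chr1", "+", 200, 499, tid = "tA", gid = "gB")))
  out2 <- longest_isoform(list(tie))
  expect_equal(out2[[1]]$transcripts[[1]]$transcript_id, "tA")

  single <- make_gene("chr1", "+", 1, 300, gid = "gC")
  expect_length(longest_isoform(list(single)), 1)
  # idempotent, never changes gene count
  expect_equal(longest_isoform(out2), out2)
})

test_that("computed phases follow the cumulative GFF3 convention on both strands", {
  # 7 + 8 nt segments: second phase (+) = (3 - 7 mod 3) mod 3 = 2
  tm <- make_tm("chr1", "+", c(1, 11), c(7, 18))
  expect_equal(tm$cds$phase, c(0L, 2L))
  # minus strand: transcript order is right to left (first segment is 8 nt)
  tmm <- make_tm("chr1", "-", c(1, 11), c(7, 18))
  expect_equal(tmm$cds$phase, c(1L, 0L))
})

test_that("transcript invariants are enforced", {
  expect_error(make_tm("chr1", "+", c(1, 5), c(10, 20)), "overlap")
  expect_error(make_tm("chr1", "*", 1, 10), "strand")
  expect_error(transcript_model("t", "g", "chr1", "+",
                                data.frame(start = 10, end = 5)),
               "end must be >= start")
})
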