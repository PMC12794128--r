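# ORF enumeration, hexamer Markov model training/scoring, start refinement
# and non-overlapping selection.

mk_orf <- function(t_start, t_end, score, completeness = "complete",
                   pep_len = (t_end - t_start + 1) %/% 3 - 1) {
  structure(list(pt_id = "pt1", t_start = as.integer(t_start),
                 t_end = as.integer(t_end), completeness = completeness,
                 nt = NA_character_, peptide = strrep("K", pep_len),
                 score = score),
            class = "open_reading_frame")
}

test_that("a planted 101-codon ORF is enumerated exactly once as complete", {
  set.seed(1)
  seq <- paste0(random_dna(10), "ATG", gen_coding_seq(100), "TAA", random_dna(10))
  orfs <- enumerate_orfs(seq, min_len_aa = 100, allow_partial = FALSE)
  expect_length(orfs, 1)
  expect_equal(orfs[[1]]$completeness, "complete")
  expect_equal(nchar(orfs[[1]]$peptide), 101L)
  expect_equal(orfs[[1]]$t_start, 11L)
  expect_equal(orfs[[1]]$t_end, 11L + 306L - 1L)
})

test_that("a frame with no ATG and no stop yields one internal ORF when partials are allowed", {
  set.seed(4)
  # poly-CA repeat: no ATG, no stop codon in any frame
  seq <- strrep("CA", 200)
  orfs <- enumerate_orfs(seq, min_len_aa = 100, allow_partial = TRUE)
  expect_true(length(orfs) >= 1)
  expect_true(all(vapply(orfs, `[[`, "", "completeness") == "internal"))
  expect_length(enumerate_orfs(seq, min_len_aa = 100, allow_partial = FALSE), 0)
})

test_that("ORFs below the length gate are suppressed", {
  expect_length(enumerate_orfs("ATGTAA", min_len_aa = 100), 0)
  expect_length(enumerate_orfs("ATGAAATAA", min_len_aa = 2, allow_partial = FALSE), 1)
})

test_that("every enumerated ORF is a multiple of 3 and translates without internal stop", {
  set.seed(1)
  for (rep in 1:20) {
    seq <- paste0(random_dna(400), "ATG", gen_coding_seq(sample(100:150, 1)),
                  "TGA", random_dna(400))
    orfs <- enumerate_orfs(seq, min_len_aa = 30, allow_partial = TRUE)
    expect_true(length(orfs) >= 1)
    for (o in orfs) {
      expect_equal((o$t_end - o$t_start + 1) %% 3, 0)
      expect_equal(o$nt, substr(seq, o$t_start, o$t_end))
      expect_false(attr(translate_cds(o$nt), "internal_stop"))
      if (o$completeness == "complete") {
        expect_true(startsWith(o$nt, "ATG"))
        expect_true(substr(o$nt, nchar(o$nt) - 2, nchar(o$nt)) %in% c("TAA", "TAG", "TGA"))
      }
    }
  }
})

train_fixture_pts <- function(n = 60, body = 150) {
  lapply(seq_len(n), function(i)
    wrap_pt(paste0(random_dna(300), gen_orf(body), random_dna(300)),
            pt_id = paste0("tp", i)))
}

test_that("too few training ORFs fall back to a zero-information model scoring 0", {
  set.seed(1)
  pts <- train_fixture_pts(5)
  expect_warning(m <- train_model(pts, min_training = 50), "zero-information")
  expect_true(m$zero_information)
  expect_equal(score_orf(m, gen_orf(80)), 0)
})

test_that("training is deterministic and deduplicates identical ORF sequences", {
  set.seed(1)
  pts <- train_fixture_pts(55)
  m1 <- train_model(pts)
  m2 <- train_model(pts)
  expect_identical(m1, m2)
  expect_gte(m1$n_training, 55L)  # at least the 55 planted ORFs
  # feeding a duplicated pseudo-transcript adds no training sequence
  # (the coding tables; the background legitimately sees the extra sequence)
  m3 <- train_model(c(pts, pts[1]))
  expect_equal(m3$n_training, m1$n_training)
  expect_identical(m3$coding, m1$coding)
})

test_that("scores are additive over in-frame concatenation with carried context", {
  set.seed(2)
  m <- train_model(train_fixture_pts(55))
  s1 <- gen_coding_seq(40)
  s2 <- gen_coding_seq(40)
  expect_equal(score_orf(m, paste0(s1, s2)),
               score_orf(m, s1) + score_orf(m, s2, prior = s1),
               tolerance = 1e-10)
  expect_error(score_orf(m, "ATGA"), "multiple of 3")
})

test_that("coding-table sequences outscore background sequences (sign test)", {
  set.seed(3)
  m <- train_model(train_fixture_pts(60))
  n <- 200
  d <- vapply(seq_len(n), function(i)
    score_orf(m, gen_coding_seq(100)) - score_orf(m, random_dna(300)), numeric(1))
  expect_true(mean(d) > 0)
  p <- stats::binom.test(sum(d > 0), n, 0.5, alternative = "greater")$p.value
  expect_lt(p, 0.01)
})


test_that("training on simulated ORFs recovers the generator's conditionals (TV <= 0.05)", {
  set.seed(5)
  pts <- lapply(seq_len(500), function(i) wrap_pt(gen_orf(150), paste0("o", i)))
  m <- train_model(pts, top_n = 500, min_len_aa = 100)
  expect_equal(m$n_training, 500L)
  est <- m$coding[[3]]           # order-2 table, [base, ctx, frame]
  truth <- analytic_order2_truth()
  tv <- apply(abs(est - truth), c(2, 3), sum) / 2
  expect_lt(max(tv), 0.05)
})

test_that("select_orfs keeps non-overlapping ORFs greedily by score, completeness, length", {
  a <- mk_orf(1, 300, 40)
  b <- mk_orf(401, 900, 25)
  expect_length(select_orfs(NULL, list(a, b), min_score = 0, min_len_aa = 50), 2)
  # overlapping: higher score wins
  ov <- mk_orf(151, 600, 25)
  kept <- select_orfs(NULL, list(ov, a), min_score = 0, min_len_aa = 50)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$score, 40)
  # equal scores: longer wins
  l600 <- mk_orf(1, 600, 30)
  l450 <- mk_orf(301, 750, 30)
  kept2 <- select_orfs(NULL, list(l450, l600), min_score = 0, min_len_aa = 50)
  expect_equal(kept2[[1]]$t_end - kept2[[1]]$t_start + 1L, 600L)
  # thresholds are inclusive gates
  expect_length(select_orfs(NULL, list(mk_orf(1, 300, -1)), 0, 50), 0)
  expect_length(select_orfs(NULL, list(mk_orf(1, 300, 0, pep_len = 49)), 0, 50), 0)
})

test_that("selection output is non-overlapping and permutation-invariant", {
  set.seed(6)
  for (rep in 1:10) {
    orfs <- lapply(1:12, function(i) {
      s <- sample(1:3000, 1)
      mk_orf(s, s + 3 * sample(60:200, 1) - 1, sample(1:50, 1))
    })
    kept <- select_orfs(NULL, orfs, min_score = 0, min_len_aa = 50)
    ts <- vapply(kept, `[[`, integer(1), "t_start")
    te <- vapply(kept, `[[`, integer(1), "t_end")
    if (length(kept) > 1) {
      o <- order(ts)
      expect_true(all(ts[o][-1] > te[o][-length(o)]))
    }
    perm <- sample(seq_along(orfs))
    kept2 <- select_orfs(NULL, orfs[perm], min_score = 0, min_len_aa = 50)
    expect_equal(sort(vapply(kept2, `[[`, integer(1), "t_start")), sort(ts))
  }
})

test_that("start refinement anchors the ATG at the 5' homology boundary", {
  set.seed(7)
  # genome: flank + gene + flank; homology block covers exactly the CDS
  cds <- gen_orf(120)
  genome <- c(ctg = paste0(random_dna(300), cds, random_dna(300)))
  member <- mk_chain("ctg", "+", 301, 300 + nchar(cds), 1, "p1")
  pt <- make_pt(genome, "ctg", "+", 1, nchar(genome[["ctg"]]), members = list(member))
  orfs <- enumerate_orfs(pt, min_len_aa = 100, allow_partial = TRUE)
  m <- structure(list(order = 5L, pseudocount = 1, zero_information = TRUE,
                      n_training = 0L), class = "markov_coding_model")
  refined <- refine_orf_starts(m, pt, orfs)
  comp <- Filter(function(o) o$completeness == "complete", refined)
  expect_length(comp, 1)
  expect_equal(comp[[1]]$t_start, 301L)
  expect_equal(comp[[1]]$t_end, 300L + nchar(cds))
})
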