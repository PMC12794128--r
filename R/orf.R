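# ORF enumeration and the self-trained frame-periodic hexamer Markov model.
#
# The coding-potential model is a 5th-order (hexamer), frame-periodic Markov
# log-odds score: for each frame (position-in-codon) the conditional
# probability of a base given its 5 preceding bases under a coding model
# trained on the longest complete ORFs of the run's own pseudo-transcripts,
# against a frame-free background trained on all pseudo-transcript sequence.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

orf_new <- function(pt_id, t_start, t_end, completeness, nt,
                    table = 1L, score = NA_real_) {
  structure(list(pt_id = pt_id, t_start = as.integer(t_start),
                 t_end = as.integer(t_end), completeness = completeness,
                 nt = nt, peptide = peptide_of(nt, table),
                 score = score),
            class = "open_reading_frame")
}

#' Enumerate candidate ORFs in a pseudo-transcript
#'
#' Scans the three forward frames only (the strand is already fixed by the
#' protein alignment). Within each stop-to-stop segment the longest
#' ATG-initiated ORF is kept (complete when stop-terminated); when
#' `allow_partial`, segments truncated by the pseudo-transcript ends are
#' reported with completeness `5prime_partial`, `3prime_partial` or
#' `internal`. Only ORFs with peptide length >= `min_len_aa` are returned.
#'
#' @param pt a `pseudo_transcript`, or a plain nucleotide string.
#' @param min_len_aa minimum peptide length in amino acids (>= 1).
#' @param allow_partial report end-truncated ORFs as well as complete ones.
#' @param table NCBI translation-table number.
#' @return list of `open_reading_frame` objects sorted by (t_start, t_end);
#'   every ORF spans a multiple of 3 nt and translates with no internal stop.
#' @export
enumerate_orfs <- function(pt, min_len_aa = 100L, allow_partial = TRUE, table = 1L) {
  stopifnot(min_len_aa >= 1L)
  seq <- if (is.character(pt)) toupper(pt) else pt$sequence
  pt_id <- if (is.character(pt)) "seq" else pt$pt_id
  L <- nchar(seq)
  out <- list()
  for (f in 0:2) {
    ncod <- (L - f) %/% 3L
    if (ncod < 1L) next
    cs <- f + 1L + 3L * (0:(ncod - 1L))
    codons <- substring(seq, cs, cs + 2L)
    stops <- which(codons %in% .STOP_CODONS)
    atgs <- which(codons == "ATG")
    seg_start <- c(1L, stops + 1L)
    seg_stop <- c(stops, NA_integer_)
    for (si in seq_along(seg_start)) {
      a <- seg_start[si]
      s <- seg_stop[si]
      if (!is.na(s)) {
        seg_atgs <- atgs[atgs >= a & atgs < s]
        if (length(seg_atgs)) {
          st <- seg_atgs[1L]          # earliest ATG = longest ORF in segment
          if (s - st >= min_len_aa)
            out[[length(out) + 1L]] <- orf_new(pt_id, cs[st], cs[s] + 2L,
                                               "complete",
                                               substr(seq, cs[st], cs[s] + 2L),
                                               table)
        } else if (allow_partial && a == 1L && s > a) {
          # 5'-truncated: the segment abuts the transcript start, no ATG seen
          if (s - a >= min_len_aa)
            out[[length(out) + 1L]] <- orf_new(pt_id, cs[a], cs[s] + 2L,
                                               "5prime_partial",
                                               substr(seq, cs[a], cs[s] + 2L),
                                               table)
        }
      } else {
        if (a > ncod) next
        seg_atgs <- atgs[atgs >= a]
        if (length(seg_atgs)) {
          if (allow_partial) {
            st <- seg_atgs[1L]
            if (ncod - st + 1L >= min_len_aa)
              out[[length(out) + 1L]] <- orf_new(pt_id, cs[st], cs[ncod] + 2L,
                                                 "3prime_partial",
                                                 substr(seq, cs[st], cs[ncod] + 2L),
                                                 table)
          }
        } else if (allow_partial && a == 1L) {
          # no start, no stop anywhere in this frame: internal ORF
          if (ncod >= min_len_aa)
            out[[length(out) + 1L]] <- orf_new(pt_id, cs[1L], cs[ncod] + 2L,
                                               "internal",
                                               substr(seq, cs[1L], cs[ncod] + 2L),
                                               table)
        }
      }
    }
  }
  ts <- vapply(out, `[[`, integer(1), "t_start")
  te <- vapply(out, `[[`, integer(1), "t_end")
  out[order(ts, te)]
}

# ---- Markov model ----------------------------------------------------------

# Count (context, base) occurrences at order k over concatenated encoded
# sequences (NA-separated so contexts never span sequence boundaries).
# With `frames`, counts are kept per frame: array [4 bases, 4^k contexts, 3];
# without, [4, 4^k].
markov_counts <- function(enc, k, frames = NULL) {
  nctx <- 4L^k
  dims <- if (is.null(frames)) c(4L, nctx) else c(4L, nctx, 3L)
  n <- length(enc)
  if (n < k + 1L) return(array(0L, dim = dims))
  pos <- (k + 1L):n
  base <- enc[pos]
  ctx <- rep(0, length(pos))
  if (k > 0L) for (j in seq_len(k)) ctx <- ctx + enc[pos - j] * 4^(j - 1L)
  ok <- !is.na(base) & !is.na(ctx)
  if (!is.null(frames)) {
    fr <- frames[pos]
    ok <- ok & !is.na(fr)
    bin <- fr[ok] * (4 * nctx) + ctx[ok] * 4 + base[ok]
    array(tabulate(bin + 1, nbins = 3L * 4L * nctx), dim = dims)
  } else {
    bin <- ctx[ok] * 4 + base[ok]
    array(tabulate(bin + 1, nbins = 4L * nctx), dim = dims)
  }
}

# counts -> conditional probabilities with additive smoothing over the 4 bases
counts_to_probs <- function(counts, pseudocount) {
  sm <- counts + pseudocount
  tot <- apply(sm, seq_along(dim(sm))[-1L], sum)
  sweep(sm, seq_along(dim(sm))[-1L], tot, "/")
}

zero_information_model <- function(order, pseudocount) {
  structure(list(order = as.integer(order), pseudocount = pseudocount,
                 zero_information = TRUE, n_training = 0L,
                 log_odds = NULL, coding = NULL, background = NULL),
            class = "markov_coding_model")
}

#' Train the hexamer coding-potential model from pseudo-transcripts
#'
#' Training positives are the `top_n` longest complete ORFs found across the
#' pseudo-transcripts (deduplicated by exact nucleotide sequence; ties in
#' length break lexicographically, so the model is deterministic given its
#' inputs; the fixed initial ATG and the trailing stop codon are excluded
#' from the counts). The background is the k-mer-conditional composition of all
#' pseudo-transcript sequences. Counts at every order 0..`order` are kept so
#' scoring can back off near the 5' end of a sequence.
#'
#' With fewer than `min_training` training ORFs the model degrades to a
#' zero-information model (all log-odds 0, so downstream selection ranks by
#' length alone) and a warning is emitted.
#'
#' @param pts list of `pseudo_transcript` objects (or plain strings).
#' @param top_n number of longest complete ORFs used as positives.
#' @param order Markov order (5 = hexamers).
#' @param pseudocount additive smoothing applied to every count.
#' @param min_len_aa minimum peptide length of training ORFs.
#' @param min_training minimum number of training ORFs before falling back.
#' @param table NCBI translation-table number.
#' @return object of class `markov_coding_model`.
#' @export
train_model <- function(pts, top_n = 500L, order = 5L, pseudocount = 1,
                        min_len_aa = 100L, min_training = 50L, table = 1L) {
  if (!length(pts)) stop("no pseudo-transcripts to train on")
  seqs <- vapply(pts, function(p) if (is.character(p)) toupper(p) else p$sequence, "")
  orfs <- unlist(lapply(pts, function(p)
    enumerate_orfs(p, min_len_aa = min_len_aa, allow_partial = FALSE, table = table)),
    recursive = FALSE)
  nts <- unique(vapply(orfs, `[[`, "", "nt"))
  if (length(nts)) nts <- nts[order(-nchar(nts), nts)]
  nts <- utils::head(nts, top_n)
  if (length(nts) < min_training) {
    warning("only ", length(nts), " training ORFs (< ", min_training,
            "); falling back to a zero-information model")
    return(zero_information_model(order, pseudocount))
  }

  # training positives are complete ORFs; the fixed initial ATG and the
  # trailing stop codon are signals, not coding composition, and are
  # excluded from the counts (whole codons, so frame structure is kept)
  cods <- substr(nts, 4L, nchar(nts) - 3L)
  cod_enc <- unlist(lapply(cods, function(s) c(encode_dna(s), NA_integer_)))
  cod_fr <- unlist(lapply(cods, function(s) c((seq_len(nchar(s)) - 1L) %% 3L, NA_integer_)))
  bg_enc <- unlist(lapply(seqs, function(s) c(encode_dna(s), NA_integer_)))

  coding <- vector("list", order + 1L)
  background <- vector("list", order + 1L)
  log_odds <- vector("list", order + 1L)
  for (k in 0:order) {
    cp <- counts_to_probs(markov_counts(cod_enc, k, frames = cod_fr), pseudocount)
    bp <- counts_to_probs(markov_counts(bg_enc, k), pseudocount)
    coding[[k + 1L]] <- cp
    background[[k + 1L]] <- bp
    lo <- log(cp) - rep(log(bp), times = 3L)  # broadcast background over frames
    log_odds[[k + 1L]] <- array(lo, dim = dim(cp))
  }
  structure(list(order = as.integer(order), pseudocount = pseudocount,
                 zero_information = FALSE, n_training = length(nts),
                 log_odds = log_odds, coding = coding, background = background),
            class = "markov_coding_model")
}

#' @export
print.markov_coding_model <- function(x, ...) {
  if (x$zero_information)
    cat("<markov_coding_model> zero-information fallback (all log-odds 0)\n")
  else
    cat(sprintf("<markov_coding_model> order %d, %d training ORFs, pseudocount %g\n",
                x$order, x$n_training, x$pseudocount))
  invisible(x)
}

# Per-position log-odds for positions `pos` of encoded sequence `enc`, with
# frames `fr` (0..2). Contexts shorter than the model order (near a sequence
# start) back off to the lower-order tables; windows touching non-ACGT
# characters contribute 0.
score_positions <- function(model, enc, pos, fr) {
  out <- numeric(length(pos))
  if (model$zero_information) return(out)
  k_i <- pmin(pos - 1L, model$order)
  for (k in unique(k_i)) {
    sel <- which(k_i == k)
    p <- pos[sel]
    base <- enc[p]
    ctx <- rep(0, length(p))
    if (k > 0L) for (j in seq_len(k)) ctx <- ctx + enc[p - j] * 4^(j - 1L)
    ok <- !is.na(base) & !is.na(ctx)
    v <- numeric(length(p))
    if (any(ok)) {
      lo <- model$log_odds[[k + 1L]]
      v[ok] <- lo[cbind(base[ok] + 1L, ctx[ok] + 1L, fr[sel][ok] + 1L)]
    }
    out[sel] <- v
  }
  out
}

#' Score a coding sequence under the hexamer model
#'
#' Sum over positions of the frame-appropriate log-odds (nats). The score is
#' additive over in-frame concatenation: `score_orf(m, paste0(a, b)) ==
#' score_orf(m, a) + score_orf(m, b, prior = a)` when `nchar(a)` is a
#' multiple of 3 (`prior` supplies the 5' context and frame offset).
#'
#' @param model a `markov_coding_model`.
#' @param nt nucleotide sequence, length a multiple of 3.
#' @param prior optional 5' context preceding `nt`.
#' @return total log-odds score (0 for a zero-information model).
#' @export
score_orf <- function(model, nt, prior = "") {
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not a multiple of 3")
  if (n == 0L) return(0)
  if (model$zero_information) return(0)
  m <- nchar(prior)
  enc <- encode_dna(paste0(prior, nt))
  pos <- (m + 1L):(m + n)
  fr <- (pos - 1L) %% 3L
  sum(score_positions(model, enc, pos, fr))
}

# Transcript-coordinate intervals covered by the homology blocks of the
# locus members (each member block lies within a single merged block, so it
# maps to one contiguous transcript interval).
pt_homology_t <- function(pt) {
  members <- tryCatch(pt$locus$members, error = function(e) NULL)
  if (!length(members)) return(NULL)
  tb <- pt_block_table(pt)
  g2t <- function(g) {
    row <- which(tb$start <= g & tb$end >= g)[1L]
    if (is.na(row)) return(NA_integer_)
    if (pt$strand == "+") as.integer(tb$t_start[row] + (g - tb$start[row]))
    else as.integer(tb$t_start[row] + (tb$end[row] - g))
  }
  iv <- do.call(rbind, lapply(members, function(ch) ch$blocks))
  t1 <- vapply(iv$start, g2t, integer(1))
  t2 <- vapply(iv$end, g2t, integer(1))
  data.frame(t_start = pmin(t1, t2), t_end = pmax(t1, t2))
}

#' Refine ORF start codons against the homology evidence and score all ORFs
#'
#' An enumerated ORF always takes the longest ATG-initiated form of its
#' stop-to-stop segment, which can overrun the true start into the expanded
#' flanks (any stop-free upstream ATG extends it). For each ATG-initiated ORF
#' this step moves the start to the in-frame ATG nearest the 5' boundary of
#' the homology-aligned blocks overlapping the ORF — the aligned protein
#' evidence is what delineates the coding region, and the flanks exist only
#' to recover boundary codons homology did not reach. Ties (equidistant
#' up/downstream) resolve into the supported region. When the
#' pseudo-transcript carries no homology information, the start maximizing
#' the Markov log-odds of the resulting ORF is used instead (earliest ATG
#' under a zero-information model, i.e. the longest form). All returned ORFs
#' carry their final score.
#'
#' @param model a `markov_coding_model`.
#' @param pt the `pseudo_transcript` the ORFs live in.
#' @param orfs list of ORFs from [enumerate_orfs()].
#' @param refine set FALSE to score without moving any start.
#' @param table NCBI translation-table number.
#' @return list of scored `open_reading_frame` objects.
#' @export
refine_orf_starts <- function(model, pt, orfs, refine = TRUE, table = 1L) {
  if (!length(orfs)) return(orfs)
  seq <- if (is.character(pt)) toupper(pt) else pt$sequence
  enc <- encode_dna(seq)
  hom <- if (refine) pt_homology_t(pt) else NULL
  lapply(orfs, function(orf) {
    if (refine && orf$completeness %in% c("complete", "3prime_partial")) {
      n_cod <- (orf$t_end - orf$t_start + 1L) %/% 3L
      cod_start <- orf$t_start + 3L * (0:(n_cod - 1L))
      codons <- substring(seq, cod_start, cod_start + 2L)
      cand <- which(codons == "ATG")
      if (orf$completeness == "complete") cand <- cand[cand < n_cod]
      if (length(cand) > 1L) {
        best <- cand[1L]
        t_hom <- NA_integer_
        if (!is.null(hom)) {
          ov <- hom[hom$t_start <= orf$t_end & hom$t_end >= orf$t_start, , drop = FALSE]
          if (nrow(ov)) t_hom <- min(ov$t_start)
        }
        if (!is.na(t_hom)) {
          dist <- cod_start[cand] - t_hom
          best <- cand[order(abs(dist), -sign(dist))[1L]]
        } else if (!model$zero_information) {
          pos <- orf$t_start:orf$t_end
          fr <- (pos - orf$t_start) %% 3L
          v <- score_positions(model, enc, pos, fr)
          suffix <- sum(v) - c(0, cumsum(v))[3L * (cand - 1L) + 1L]
          best <- cand[order(-suffix, cand)[1L]]
        }
        if (best > 1L) {
          new_start <- orf$t_start + 3L * (best - 1L)
          orf <- orf_new(orf$pt_id, new_start, orf$t_end, orf$completeness,
                         substr(seq, new_start, orf$t_end), table)
        }
      }
    }
    # stop-terminated forms are scored on their coding part only (the stop
    # codon is not an emission of the coding model)
    coding_nt <- if (orf$completeness %in% c("complete", "5prime_partial"))
      substr(orf$nt, 1L, nchar(orf$nt) - 3L) else orf$nt
    orf$score <- score_orf(model, coding_nt)
    orf
  })
}

#' Select a non-overlapping set of ORFs for one pseudo-transcript
#'
#' Greedy selection by descending score, completeness (complete outranks
#' partial at equal score), length, then leftmost start: an ORF is retained
#' if it passes both thresholds and does not overlap any already-retained
#' ORF in transcript coordinates. Two or more retained ORFs license a
#' downstream gene split.
#'
#' @param pt the `pseudo_transcript` (unused except for sanity; may be NULL).
#' @param orfs scored ORF list.
#' @param min_score minimum log-odds score (inclusive).
#' @param min_len_aa minimum peptide length (inclusive).
#' @return list of retained ORFs, pairwise non-overlapping, in selection
#'   order; invariant under permutation of the input.
#' @export
select_orfs <- function(pt, orfs, min_score = 0, min_len_aa = 100L) {
  if (!length(orfs)) return(orfs)
  score <- vapply(orfs, `[[`, numeric(1), "score")
  if (anyNA(score)) stop("select_orfs requires scored ORFs")
  plen <- vapply(orfs, function(o) nchar(o$peptide), integer(1))
  keep <- score >= min_score & plen >= min_len_aa
  orfs <- orfs[keep]
  if (!length(orfs)) return(orfs)
  score <- score[keep]
  ts <- vapply(orfs, `[[`, integer(1), "t_start")
  te <- vapply(orfs, `[[`, integer(1), "t_end")
  partial <- vapply(orfs, function(o) o$completeness != "complete", logical(1))
  ord <- order(-score, partial, -(te - ts + 1L), ts)
  retained <- integer()
  for (i in ord) {
    if (!length(retained) ||
        all(ts[i] > te[retained] | te[i] < ts[retained]))
      retained <- c(retained, i)
  }
  orfs[retained]
}

#' Dump the full-order log-odds table as a data frame
#'
#' One row per (frame, context, base) with the log-odds value; useful for
#' inspecting what the self-trained model learned.
#'
#' @param model a trained `markov_coding_model`.
#' @return data.frame with columns frame, context, base, log_odds.
#' @export
model_table <- function(model) {
  if (model$zero_information) stop("zero-information model has no tables")
  k <- model$order
  bases <- c("A", "C", "G", "T")
  nctx <- 4L^k
  ctx_str <- vapply(0:(nctx - 1L), function(ci) {
    paste(rev(bases[(ci %/% 4^(0:(k - 1))) %% 4 + 1]), collapse = "")
  }, "")
  lo <- model$log_odds[[k + 1L]]
  data.frame(frame = rep(0:2, each = 4L * nctx),
             context = rep(rep(ctx_str, each = 4L), times = 3L),
             base = rep(bases, times = 3L * nctx),
             log_odds = as.vector(lo))
}
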