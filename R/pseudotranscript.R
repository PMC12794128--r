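# Locus construction and pseudo-transcript assembly.
#
# A pseudo-transcript is the spliced union of all homology-aligned blocks at
# one strand-aware locus: a stand-in for an mRNA lacking UTRs, with an exact
# bijective transcript<->genome coordinate map.

#' Cluster alignment chains into strand-aware loci
#'
#' Single-linkage clustering: two chains join one locus iff they share seqid
#' and strand and at least one pair of blocks overlaps by >= 1 bp
#' (block-level, not span-level, so a gene nested in another gene's intron is
#' not fused into its host's locus). Opposite-strand overlaps never merge.
#'
#' @param chains list of [alignment_chain()] objects.
#' @return list of `locus` objects sorted by (seqid, leftmost merged start);
#'   each locus carries its member chains and the coalesced union of their
#'   blocks (overlapping or book-ended intervals merged).
#' @export
cluster_chains <- function(chains) {
  if (!length(chains)) return(list())
  key <- vapply(chains, function(ch) paste(ch$seqid, ch$strand, sep = "\r"), "")
  loci <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    grp <- chains[idx]
    nb <- vapply(grp, function(ch) nrow(ch$blocks), integer(1))
    starts <- unlist(lapply(grp, function(ch) ch$blocks$start))
    ends <- unlist(lapply(grp, function(ch) ch$blocks$end))
    chain_of_block <- rep(seq_along(grp), nb)
    ir <- IRanges::IRanges(start = starts, end = ends)
    # connected components of the block-overlap graph: overlapping-only reduce
    comp_ranges <- IRanges::reduce(ir, min.gapwidth = 0L)
    comp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, comp_ranges))
    parent <- uf_new(length(grp))
    first_chain <- rep(NA_integer_, length(comp_ranges))
    for (b in seq_along(comp)) {
      ci <- chain_of_block[b]
      cc <- comp[b]
      if (is.na(first_chain[cc])) first_chain[cc] <- ci
      else parent <- uf_union(parent, first_chain[cc], ci)
    }
    roots <- vapply(seq_along(grp), function(i) uf_find(parent, i), integer(1))
    for (r in unique(roots)) {
      members <- grp[roots == r]
      blocks <- do.call(rbind, lapply(members, `[[`, "blocks"))
      merged <- IRanges::reduce(IRanges::IRanges(blocks$start, blocks$end))
      loci[[length(loci) + 1L]] <- structure(
        list(seqid = members[[1L]]$seqid, strand = members[[1L]]$strand,
             members = members,
             merged_blocks = data.frame(start = IRanges::start(merged),
                                        end = IRanges::end(merged))),
        class = "locus")
    }
  }
  seqid <- vapply(loci, `[[`, "", "seqid")
  leftmost <- vapply(loci, function(l) min(l$merged_blocks$start), integer(1))
  strand <- vapply(loci, `[[`, "", "strand")
  loci[order(seqid, leftmost, strand)]
}

#' Merge and flank-extend the blocks of one locus
#'
#' Coalesces overlapping or book-ended member blocks, then extends the two
#' outermost blocks outward by `terminal_flank` bp, clipped to contig bounds
#' and to `left_limit`/`right_limit` (the nearest block of an adjacent locus
#' on the same strand, when known). Internal block boundaries — the putative
#' splice junctions — are never altered.
#'
#' @param locus a `locus` from [cluster_chains()].
#' @param terminal_flank extension in bp (>= 0).
#' @param genome_lengths named integer vector of contig lengths.
#' @param left_limit,right_limit extension bounds (1-based inclusive).
#' @return data.frame of merged blocks (`start`, `end`).
#' @export
merge_blocks <- function(locus, terminal_flank = 300L, genome_lengths = NULL,
                         left_limit = 1L, right_limit = NULL) {
  stopifnot(terminal_flank >= 0L)
  blocks <- do.call(rbind, lapply(locus$members, `[[`, "blocks"))
  merged <- IRanges::reduce(IRanges::IRanges(blocks$start, blocks$end))
  s <- IRanges::start(merged); e <- IRanges::end(merged)
  contig_len <- if (!is.null(genome_lengths)) {
    if (!locus$seqid %in% names(genome_lengths))
      stop("contig '", locus$seqid, "' not in genome_lengths")
    as.integer(genome_lengths[[locus$seqid]])
  } else NA_integer_
  if (is.null(right_limit)) right_limit <- if (is.na(contig_len)) max(e) else contig_len
  if (!is.na(contig_len)) right_limit <- min(right_limit, contig_len)
  left_limit <- max(1L, left_limit)
  s[1L] <- max(left_limit, s[1L] - terminal_flank)
  n <- length(e)
  e[n] <- min(right_limit, e[n] + terminal_flank)
  data.frame(start = s, end = e)
}

# Apply merge_blocks across a sorted locus list, bounding each extension by
# the neighbouring locus on the same contig and strand.
expand_loci <- function(loci, terminal_flank, genome_lengths) {
  if (!length(loci)) return(loci)
  key <- vapply(loci, function(l) paste(l$seqid, l$strand, sep = "\r"), "")
  # neighbour limits come from the original homology blocks, not from the
  # neighbours' own flank extensions (extensions may share intergenic space
  # but never cross into an adjacent locus's blocks)
  orig <- lapply(loci, `[[`, "merged_blocks")
  for (k in unique(key)) {
    idx <- which(key == k)
    lm <- vapply(orig[idx], function(b) min(b$start), integer(1))
    idx <- idx[order(lm)]
    for (j in seq_along(idx)) {
      left <- if (j > 1L) max(orig[[idx[j - 1L]]]$end) + 1L else 1L
      right <- if (j < length(idx)) min(orig[[idx[j + 1L]]]$start) - 1L else NULL
      loci[[idx[j]]]$merged_blocks <- merge_blocks(
        loci[[idx[j]]], terminal_flank, genome_lengths,
        left_limit = left, right_limit = right)
    }
  }
  loci
}

#' Assemble the pseudo-transcript of a locus
#'
#' The sequence is the spliced extraction of the merged blocks in locus
#' strand orientation; the coordinate map (kept as block arithmetic, exposed
#' through [map_to_genome()] and [pt_genome_positions()]) is a strict
#' bijection between transcript positions 1..L and genome positions.
#'
#' @param locus a `locus` whose `merged_blocks` are final.
#' @param genome named character vector of contig sequences.
#' @param pt_id identifier for the pseudo-transcript.
#' @return object of class `pseudo_transcript`.
#' @export
build_pseudotranscript <- function(locus, genome, pt_id = "pt1") {
  blocks <- locus$merged_blocks
  seq <- extract_spliced_sequence(genome, blocks, locus$strand, seqid = locus$seqid)
  structure(list(pt_id = pt_id, seqid = locus$seqid, strand = locus$strand,
                 blocks = blocks[order(blocks$start), , drop = FALSE],
                 sequence = seq, length = nchar(seq), locus = locus),
            class = "pseudo_transcript")
}

#' @export
print.pseudo_transcript <- function(x, ...) {
  cat(sprintf("<pseudo_transcript> %s  %s(%s)  %d block(s), %d nt\n",
              x$pt_id, x$seqid, x$strand, nrow(x$blocks), x$length))
  invisible(x)
}

# Blocks annotated with their transcript-coordinate spans, in transcript
# (5'->3') order: ascending genomic for '+', descending for '-'.
pt_block_table <- function(pt) {
  b <- pt$blocks
  if (pt$strand == "-") b <- b[rev(seq_len(nrow(b))), , drop = FALSE]
  w <- interval_width(b)
  t_end <- cumsum(w)
  b$t_start <- t_end - w + 1L
  b$t_end <- t_end
  b
}

#' Project a transcript range onto the genome
#'
#' Returns the minimal list of genome intervals whose strand-ordered
#' concatenation corresponds exactly to transcript positions
#' `t_start..t_end`, splitting exactly at block junctions. Intervals are
#' returned in transcript (5'->3') order, i.e. descending genomic order on
#' the minus strand.
#'
#' @param pt a `pseudo_transcript`.
#' @param t_start,t_end 1-based inclusive transcript coordinates.
#' @return data.frame with columns `seqid`, `start`, `end`, `strand`.
#' @export
map_to_genome <- function(pt, t_start, t_end) {
  if (t_start < 1L || t_end > pt$length || t_start > t_end)
    stop("transcript range ", t_start, "-", t_end,
         " out of bounds for pseudo-transcript of length ", pt$length)
  tb <- pt_block_table(pt)
  sel <- tb$t_start <= t_end & tb$t_end >= t_start
  tb <- tb[sel, , drop = FALSE]
  off1 <- pmax(t_start, tb$t_start) - tb$t_start
  off2 <- pmin(t_end, tb$t_end) - tb$t_start
  if (pt$strand == "+") {
    gs <- tb$start + off1
    ge <- tb$start + off2
  } else {
    gs <- tb$end - off2
    ge <- tb$end - off1
  }
  data.frame(seqid = rep(pt$seqid, nrow(tb)), start = gs, end = ge,
             strand = rep(pt$strand, nrow(tb)), stringsAsFactors = FALSE)
}

#' Genome position of each transcript position
#'
#' The full coordinate map: element i is the genome coordinate of transcript
#' position i (strictly increasing on '+', strictly decreasing on '-').
#'
#' @param pt a `pseudo_transcript`.
#' @return integer vector of length `pt$length`.
#' @export
pt_genome_positions <- function(pt) {
  tb <- pt_block_table(pt)
  unlist(lapply(seq_len(nrow(tb)), function(i) {
    if (pt$strand == "+") tb$start[i]:tb$end[i] else tb$end[i]:tb$start[i]
  }), use.names = FALSE)
}
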