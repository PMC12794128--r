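# Ingestion of spliced protein-to-genome alignments (miniprot-style GFF3).

#' Construct an alignment chain
#'
#' One protein's spliced alignment to one locus: an ordered set of aligned
#' CDS blocks on a single contig and strand, with the aligner-reported
#' identity fraction.
#'
#' @param query_id protein identifier.
#' @param seqid,strand contig and strand of the alignment.
#' @param blocks data.frame with columns `start`, `end` (1-based inclusive),
#'   non-overlapping; sorted by start internally.
#' @param identity fraction of matching aligned residues, in [0, 1].
#' @param aln_score aligner-reported score (unitless, `NA` if absent).
#' @return object of class `alignment_chain`.
#' @export
alignment_chain <- function(query_id, seqid, strand, blocks,
                            identity, aln_score = NA_real_) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  check_intervals(blocks, paste0("blocks of ", query_id))
  if (nrow(blocks) == 0L) stop("alignment chain ", query_id, " has no blocks")
  blocks$start <- as.integer(blocks$start)
  blocks$end <- as.integer(blocks$end)
  blocks <- blocks[order(blocks$start, blocks$end), c("start", "end"), drop = FALSE]
  check_disjoint(blocks, paste0("blocks of ", query_id))
  rownames(blocks) <- NULL
  identity <- as.numeric(identity)
  if (is.na(identity) || identity < 0 || identity > 1)
    stop("identity of ", query_id, " must be in [0, 1]")
  structure(list(query_id = query_id, seqid = seqid, strand = strand,
                 blocks = blocks, identity = identity,
                 aln_score = as.numeric(aln_score)),
            class = "alignment_chain")
}

#' Parse a miniprot-style alignment GFF3 into alignment chains
#'
#' One chain is produced per mRNA record (so a protein aligned to several loci
#' yields several independent chains). The identity fraction is read from the
#' mRNA attribute named by `identity_key`; the query protein id is taken from
#' the first token of the `Target` attribute when present, else from `ID`.
#' mRNA records without CDS children are skipped with a warning.
#'
#' @param path GFF3 file as emitted by `miniprot --gff`.
#' @param identity_key attribute holding the identity (default "Identity");
#'   configurable to tolerate aligner dialect drift.
#' @return list of [alignment_chain()] objects, in file order.
#' @export
parse_alignment_gff3 <- function(path, identity_key = "Identity") {
  tab <- parse_gff3_table(path)
  if (!nrow(tab)) return(list())
  is_mrna <- tab$type == "mRNA"
  is_cds <- tab$type == "CDS"

  cds_parent <- vapply(tab$attributes[is_cds],
                       function(a) attr_get(a, "Parent") %||% NA_character_, "")
  cds_rows <- which(is_cds)
  by_parent <- split(cds_rows, cds_parent)

  chains <- list()
  for (r in which(is_mrna)) {
    attrs <- tab$attributes[[r]]
    id <- attr_get(attrs, "ID") %||% paste0("line", tab$line[r])
    target <- attr_get(attrs, "Target")
    query_id <- if (!is.null(target)) strsplit(target, "[ \t]")[[1L]][1L] else id
    ident_raw <- attr_get(attrs, identity_key)
    ident <- suppressWarnings(as.numeric(ident_raw))
    if (is.null(ident_raw) || is.na(ident))
      stop("unparseable or missing ", identity_key, " attribute for mRNA record '",
           id, "' at line ", tab$line[r])
    rows <- by_parent[[id]]
    if (is.null(rows)) {
      warning("mRNA record '", id, "' has no CDS children; chain skipped")
      next
    }
    if (length(unique(tab$seqid[rows])) != 1L || length(unique(tab$strand[rows])) != 1L)
      stop("CDS children of mRNA '", id, "' span multiple contigs/strands")
    chains[[length(chains) + 1L]] <- alignment_chain(
      query_id = query_id, seqid = tab$seqid[r], strand = tab$strand[r],
      blocks = data.frame(start = tab$start[rows], end = tab$end[rows]),
      identity = ident,
      aln_score = suppressWarnings(as.numeric(tab$score[r])))
  }
  chains
}

#' Filter alignment chains by identity
#'
#' Retains exactly the chains with identity >= `min_identity` (inclusive:
#' lowering the threshold to 0.8 admits 0.8-identity chains). Input order is
#' preserved.
#'
#' @param chains list of [alignment_chain()] objects.
#' @param min_identity fraction in [0, 1].
#' @return filtered list.
#' @export
filter_chains <- function(chains, min_identity = 0.9) {
  stopifnot(min_identity >= 0, min_identity <= 1)
  keep <- vapply(chains, function(ch) ch$identity >= min_identity, logical(1))
  chains[keep]
}
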