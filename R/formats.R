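# Gene-model containers and GFF3 / sequence plumbing.
#
# Coordinates are GFF3: 1-based, inclusive, at every external interface.
# CDS coordinates include the stop codon for complete models (miniprot /
# common annotation convention), so evaluation against such annotations is
# consistent.

#' Construct a transcript model
#'
#' A transcript model is a chain of CDS segments on one contig and strand,
#' stored in ascending genomic order with per-segment GFF3 phases.
#'
#' @param transcript_id,gene_id identifiers.
#' @param seqid contig name.
#' @param strand "+" or "-".
#' @param cds data.frame with columns `start`, `end` and optionally `phase`
#'   (in {0,1,2}); rows may be given in any order and are sorted by start.
#'   When `phase` is absent it is computed cumulatively from the 5' end
#'   assuming the first segment has phase 0.
#' @param score ORF log-odds score (nats; `NA` when unscored).
#' @param source_proteins character vector of supporting query protein ids.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, seqid, strand, cds,
                             score = NA_real_, source_proteins = character()) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L, nzchar(transcript_id))
  stopifnot(is.character(seqid), length(seqid) == 1L, nzchar(seqid))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  check_intervals(cds, paste0("CDS of ", transcript_id))
  if (nrow(cds) == 0L) stop("transcript ", transcript_id, " has no CDS")
  cds$start <- as.integer(cds$start)
  cds$end <- as.integer(cds$end)
  o <- order(cds$start, cds$end)
  cds <- cds[o, , drop = FALSE]
  check_disjoint(cds, paste0("CDS of ", transcript_id))
  if (is.null(cds$phase)) {
    cds$phase <- cds_phases(cds, strand)
  } else {
    cds$phase <- as.integer(cds$phase)
    if (any(!cds$phase %in% 0:2)) stop("phases must be 0, 1 or 2 (", transcript_id, ")")
  }
  rownames(cds) <- NULL
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 seqid = seqid, strand = strand,
                 cds = cds[, c("start", "end", "phase")],
                 score = as.numeric(score),
                 source_proteins = unique(as.character(source_proteins))),
            class = "transcript_model")
}

# GFF3 phases computed in transcript (5'->3') order for a CDS chain given in
# ascending genomic order: phase_i = (3 - cumulative_length_before_i mod 3) mod 3.
cds_phases <- function(cds, strand) {
  w <- interval_width(cds)
  if (strand == "-") w <- rev(w)
  cum <- cumsum(c(0L, w[-length(w)]))
  ph <- (3L - (cum %% 3L)) %% 3L
  if (strand == "-") ph <- rev(ph)
  ph
}

#' Total CDS length of a transcript model (nt)
#' @param tm a `transcript_model`.
#' @export
cds_length <- function(tm) sum(interval_width(tm$cds))

#' Construct a gene model
#'
#' @param gene_id identifier, unique within an annotation set.
#' @param transcripts non-empty list of [transcript_model()] objects sharing
#'   one contig and strand.
#' @return object of class `gene_model` with a `span` covering all CDS.
#' @export
gene_model <- function(gene_id, transcripts) {
  if (!length(transcripts)) stop("gene ", gene_id, " has no transcripts")
  if (inherits(transcripts, "transcript_model")) transcripts <- list(transcripts)
  seqids <- vapply(transcripts, `[[`, "", "seqid")
  strands <- vapply(transcripts, `[[`, "", "strand")
  if (length(unique(seqids)) != 1L || length(unique(strands)) != 1L)
    stop("gene ", gene_id, ": transcripts span multiple contigs/strands")
  starts <- vapply(transcripts, function(t) min(t$cds$start), integer(1))
  ends <- vapply(transcripts, function(t) max(t$cds$end), integer(1))
  for (i in seq_along(transcripts)) transcripts[[i]]$gene_id <- gene_id
  structure(list(gene_id = gene_id, transcripts = transcripts,
                 seqid = seqids[[1L]], strand = strands[[1L]],
                 start = min(starts), end = max(ends)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%d-%d(%s)  %d transcript(s)\n",
              x$gene_id, x$seqid, x$start, x$end, x$strand, length(x$transcripts)))
  invisible(x)
}

# ---- GFF3 ------------------------------------------------------------------

# Tokenize a GFF3 file into a feature table, with strict 9-column and
# attribute syntax checks that report the offending line number.
parse_gff3_table <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  ln <- which(keep)
  if (!length(ln)) {
    return(data.frame(seqid = character(), source = character(), type = character(),
                      start = integer(), end = integer(), score = character(),
                      strand = character(), phase = character(), line = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1L]
    stop(sprintf("malformed GFF3 at line %d: expected 9 tab-separated columns, found %d",
                 ln[bad], nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  tab <- data.frame(seqid = m[, 1L], source = m[, 2L], type = m[, 3L],
                    start = suppressWarnings(as.integer(m[, 4L])),
                    end = suppressWarnings(as.integer(m[, 5L])),
                    score = m[, 6L], strand = m[, 7L], phase = m[, 8L],
                    line = ln, stringsAsFactors = FALSE)
  if (anyNA(tab$start) || anyNA(tab$end)) {
    bad <- which(is.na(tab$start) | is.na(tab$end))[1L]
    stop(sprintf("malformed GFF3 at line %d: non-numeric coordinates", tab$line[bad]))
  }
  tab$attributes <- lapply(seq_along(ln), function(i)
    parse_gff3_attributes(m[i, 9L], ln[i]))
  tab
}

parse_gff3_attributes <- function(s, line) {
  toks <- strsplit(s, ";", fixed = TRUE)[[1L]]
  toks <- trimws(toks)
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(stats::setNames(character(), character()))
  eq <- regexpr("=", toks, fixed = TRUE)
  if (any(eq < 0L))
    stop(sprintf("malformed attribute column at line %d: token '%s' has no '='",
                 line, toks[eq < 0L][1L]))
  stats::setNames(substring(toks, eq + 1L), substring(toks, 1L, eq - 1L))
}

attr_get <- function(attrs, key) if (key %in% names(attrs)) attrs[[key]] else NULL

#' Read a GFF3 annotation into gene models
#'
#' Expects gene / mRNA / CDS features linked through ID and Parent attributes.
#' Every CDS must resolve to an mRNA and every mRNA to a gene; orphans are an
#' error naming the offending identifiers. Coordinates are preserved exactly
#' and the returned genes are sorted by (seqid, start).
#'
#' @param path GFF3 file.
#' @return list of [gene_model()] objects.
#' @export
read_gff3 <- function(path) {
  tab <- parse_gff3_table(path)
  if (!nrow(tab)) return(list())
  is_gene <- tab$type == "gene"
  is_mrna <- tab$type == "mRNA"
  is_cds <- tab$type == "CDS"

  gene_ids <- vapply(tab$attributes[is_gene], function(a) attr_get(a, "ID") %||% NA_character_, "")
  if (anyNA(gene_ids))
    stop("gene feature without ID attribute at line ",
         tab$line[is_gene][which(is.na(gene_ids))[1L]])
  gene_rows <- which(is_gene)
  names(gene_rows) <- gene_ids

  mrna_ids <- vapply(tab$attributes[is_mrna], function(a) attr_get(a, "ID") %||% NA_character_, "")
  mrna_parent <- vapply(tab$attributes[is_mrna], function(a) attr_get(a, "Parent") %||% NA_character_, "")
  if (anyNA(mrna_ids))
    stop("mRNA feature without ID attribute at line ",
         tab$line[is_mrna][which(is.na(mrna_ids))[1L]])
  orphan_m <- !(mrna_parent %in% gene_ids)
  if (any(orphan_m))
    stop("mRNA feature(s) with no resolvable gene parent: ",
         paste(mrna_ids[orphan_m], collapse = ", "))
  mrna_rows <- which(is_mrna)
  names(mrna_rows) <- mrna_ids

  cds_parent <- lapply(tab$attributes[is_cds], function(a) {
    p <- attr_get(a, "Parent")
    if (is.null(p)) NA_character_ else strsplit(p, ",", fixed = TRUE)[[1L]]
  })
  cds_rows <- which(is_cds)
  flat_parent <- unlist(cds_parent, use.names = FALSE)
  flat_row <- rep(cds_rows, lengths(cds_parent))
  orphan_c <- is.na(flat_parent) | !(flat_parent %in% mrna_ids)
  if (any(orphan_c)) {
    ids <- vapply(tab$attributes[flat_row[orphan_c]],
                  function(a) attr_get(a, "ID") %||% "<unnamed CDS>", "")
    stop("CDS feature(s) with no resolvable mRNA parent: ",
         paste(unique(paste0(ids, " (line ", tab$line[flat_row[orphan_c]], ")")),
               collapse = ", "))
  }

  by_mrna <- split(flat_row, flat_parent)
  genes <- list()
  for (gid in gene_ids) {
    tids <- mrna_ids[mrna_parent == gid]
    tms <- list()
    for (tid in tids) {
      rows <- by_mrna[[tid]]
      if (is.null(rows))
        stop("mRNA ", tid, " has no CDS children")
      cds <- data.frame(start = tab$start[rows], end = tab$end[rows],
                        stringsAsFactors = FALSE)
      ph <- tab$phase[rows]
      if (all(ph %in% c("0", "1", "2"))) cds$phase <- as.integer(ph)
      mr <- mrna_rows[[tid]]
      sc <- suppressWarnings(as.numeric(tab$score[mr]))
      tms[[length(tms) + 1L]] <- transcript_model(
        transcript_id = tid, gene_id = gid,
        seqid = tab$seqid[mr], strand = tab$strand[mr],
        cds = cds, score = sc)
    }
    genes[[length(genes) + 1L]] <- gene_model(gid, tms)
  }
  sort_genes(genes)
}

sort_genes <- function(genes) {
  if (length(genes) < 2L) return(genes)
  seqid <- vapply(genes, `[[`, "", "seqid")
  start <- vapply(genes, `[[`, integer(1), "start")
  gid <- vapply(genes, `[[`, "", "gene_id")
  genes[order(seqid, start, gid)]
}

#' Write gene models as GFF3
#'
#' Emits a `##gff-version 3` header (plus any caller-supplied comment lines),
#' then gene, mRNA and CDS rows linked via ID/Parent, in deterministic
#' (seqid, start, gene_id) order. CDS rows carry the phase column.
#'
#' @param genes list of [gene_model()] objects.
#' @param path output file.
#' @param header_comments optional character vector of extra `#`-prefixed
#'   header lines (e.g. the pipeline configuration echo).
#' @param source value for GFF3 column 2.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(genes, path, header_comments = character(), source = "homanno") {
  gids <- vapply(genes, `[[`, "", "gene_id")
  if (anyDuplicated(gids))
    stop("refusing to write: duplicated gene_id ", gids[duplicated(gids)][1L])
  lines <- c("##gff-version 3", header_comments)
  for (g in sort_genes(genes)) {
    lines <- c(lines, paste(g$seqid, source, "gene", g$start, g$end, ".",
                            g$strand, ".", paste0("ID=", g$gene_id), sep = "\t"))
    for (tm in g$transcripts) {
      lines <- c(lines, paste(tm$seqid, source, "mRNA",
                              min(tm$cds$start), max(tm$cds$end),
                              fmt_num(tm$score), tm$strand, ".",
                              paste0("ID=", tm$transcript_id, ";Parent=", g$gene_id),
                              sep = "\t"))
      for (i in seq_len(nrow(tm$cds))) {
        lines <- c(lines, paste(tm$seqid, source, "CDS",
                                tm$cds$start[i], tm$cds$end[i], ".",
                                tm$strand, tm$cds$phase[i],
                                paste0("ID=", tm$transcript_id, ".cds", i,
                                       ";Parent=", tm$transcript_id),
                                sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Keep only the longest isoform of each gene
#'
#' The retained transcript maximizes summed CDS length; ties break to the
#' lexicographically smallest transcript_id. Gene count never changes and the
#' operation is idempotent.
#'
#' @param genes list of [gene_model()] objects.
#' @return list of gene models, each with exactly one transcript.
#' @export
longest_isoform <- function(genes) {
  lapply(genes, function(g) {
    if (length(g$transcripts) == 1L) return(g)
    len <- vapply(g$transcripts, cds_length, integer(1))
    tid <- vapply(g$transcripts, `[[`, "", "transcript_id")
    best <- order(-len, tid)[1L]
    gene_model(g$gene_id, g$transcripts[best])
  })
}

#' Extract and splice a sequence from a genome
#'
#' Concatenates the interval substrings in ascending genomic order and
#' reverse-complements the result as a whole when `strand` is "-".
#'
#' @param genome named character vector of contig sequences (see [read_fasta()]).
#' @param intervals data.frame with columns `seqid` (optional if `seqid` given),
#'   `start`, `end`.
#' @param strand "+" or "-".
#' @param seqid contig name; defaults to the intervals' `seqid` column.
#' @return spliced nucleotide string, strand-oriented.
#' @export
extract_spliced_sequence <- function(genome, intervals, strand = "+", seqid = NULL) {
  check_intervals(intervals)
  if (is.null(seqid)) {
    seqid <- unique(intervals$seqid)
    if (length(seqid) != 1L) stop("intervals must lie on a single contig")
  }
  if (!seqid %in% names(genome)) stop("contig '", seqid, "' not found in genome")
  contig <- genome[[seqid]]
  if (nrow(intervals) && max(intervals$end) > nchar(contig))
    stop("interval beyond end of contig '", seqid, "' (length ", nchar(contig), ")")
  iv <- intervals[order(intervals$start), , drop = FALSE]
  s <- paste(substring(contig, iv$start, iv$end), collapse = "")
  if (strand == "-") s <- reverse_complement(s)
  s
}

#' Translate a CDS with the standard (or another NCBI) genetic code
#'
#' A trailing stop codon is rendered as `*`; an internal stop is reported via
#' the `internal_stop` attribute of the result. Codons containing non-ACGT
#' characters translate to `X`.
#'
#' @param cds nucleotide string, length a multiple of 3.
#' @param table NCBI translation-table number (1 = standard nuclear code).
#' @return peptide string with attribute `internal_stop` (logical).
#' @export
translate_cds <- function(cds, table = 1L) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length ", n, " is not a multiple of 3")
  if (n == 0L) return(structure("", internal_stop = FALSE))
  code <- Biostrings::getGeneticCode(as.character(table))
  codons <- substring(toupper(cds), seq.int(1L, n, 3L), seq.int(3L, n, 3L))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  structure(paste(aa, collapse = ""),
            internal_stop = any(aa[-length(aa)] == "*"))
}

# Peptide for a stop-terminated ORF: translation without the trailing '*'.
peptide_of <- function(nt, table = 1L) {
  p <- as.character(translate_cds(nt, table))
  sub("\\*$", "", p)
}
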