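# Gene-model summary statistics and base-level evaluation between two
# annotations (sensitivity / specificity a.k.a. precision / F1).

#' Summary statistics of an annotation
#'
#' Computes gene count, mean CDS segments per gene, mean CDS segment length,
#' mean summed CDS length per gene and the mono-exonic : multi-exonic ratio
#' (CDS segments stand in for exons, since homology-derived models carry no
#' UTRs). Genes are reduced to their longest isoform first if needed.
#'
#' @param genes list of [gene_model()] objects, or a GFF3 path.
#' @return object of class `annotation_stats` with fields `gene_count`,
#'   `mean_cds_per_gene`, `mean_cds_length`, `mean_cds_length_per_gene`,
#'   `mono_multi_ratio` (Inf with a warning when no multi-exonic genes) and
#'   `cds_lengths` (per-gene summed CDS length, nt).
#' @export
compute_stats <- function(genes) {
  if (is.character(genes) && length(genes) == 1L) genes <- read_gff3(genes)
  if (!length(genes)) stop("no genes: cannot compute annotation statistics")
  genes <- longest_isoform(genes)
  nseg <- vapply(genes, function(g) nrow(g$transcripts[[1L]]$cds), integer(1))
  lens <- vapply(genes, function(g) sum(interval_width(g$transcripts[[1L]]$cds)),
                 integer(1))
  n <- length(genes)
  mono <- sum(nseg == 1L)
  multi <- sum(nseg > 1L)
  if (multi == 0L) {
    warning("no multi-exonic genes; mono/multi ratio is infinite")
    ratio <- Inf
  } else ratio <- mono / multi
  structure(list(gene_count = n,
                 mean_cds_per_gene = sum(nseg) / n,
                 mean_cds_length = sum(lens) / sum(nseg),
                 mean_cds_length_per_gene = sum(lens) / n,
                 mono_multi_ratio = ratio,
                 mono_exonic = mono, multi_exonic = multi,
                 cds_lengths = lens),
            class = "annotation_stats")
}

#' @export
print.annotation_stats <- function(x, ...) {
  cat(sprintf(paste0("<annotation_stats>\n",
                     "  genes:                    %d\n",
                     "  mean CDS per gene:        %.2f\n",
                     "  mean CDS length:          %.2f nt\n",
                     "  mean CDS length per gene: %.2f nt\n",
                     "  mono:multi ratio:         %s (%d:%d)\n"),
              x$gene_count, x$mean_cds_per_gene, x$mean_cds_length,
              x$mean_cds_length_per_gene, format(round(x$mono_multi_ratio, 4)),
              x$mono_exonic, x$multi_exonic))
  invisible(x)
}

#' @export
as.data.frame.annotation_stats <- function(x, ...) {
  keys <- c("gene_count", "mean_cds_per_gene", "mean_cds_length",
            "mean_cds_length_per_gene", "mono_multi_ratio")
  data.frame(metric = keys,
             value = vapply(keys, function(k) format(x[[k]], digits = 10), ""),
             row.names = NULL)
}

# All CDS intervals of an annotation as a strand-aware GRanges.
annotation_granges <- function(genes) {
  rows <- lapply(genes, function(g) {
    do.call(rbind, lapply(g$transcripts, function(tm)
      data.frame(seqid = tm$seqid, start = tm$cds$start, end = tm$cds$end,
                 strand = tm$strand, stringsAsFactors = FALSE)))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(seqnames = tab$seqid,
                         ranges = IRanges::IRanges(tab$start, tab$end),
                         strand = tab$strand)
}

#' Base-level evaluation of a predicted annotation against a reference
#'
#' A genome base counts as coding on a given strand when covered by at least
#' one CDS on that strand; bases covered on both strands count independently
#' per strand. `tp_bases` is the size of the intersection of the predicted
#' and reference coding base sets; sensitivity = tp/ref, specificity
#' (precision) = tp/pred.
#'
#' @param pred,ref lists of [gene_model()] objects or GFF3 paths, on a shared
#'   contig namespace.
#' @return object of class `evaluation_result` with fields `sensitivity`,
#'   `specificity`, `f1`, `tp_bases`, `ref_bases`, `pred_bases` and
#'   `undefined` (TRUE with specificity NA when no bases are predicted).
#' @export
base_level_eval <- function(pred, ref) {
  if (is.character(pred) && length(pred) == 1L) pred <- read_gff3(pred)
  if (is.character(ref) && length(ref) == 1L) ref <- read_gff3(ref)
  gp <- GenomicRanges::reduce(annotation_granges(pred))
  gr <- GenomicRanges::reduce(annotation_granges(ref))
  pred_bases <- sum(IRanges::width(gp))
  ref_bases <- sum(IRanges::width(gr))
  tp <- if (length(gp) && length(gr))
    sum(IRanges::width(GenomicRanges::intersect(gp, gr))) else 0L
  if (pred_bases == 0L) {
    return(structure(list(sensitivity = 0, specificity = NA_real_, f1 = NA_real_,
                          tp_bases = 0L, ref_bases = ref_bases, pred_bases = 0L,
                          undefined = TRUE),
                     class = "evaluation_result"))
  }
  sn <- tp / ref_bases
  sp <- tp / pred_bases
  structure(list(sensitivity = sn, specificity = sp, f1 = f1_score(sn, sp),
                 tp_bases = as.integer(tp), ref_bases = as.integer(ref_bases),
                 pred_bases = as.integer(pred_bases), undefined = FALSE),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_result> (base level)\n",
                     "  sensitivity: %s   specificity: %s   F1: %s\n",
                     "  tp/ref/pred bases: %d / %d / %d\n"),
              format(round(x$sensitivity, 4)), format(round(x$specificity, 4)),
              format(round(x$f1, 4)), x$tp_bases, x$ref_bases, x$pred_bases))
  invisible(x)
}

#' F1 score: harmonic mean of sensitivity and specificity
#'
#' `F1 = (2 * Sn * Sp) / (Sn + Sp)`; defined as 0 (with a warning) when both
#' inputs are 0.
#'
#' @param sensitivity,specificity fractions in [0, 1].
#' @return the F1 score.
#' @export
f1_score <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  if (sensitivity == 0 && specificity == 0) {
    warning("sensitivity and specificity both 0; F1 defined as 0")
    return(0)
  }
  (2 * sensitivity * specificity) / (sensitivity + specificity)
}

#' Histogram of per-gene summed CDS lengths
#'
#' Bins per-gene summed CDS length (after longest-isoform reduction) into
#' `[k*bin_width, (k+1)*bin_width)` bins; counts sum to the gene count.
#'
#' @param genes list of [gene_model()] objects or a GFF3 path.
#' @param bin_width bin width in nt (> 0).
#' @return data.frame with columns `bin_start`, `bin_end` (exclusive), `count`
#'   for the non-empty bins, in ascending order.
#' @export
length_distribution <- function(genes, bin_width = 100L) {
  stopifnot(bin_width > 0L)
  if (is.character(genes) && length(genes) == 1L) genes <- read_gff3(genes)
  if (!length(genes))
    return(data.frame(bin_start = integer(), bin_end = integer(), count = integer()))
  lens <- compute_stats_lengths(genes)
  bin <- (lens %/% bin_width) * bin_width
  tab <- table(bin)
  data.frame(bin_start = as.integer(names(tab)),
             bin_end = as.integer(names(tab)) + as.integer(bin_width),
             count = as.integer(tab), row.names = NULL)
}

compute_stats_lengths <- function(genes) {
  genes <- longest_isoform(genes)
  vapply(genes, function(g) sum(interval_width(g$transcripts[[1L]]$cds)), integer(1))
}
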