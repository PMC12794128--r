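# Projection of selected ORFs to genome coordinates, locus splitting,
# filtering, deduplication, and the end-to-end pipeline.

#' Pipeline configuration
#'
#' Collects every tunable of the annotation pipeline with its default.
#' The configuration is echoed into the GFF3 header of each run.
#'
#' @param min_identity minimum alignment identity (inclusive; lower to 0.8
#'   for distantly related reference proteins).
#' @param terminal_flank bp added outward of each locus before ORF search.
#' @param min_orf_aa minimum peptide length (aa) at enumeration and filtering.
#' @param min_score minimum ORF log-odds score (nats).
#' @param markov_order order of the coding model (5 = hexamers).
#' @param train_top_n number of longest complete ORFs used for training.
#' @param pseudocount additive smoothing for model counts.
#' @param min_training_orfs below this many training ORFs the model falls
#'   back to zero information.
#' @param allow_partial report ORFs truncated by pseudo-transcript ends.
#' @param refine_starts move ATG starts to the score-maximal candidate.
#' @param identity_key attribute key holding identity in the alignment GFF3.
#' @param translation_table NCBI genetic-code table number.
#' @param id_prefix prefix for output gene ids.
#' @param seed seed for any sampling in diagnostics (the pipeline itself is
#'   deterministic).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_identity = 0.9, terminal_flank = 300L,
                            min_orf_aa = 100L, min_score = 0,
                            markov_order = 5L, train_top_n = 500L,
                            pseudocount = 1, min_training_orfs = 50L,
                            allow_partial = TRUE, refine_starts = TRUE,
                            identity_key = "Identity", translation_table = 1L,
                            id_prefix = "", seed = 1L) {
  stopifnot(min_identity >= 0, min_identity <= 1, terminal_flank >= 0,
            min_orf_aa >= 1, markov_order >= 1, train_top_n >= 1,
            pseudocount > 0, min_training_orfs >= 1)
  structure(list(min_identity = min_identity,
                 terminal_flank = as.integer(terminal_flank),
                 min_orf_aa = as.integer(min_orf_aa),
                 min_score = min_score,
                 markov_order = as.integer(markov_order),
                 train_top_n = as.integer(train_top_n),
                 pseudocount = pseudocount,
                 min_training_orfs = as.integer(min_training_orfs),
                 allow_partial = isTRUE(allow_partial),
                 refine_starts = isTRUE(refine_starts),
                 identity_key = identity_key,
                 translation_table = as.integer(translation_table),
                 id_prefix = id_prefix,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_header <- function(config) {
  vals <- vapply(config, function(v) paste(format(v, scientific = FALSE), collapse = ","), "")
  c(paste0("#!annotator homanno ",
           as.character(utils::packageVersion("homanno"))),
    paste0("#!config ", paste(names(vals), vals, sep = "=", collapse = " ")))
}

#' Project an ORF from transcript to genome coordinates
#'
#' CDS intervals come from [map_to_genome()]; phases are computed
#' cumulatively from the 5' end (`phase_i = (3 - L_before mod 3) mod 3`).
#' A projected chain translating with an internal stop indicates a
#' coordinate-map defect and is a hard error.
#'
#' @param pt the `pseudo_transcript` the ORF lives in.
#' @param orf an `open_reading_frame` within `pt`.
#' @param transcript_id,gene_id identifiers for the resulting model.
#' @param source_proteins supporting query protein ids.
#' @param table NCBI translation-table number.
#' @return a [transcript_model()].
#' @export
project_orf <- function(pt, orf, transcript_id = paste0(pt$pt_id, ".t1"),
                        gene_id = paste0(pt$pt_id, ".g1"),
                        source_proteins = character(), table = 1L) {
  iv <- map_to_genome(pt, orf$t_start, orf$t_end)   # transcript order
  w <- interval_width(iv)
  cum <- cumsum(c(0L, w[-length(w)]))
  phase <- (3L - (cum %% 3L)) %% 3L
  if (attr(translate_cds(orf$nt, table), "internal_stop"))
    stop("projected CDS of ", transcript_id,
         " translates with an internal stop: coordinate-map defect")
  cds <- data.frame(start = iv$start, end = iv$end, phase = phase)
  cds <- cds[order(cds$start), , drop = FALSE]
  transcript_model(transcript_id = transcript_id, gene_id = gene_id,
                   seqid = pt$seqid, strand = pt$strand, cds = cds,
                   score = orf$score, source_proteins = source_proteins)
}

#' Split a pseudo-transcript into one gene per retained ORF
#'
#' Where a pseudo-transcript contains several genes (overlapping genes merged
#' into one locus), each retained non-overlapping ORF becomes its own gene,
#' numbered left-to-right in genome order. Zero retained ORFs drop the locus.
#'
#' @param pt the `pseudo_transcript`.
#' @param retained_orfs output of [select_orfs()] (pairwise non-overlapping
#'   in transcript coordinates).
#' @param table NCBI translation-table number.
#' @return list of [gene_model()] objects with disjoint genomic spans.
#' @export
split_locus <- function(pt, retained_orfs, table = 1L) {
  if (!length(retained_orfs)) return(list())
  sources <- unique(vapply(pt$locus$members, `[[`, "", "query_id"))
  tms <- lapply(retained_orfs, function(orf)
    project_orf(pt, orf, source_proteins = sources, table = table))
  starts <- vapply(tms, function(tm) min(tm$cds$start), integer(1))
  tms <- tms[order(starts)]
  lapply(seq_along(tms), function(i) {
    tm <- tms[[i]]
    tm$transcript_id <- sprintf("%s.g%d.t1", pt$pt_id, i)
    gene_model(sprintf("%s.g%d", pt$pt_id, i), list(tm))
  })
}

#' Filter gene models by peptide length and score
#'
#' Retains models whose (single-transcript) peptide length is at least
#' `min_orf_aa` and whose score is at least `min_score`. Each dropped gene is
#' recorded in a rejection log with the criterion that failed.
#'
#' @param models list of [gene_model()] objects.
#' @param min_orf_aa minimum peptide length (aa).
#' @param min_score minimum ORF score.
#' @return list with elements `models` (kept) and `rejected` (data.frame:
#'   gene_id, seqid, start, end, criterion, value, threshold).
#' @export
filter_models <- function(models, min_orf_aa = 100L, min_score = 0) {
  rej <- list()
  keep <- logical(length(models))
  for (i in seq_along(models)) {
    g <- models[[i]]
    tm <- g$transcripts[[1L]]
    # peptide length: coding codons, excluding the stop of a complete model
    plen <- (cds_length(tm) %/% 3L) - 1L
    if (plen < min_orf_aa) {
      rej[[length(rej) + 1L]] <- data.frame(
        gene_id = g$gene_id, seqid = g$seqid, start = g$start, end = g$end,
        criterion = "length", value = plen, threshold = min_orf_aa)
    } else if (!is.na(tm$score) && tm$score < min_score) {
      rej[[length(rej) + 1L]] <- data.frame(
        gene_id = g$gene_id, seqid = g$seqid, start = g$start, end = g$end,
        criterion = "score", value = tm$score, threshold = min_score)
    } else keep[i] <- TRUE
  }
  rejected <- if (length(rej)) do.call(rbind, rej) else
    data.frame(gene_id = character(), seqid = character(), start = integer(),
               end = integer(), criterion = character(), value = numeric(),
               threshold = numeric())
  list(models = models[keep], rejected = rejected)
}

cds_signature <- function(g) {
  tm <- g$transcripts[[1L]]
  paste(g$seqid, g$strand,
        paste(tm$cds$start, tm$cds$end, sep = "-", collapse = ","), sep = ":")
}

#' Deduplicate gene models into a non-redundant set
#'
#' Models with an identical (seqid, strand, CDS chain) collapse to one, their
#' supporting proteins merged. Among same-strand models whose CDS chains
#' still overlap — a residual conflict — the higher-scoring (then longer,
#' then leftmost) model survives. The output is sorted by genome position
#' and renamed with sequential ids `{id_prefix}gene-N`.
#'
#' @param models list of single-transcript [gene_model()] objects.
#' @param id_prefix prefix for the sequential gene ids.
#' @return non-redundant list of gene models: no two output genes on the same
#'   strand have overlapping CDS chains.
#' @export
deduplicate <- function(models, id_prefix = "") {
  if (!length(models)) return(models)
  sig <- vapply(models, cds_signature, "")
  uniq <- list()
  for (i in seq_along(models)) {
    s <- sig[i]
    if (is.null(uniq[[s]])) uniq[[s]] <- models[[i]]
    else {
      uniq[[s]]$transcripts[[1L]]$source_proteins <- sort(unique(c(
        uniq[[s]]$transcripts[[1L]]$source_proteins,
        models[[i]]$transcripts[[1L]]$source_proteins)))
    }
  }
  models <- unname(uniq)

  score <- vapply(models, function(g) {
    s <- g$transcripts[[1L]]$score
    if (is.na(s)) -Inf else s
  }, numeric(1))
  len <- vapply(models, function(g) cds_length(g$transcripts[[1L]]), integer(1))
  start <- vapply(models, `[[`, integer(1), "start")
  seqid <- vapply(models, `[[`, "", "seqid")
  strand <- vapply(models, `[[`, "", "strand")
  ord <- order(-score, -len, seqid, start)

  kept <- list()
  kept_gr <- GenomicRanges::GRanges()
  for (i in ord) {
    g <- models[[i]]
    gr <- GenomicRanges::GRanges(
      seqnames = g$seqid,
      ranges = IRanges::IRanges(g$transcripts[[1L]]$cds$start,
                                g$transcripts[[1L]]$cds$end),
      strand = g$strand)
    if (!length(kept_gr) ||
        !any(IRanges::overlapsAny(gr, kept_gr))) {
      kept[[length(kept) + 1L]] <- g
      kept_gr <- c(kept_gr, gr)
    }
  }
  kept <- sort_genes(kept)
  for (i in seq_along(kept)) {
    gid <- sprintf("%sgene-%d", id_prefix, i)
    tm <- kept[[i]]$transcripts[[1L]]
    tm$transcript_id <- paste0(gid, ".t1")
    tm$gene_id <- gid
    kept[[i]] <- gene_model(gid, list(tm))
  }
  kept
}

#' Run the full homology-based annotation pipeline
#'
#' Composes filter -> cluster -> flank-merge -> pseudo-transcript assembly ->
#' model training -> ORF enumeration/scoring/selection -> projection ->
#' splitting -> filtering -> deduplication. The run is deterministic:
#' identical inputs and config give byte-identical outputs.
#'
#' @param genome genome FASTA path or named character vector of contigs.
#' @param alignments miniprot-style GFF3 path or a list of
#'   [alignment_chain()] objects.
#' @param config a [pipeline_config()].
#' @param out_prefix when given, writes `<prefix>.gff3`, `<prefix>.cds.fa`,
#'   `<prefix>.pep.fa`, `<prefix>.stats.tsv` and `<prefix>.rejected.tsv`.
#' @param quiet suppress per-stage progress messages.
#' @return (invisibly when writing) list with elements `genes`, `stats`,
#'   `rejected`, `model`, `config`, `cds` and `proteins` (named character
#'   vectors), and `n_chains`/`n_loci` stage counts.
#' @export
run_pipeline <- function(genome, alignments, config = pipeline_config(),
                         out_prefix = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  if (is.character(alignments) && length(alignments) == 1L)
    alignments <- parse_alignment_gff3(alignments, identity_key = config$identity_key)

  missing_ctg <- setdiff(unique(vapply(alignments, `[[`, "", "seqid")), names(genome))
  if (length(missing_ctg))
    stop("alignment contig(s) absent from genome: ",
         paste(missing_ctg, collapse = ", "))
  genome_lengths <- stats::setNames(nchar(genome), names(genome))

  say("chains in: ", length(alignments))
  chains <- filter_chains(alignments, config$min_identity)
  say("chains passing identity >= ", config$min_identity, ": ", length(chains))
  empty <- list(genes = list(), stats = NULL,
                rejected = filter_models(list())$rejected,
                model = NULL, config = config,
                cds = character(), proteins = character(),
                n_chains = length(chains), n_loci = 0L)
  if (!length(chains)) {
    warning("no alignment chains pass the identity filter; empty annotation")
    if (!is.null(out_prefix)) write_outputs(empty, out_prefix)
    return(empty)
  }

  loci <- cluster_chains(chains)
  loci <- expand_loci(loci, config$terminal_flank, genome_lengths)
  say("loci: ", length(loci))
  pts <- lapply(seq_along(loci), function(i)
    build_pseudotranscript(loci[[i]], genome, pt_id = sprintf("pt%d", i)))

  model <- withCallingHandlers(
    train_model(pts, top_n = config$train_top_n, order = config$markov_order,
                pseudocount = config$pseudocount, min_len_aa = config$min_orf_aa,
                min_training = config$min_training_orfs,
                table = config$translation_table),
    warning = function(w) { say("model: ", conditionMessage(w)) })
  say("model: ", if (model$zero_information) "zero-information fallback"
      else paste0(model$n_training, " training ORFs"))

  models <- list()
  for (pt in pts) {
    orfs <- enumerate_orfs(pt, min_len_aa = config$min_orf_aa,
                           allow_partial = config$allow_partial,
                           table = config$translation_table)
    orfs <- refine_orf_starts(model, pt, orfs, refine = config$refine_starts,
                              table = config$translation_table)
    sel <- select_orfs(pt, orfs, min_score = config$min_score,
                       min_len_aa = config$min_orf_aa)
    models <- c(models, split_locus(pt, sel, table = config$translation_table))
  }
  say("candidate gene models: ", length(models))

  flt <- filter_models(models, min_orf_aa = config$min_orf_aa,
                       min_score = config$min_score)
  genes <- deduplicate(flt$models, id_prefix = config$id_prefix)
  say("non-redundant gene models: ", length(genes))

  cds <- character(); proteins <- character()
  for (g in genes) {
    tm <- g$transcripts[[1L]]
    nt <- extract_spliced_sequence(genome, tm$cds, tm$strand, seqid = tm$seqid)
    cds[[tm$transcript_id]] <- nt
    proteins[[tm$transcript_id]] <- peptide_of(nt, config$translation_table)
  }

  res <- list(genes = genes,
              stats = if (length(genes)) compute_stats(genes) else NULL,
              rejected = flt$rejected, model = model, config = config,
              cds = cds, proteins = proteins,
              n_chains = length(chains), n_loci = length(loci))
  if (!is.null(out_prefix)) {
    write_outputs(res, out_prefix)
    return(invisible(res))
  }
  res
}

write_outputs <- function(res, out_prefix) {
  write_gff3(res$genes, paste0(out_prefix, ".gff3"),
             header_comments = config_header(res$config))
  write_fasta(res$cds, paste0(out_prefix, ".cds.fa"))
  write_fasta(res$proteins, paste0(out_prefix, ".pep.fa"))
  stats_tab <- if (!is.null(res$stats)) as.data.frame(res$stats) else
    data.frame(metric = character(), value = character())
  utils::write.table(stats_tab, paste0(out_prefix, ".stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$rejected, paste0(out_prefix, ".rejected.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_prefix)
}
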