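# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# IUPAC-aware complement; unknown characters pass through unchanged.
.IUPAC_FWD <- "ACGTUMRWSYKVHDBNacgtumrwsykvhdbn"
.IUPAC_REV <- "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn"

#' Reverse complement of a nucleotide string
#'
#' IUPAC ambiguity codes are complemented; any other character (e.g. gap
#' symbols) is preserved in place, so soft-masked or N-containing genomes
#' survive a round trip.
#'
#' @param x single nucleotide string.
#' @return the reverse-complemented string.
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) return(x)
  chartr(.IUPAC_FWD, .IUPAC_REV, intToUtf8(rev(utf8ToInt(x))))
}

# Encode A/C/G/T as 0..3; anything else (N, ambiguity codes) becomes NA so
# Markov counting and scoring skip windows touching it.
encode_dna <- function(x) {
  v <- utf8ToInt(toupper(x))
  e <- rep(NA_integer_, length(v))
  e[v == 65L] <- 0L  # A
  e[v == 67L] <- 1L  # C
  e[v == 71L] <- 2L  # G
  e[v == 84L] <- 3L  # T
  e
}

# Validate an interval data frame (columns start, end; 1-based inclusive).
check_intervals <- function(iv, what = "interval set") {
  if (!is.data.frame(iv) || !all(c("start", "end") %in% names(iv)))
    stop(what, " must be a data.frame with 'start' and 'end' columns")
  if (nrow(iv) == 0L) return(invisible(iv))
  if (any(iv$start < 1L)) stop(what, ": start positions must be >= 1")
  if (any(iv$end < iv$start)) stop(what, ": end must be >= start")
  invisible(iv)
}

# Sorted, pairwise-disjoint check (after ascending sort by start).
check_disjoint <- function(iv, what = "interval set") {
  if (nrow(iv) < 2L) return(invisible(iv))
  o <- order(iv$start, iv$end)
  s <- iv$start[o]; e <- iv$end[o]
  if (any(s[-1L] <= e[-length(e)]))
    stop(what, ": intervals overlap")
  invisible(iv)
}

interval_width <- function(iv) iv$end - iv$start + 1L

# Deterministic number formatting for writers (byte-identical outputs).
fmt_num <- function(x, digits = 4L) {
  ifelse(is.na(x) | !is.finite(x), ".", sprintf(paste0("%.", digits, "f"), x))
}

#' Read a genome (or any) FASTA file into a named character vector
#'
#' Sequence names are truncated at the first whitespace; sequences are
#' uppercased (FASTA parsing is case-insensitive; soft-masking carries no
#' meaning downstream). Non-ACGT characters are preserved and translate to
#' "X"-producing codons.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector; names become headers (and may carry
#'   free-text after the identifier).
#' @param path output file.
#' @param width line-wrap width in characters.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs))
  if (length(seqs)) stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq.int(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

# Minimal union-find used by single-linkage clustering.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}
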