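# Strand-aware extraction of fixed-width promoter windows upstream of the
# TSS.  Coordinates are 0-based half-open throughout; minus-strand promoters
# are emitted reverse-complemented (5'->3' relative to the gene) so the
# scanner treats all promoters uniformly.

#' Extract upstream promoter windows
#'
#' For a plus-strand gene with TSS at `t` (0-based) the promoter is the
#' genomic interval `[max(0, t - window), t)`; for a minus-strand gene it is
#' `[t + 1, min(L, t + 1 + window))` and the emitted sequence is the reverse
#' complement of the genomic slice.  The TSS base itself is never included.
#' Promoters running off a contig edge are truncated, kept, and their
#' shortened `effective_length` recorded.  Soft-masked (lower-case) bases
#' are upper-cased; hard-masked `N` runs are retained and never match any
#' pattern downstream.
#'
#' @param genome A named [Biostrings::DNAStringSet] (or named character
#'   vector) of contig sequences.
#' @param genes A gene-model table from [read_annotation()].
#' @param window Promoter width in bases (default 1000).
#' @return A data frame with columns `gene_id`, `contig`, `start`, `end`
#'   (0-based half-open genomic interval), `strand`, `sequence` (oriented
#'   5'->3' relative to the gene) and `effective_length`.
#' @export
extract_promoters <- function(genome, genes, window = 1000L) {
  if (!is.numeric(window) || length(window) != 1L || window < 1) {
    stop("'window' must be a positive number of bases", call. = FALSE)
  }
  window <- as.integer(window)
  if (methods::is(genome, "DNAStringSet")) {
    genome <- as.character(genome)
  }
  if (is.null(names(genome))) {
    stop("'genome' must be named by contig", call. = FALSE)
  }
  missing_contigs <- setdiff(unique(genes$contig), names(genome))
  if (length(missing_contigs) > 0L) {
    stop(sprintf("contig(s) absent from genome: %s",
                 paste(missing_contigs, collapse = ", ")), call. = FALSE)
  }
  clen <- nchar(genome)[genes$contig]
  bad_tss <- which(genes$tss < 0L | genes$tss >= clen)
  if (length(bad_tss) > 0L) {
    stop(sprintf("TSS of gene '%s' outside contig bounds",
                 genes$gene_id[bad_tss[1L]]), call. = FALSE)
  }
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0L, genes$tss - window), genes$tss + 1L)
  end <- ifelse(plus, genes$tss, pmin(clen, genes$tss + 1L + window))
  # genomic slice, 0-based half-open -> substring is 1-based inclusive
  seqs <- substring(genome[genes$contig], start + 1L, end)
  seqs <- toupper(seqs)
  if (any(!plus)) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[!plus])))
    seqs[!plus] <- rc
  }
  data.frame(
    gene_id = genes$gene_id,
    contig = genes$contig,
    start = as.integer(start),
    end = as.integer(end),
    strand = genes$strand,
    sequence = unname(seqs),
    effective_length = as.integer(end - start),
    stringsAsFactors = FALSE
  )
}
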