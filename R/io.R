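# Readers and writers for the external formats.  All coordinates are
# normalized on read to the internal 0-based, half-open convention; every
# other module consumes only the in-memory tables produced here.

IUPAC_ALPHABET <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N")

read_tsv_raw <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#", na.strings = c("NA", ""))
}

coerce_numeric_col <- function(df, col, path) {
  raw <- df[[col]]
  if (is.numeric(raw)) return(raw)
  num <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(num) & !is.na(raw))
  if (length(bad) > 0L) {
    stop(sprintf("%s: non-numeric value '%s' in column '%s' (data row %d)",
                 path, raw[bad[1L]], col, bad[1L]), call. = FALSE)
  }
  num
}

#' Read a differential-expression table
#'
#' Reads a TSV with one row per gene x tissue x comparison carrying the log2
#' fold change and p-value reported by an upstream differential-expression
#' analysis (the pipeline consumes finished tables; it does not fit the
#' expression model itself).
#'
#' @param path Path to a tab-separated file with header columns `gene_id`,
#'   `tissue`, `comparison`, `log2fc`, `p_value` and optionally `adj_p`.
#'   Lines starting with `#` are ignored.
#' @return A data frame with those columns, row order preserved.
#' @export
read_de_table <- function(path) {
  df <- read_tsv_raw(path)
  required <- c("gene_id", "tissue", "comparison", "log2fc", "p_value")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing mandatory column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df$log2fc <- coerce_numeric_col(df, "log2fc", path)
  df$p_value <- coerce_numeric_col(df, "p_value", path)
  has_adj <- "adj_p" %in% names(df)
  if (has_adj) df$adj_p <- coerce_numeric_col(df, "adj_p", path)
  bad_p <- which(!is.na(df$p_value) & (df$p_value < 0 | df$p_value > 1))
  if (length(bad_p) > 0L) {
    stop(sprintf("%s: p_value %g outside [0,1] (data row %d)", path,
                 df$p_value[bad_p[1L]], bad_p[1L]), call. = FALSE)
  }
  if (has_adj) {
    bad_a <- which(!is.na(df$adj_p) & (df$adj_p < 0 | df$adj_p > 1))
    if (length(bad_a) > 0L) {
      stop(sprintf("%s: adj_p %g outside [0,1] (data row %d)", path,
                   df$adj_p[bad_a[1L]], bad_a[1L]), call. = FALSE)
    }
  }
  key <- paste(df$gene_id, df$tissue, df$comparison, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop(sprintf("%s: duplicate (gene_id, tissue, comparison) key: %s", path,
                 gsub("\r", "/", d, fixed = TRUE)), call. = FALSE)
  }
  cols <- c(required, if (has_adj) "adj_p")
  df[, cols, drop = FALSE]
}

#' Read gene models from BED6 or GFF3
#'
#' Parses gene annotations and reduces each feature to the gene model the
#' promoter extractor needs: contig, strand, and the transcription start
#' site.  The TSS is the first transcribed base: the feature start on the
#' plus strand, the feature end on the minus strand.  All positions are
#' normalized to 0-based coordinates (BED is native; GFF3 is converted).
#'
#' @param path Path to a BED6 or GFF3 file.
#' @param dialect `"BED6"` or `"GFF3"`.
#' @return A data frame with columns `gene_id`, `contig`, `strand`, `tss`
#'   (0-based).  Duplicate gene ids keep the first occurrence with a warning.
#' @export
read_annotation <- function(path, dialect = c("BED6", "GFF3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  gr <- tryCatch(
    rtracklayer::import(path,
                        format = if (dialect == "BED6") "BED" else "GFF3"),
    error = function(e) {
      stop(sprintf("%s: malformed %s record (%s)", path, dialect,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop(sprintf("%s: strand must be '+' or '-' (found '%s')", path,
                 strand[!strand %in% c("+", "-")][1L]), call. = FALSE)
  }
  ids <- if (dialect == "BED6") {
    gr$name
  } else {
    mc <- S4Vectors::mcols(gr)
    id <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA, length(gr))
    for (alt in c("Name", "gene_id")) {
      if (alt %in% names(mc)) id[is.na(id)] <- as.character(mc[[alt]])[is.na(id)]
    }
    id
  }
  if (any(is.na(ids) | ids == "")) {
    stop(sprintf("%s: every gene record needs an identifier", path),
         call. = FALSE)
  }
  # rtracklayer yields 1-based starts/ends for both dialects; 0-based TSS is
  # start-1 on plus and end-1 on minus (last base = first transcribed base).
  tss <- ifelse(strand == "+",
                BiocGenerics::start(gr) - 1L,
                BiocGenerics::end(gr) - 1L)
  out <- data.frame(
    gene_id = as.character(ids),
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    tss = as.integer(tss),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$gene_id)) {
    dup <- unique(out$gene_id[duplicated(out$gene_id)])
    warning(sprintf("%s: duplicate gene_id(s) %s; keeping first occurrence",
                    path, paste(utils::head(dup, 5L), collapse = ", ")),
            call. = FALSE)
    out <- out[!duplicated(out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Read a genome FASTA
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  genome <- Biostrings::readDNAStringSet(path)
  # keep only the first whitespace-delimited token of each header
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Read a motif table
#'
#' Each row maps a transcription factor gene to one IUPAC consensus pattern
#' for its binding site.  Patterns are validated against the 15-letter IUPAC
#' nucleotide alphabet and upper-cased.
#'
#' @param path TSV with header columns `motif_id`, `tf_gene_id`, `pattern`.
#' @return A data frame with those columns.
#' @export
read_motifs <- function(path) {
  df <- read_tsv_raw(path)
  required <- c("motif_id", "tf_gene_id", "pattern")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing mandatory column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df$pattern <- toupper(ifelse(is.na(df$pattern), "", df$pattern))
  for (i in seq_len(nrow(df))) {
    validate_iupac(df$pattern[i], df$motif_id[i])
  }
  df[, required, drop = FALSE]
}

validate_iupac <- function(pattern, motif_id) {
  if (is.na(pattern) || nchar(pattern) < 1L) {
    stop(sprintf("motif '%s': pattern must have length >= 1", motif_id),
         call. = FALSE)
  }
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, IUPAC_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("motif '%s': character '%s' is not an IUPAC nucleotide code",
                 motif_id, bad[1L]), call. = FALSE)
  }
  invisible(pattern)
}

#' Read a gene-category table
#'
#' @param path TSV with header columns `gene_id`, `category` and optionally
#'   `role` (one of `activator`, `inhibitor`, `na`).
#' @return A data frame with columns `gene_id`, `category`, `role`.
#' @export
read_categories <- function(path) {
  df <- read_tsv_raw(path)
  missing <- setdiff(c("gene_id", "category"), names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing mandatory column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!"role" %in% names(df)) df$role <- "na"
  df$role[is.na(df$role)] <- "na"
  bad <- setdiff(unique(df$role), c("activator", "inhibitor", "na"))
  if (length(bad) > 0L) {
    stop(sprintf("%s: role must be activator/inhibitor/na (found '%s')",
                 path, bad[1L]), call. = FALSE)
  }
  df[, c("gene_id", "category", "role"), drop = FALSE]
}

#' Read an expression-signature table
#'
#' A signature lists, for each gene, the direction of expression change
#' reported by prior studies (for example age-related up- or
#' down-regulation); `na` marks genes with a known involvement but no stated
#' direction, which are excluded from concordance denominators.
#'
#' @param path TSV with header columns `gene_id`, `expected_direction`
#'   (one of `up`, `down`, `na`).
#' @return A data frame with those columns.
#' @export
read_signature <- function(path) {
  df <- read_tsv_raw(path)
  missing <- setdiff(c("gene_id", "expected_direction"), names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing mandatory column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df$expected_direction[is.na(df$expected_direction)] <- "na"
  bad <- setdiff(unique(df$expected_direction), c("up", "down", "na"))
  if (length(bad) > 0L) {
    stop(sprintf("%s: expected_direction must be up/down/na (found '%s')",
                 path, bad[1L]), call. = FALSE)
  }
  df[, c("gene_id", "expected_direction"), drop = FALSE]
}

# Shortest decimal representation that parses back to the identical double.
format_exact <- function(x) {
  out <- format(x, digits = 15L, trim = TRUE, scientific = FALSE)
  redo <- !is.na(x) & suppressWarnings(as.numeric(out)) != x
  if (any(redo)) {
    out[redo] <- format(x[redo], digits = 17L, trim = TRUE)
  }
  out[is.na(x)] <- "NA"
  out
}

#' Write a deterministic TSV report
#'
#' Writes a data frame as a tab-separated file whose bytes depend only on
#' the data and metadata supplied: numeric columns are rendered with the
#' shortest decimal representation that parses back to the identical double,
#' so a write/read round trip is lossless.  Optional run metadata (config
#' echo, seed) is emitted as leading `#` comment lines, which all readers in
#' this package skip.
#'
#' @param df A data frame.
#' @param path Output path.
#' @param metadata Optional named list echoed as `# name: value` lines.
#' @return Invisibly, `path`.
#' @export
write_tsv_report <- function(df, path, metadata = NULL) {
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop(sprintf("cannot write '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  on.exit(close(con))
  lines <- character(0)
  if (!is.null(metadata)) {
    lines <- sprintf("# %s: %s", names(metadata),
                     vapply(metadata, function(v)
                       paste(as.character(v), collapse = ","), ""))
  }
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format_exact(out[[j]])
  }
  body <- c(paste(names(out), collapse = "\t"),
            if (nrow(out) > 0L)
              do.call(paste, c(lapply(out, as.character), sep = "\t")))
  writeLines(c(lines, body), con = con, sep = "\n")
  invisible(path)
}

#' Write a deterministic JSON report
#'
#' @param x A list (converted with `auto_unbox`; numbers at full precision).
#' @param path Output path.
#' @param metadata Optional named list merged in under `run_metadata`.
#' @return Invisibly, `path`.
#' @export
write_json_report <- function(x, path, metadata = NULL) {
  if (!is.null(metadata)) x <- c(list(run_metadata = metadata), x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write promoters as FASTA and BED
#'
#' @param promoters A promoter table from [extract_promoters()].
#' @param fasta_path,bed_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the promoter table.
#' @export
write_promoters <- function(promoters, fasta_path = NULL, bed_path = NULL) {
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::DNAStringSet(promoters$sequence)
    names(seqs) <- sprintf("%s %s:%d-%d(%s)", promoters$gene_id,
                           promoters$contig, promoters$start,
                           promoters$end, promoters$strand)
    Biostrings::writeXStringSet(seqs, fasta_path)
  }
  if (!is.null(bed_path)) {
    bed <- data.frame(promoters$contig, promoters$start, promoters$end,
                      promoters$gene_id, 0L, promoters$strand)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(promoters)
}
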