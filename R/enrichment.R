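# Genome-background occurrence statistics per motif, enrichment/depletion
# calls on DE-gene promoters, and TF-target expression-direction
# concordance.

#' Genome-background occurrence profile for one motif
#'
#' Computes the mean and sample standard deviation (n-1 denominator) of the
#' per-promoter occurrence count of a motif over the promoters of all
#' annotated genes, and the resulting calling band
#' `[mean - k*sd, mean + k*sd]`.  The background deliberately includes the
#' DE genes' own promoters: they are genes of the genome (use
#' `exclude_genes` to remove them if a leave-out background is wanted).
#'
#' @param counts A `count_matrix` from [scan_promoters()] over the full gene
#'   annotation, or a named integer vector of per-promoter counts.
#' @param motif_id Motif column to profile (unneeded for a vector).
#' @param sd_multiplier Band half-width in standard deviations.
#' @param exclude_genes Optional gene ids dropped from the background.
#' @param min_length Optional minimum promoter `effective_length`; when
#'   supplied together with `promoters`, truncated promoters shorter than
#'   this are excluded from the background.
#' @param promoters Optional promoter table used with `min_length`.
#' @return A list of class `occurrence_profile` with `motif_id`,
#'   `n_promoters`, `mean`, `sd`, `lo_threshold`, `hi_threshold`.
#' @examples
#' background_profile(c(g1 = 0, g2 = 1, g3 = 2, g4 = 3, g5 = 4), "m")
#' @export
background_profile <- function(counts, motif_id = NULL, sd_multiplier = 1,
                               exclude_genes = NULL, min_length = NULL,
                               promoters = NULL) {
  if (inherits(counts, "count_matrix")) counts <- counts$total
  if (is.matrix(counts)) {
    if (is.null(motif_id)) {
      stop("'motif_id' is required when 'counts' is a matrix", call. = FALSE)
    }
    if (!motif_id %in% colnames(counts)) {
      stop(sprintf("motif '%s' not in count matrix", motif_id), call. = FALSE)
    }
    counts <- counts[, motif_id]
  } else if (is.null(motif_id)) {
    motif_id <- NA_character_
  }
  if (!is.null(exclude_genes)) {
    counts <- counts[!names(counts) %in% exclude_genes]
  }
  if (!is.null(min_length) && !is.null(promoters)) {
    keep <- promoters$gene_id[promoters$effective_length >= min_length]
    counts <- counts[names(counts) %in% keep]
  }
  n <- length(counts)
  if (n < 2L) {
    stop("background requires at least 2 promoters (SD undefined)",
         call. = FALSE)
  }
  mu <- mean(counts)
  s <- stats::sd(counts)
  structure(
    list(
      motif_id = motif_id,
      n_promoters = n,
      mean = mu,
      sd = s,
      lo_threshold = mu - sd_multiplier * s,
      hi_threshold = mu + sd_multiplier * s,
      sd_multiplier = sd_multiplier
    ),
    class = "occurrence_profile"
  )
}

#' @export
print.occurrence_profile <- function(x, ...) {
  cat(sprintf(
    "Background profile '%s': n = %d, mean = %.4g, sd = %.4g, band [%.4g, %.4g]\n",
    x$motif_id, x$n_promoters, x$mean, x$sd, x$lo_threshold, x$hi_threshold))
  invisible(x)
}

#' Background profiles for every motif in a count matrix
#'
#' @inheritParams background_profile
#' @return A named list of `occurrence_profile` objects, one per motif.
#' @export
background_profiles <- function(counts, sd_multiplier = 1,
                                exclude_genes = NULL) {
  mat <- if (inherits(counts, "count_matrix")) counts$total else counts
  profs <- lapply(colnames(mat), function(m) {
    background_profile(mat, m, sd_multiplier = sd_multiplier,
                       exclude_genes = exclude_genes)
  })
  names(profs) <- colnames(mat)
  profs
}

#' Tabulate occurrence profiles
#'
#' @param profiles A list of `occurrence_profile` objects.
#' @return A data frame with one row per motif.
#' @export
profile_table <- function(profiles) {
  if (inherits(profiles, "occurrence_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(motif_id = p$motif_id, n_promoters = p$n_promoters,
               mean = p$mean, sd = p$sd, lo_threshold = p$lo_threshold,
               hi_threshold = p$hi_threshold, stringsAsFactors = FALSE)
  }))
}

#' Call enriched and depleted promoters
#'
#' Classifies each (gene, motif) count against the motif's background band
#' with strict inequalities: `enriched` when the count is strictly above the
#' high threshold, `depleted` when strictly below the low threshold,
#' `typical` otherwise (counts exactly on a threshold are typical).
#'
#' @param counts A `count_matrix` (or gene x motif integer matrix) that
#'   contains the genes to call; usually the full-genome matrix restricted
#'   via `genes`.
#' @param profiles A named list of `occurrence_profile` objects (one per
#'   motif), computed from the full-genome matrix.
#' @param genes Optional gene ids to call (default: all rows).  Requested
#'   genes absent from the matrix (no promoter) are recorded in the
#'   `skipped_genes` attribute rather than failing.
#' @return A data frame with `gene_id`, `motif_id`, `count`, `call`;
#'   attribute `skipped_genes` lists genes without a promoter row.
#' @export
call_candidates <- function(counts, profiles, genes = NULL) {
  mat <- if (inherits(counts, "count_matrix")) counts$total else counts
  if (is.null(genes)) genes <- rownames(mat)
  genes <- unique(as.character(genes))
  skipped <- setdiff(genes, rownames(mat))
  genes <- intersect(genes, rownames(mat))
  motif_ids <- names(profiles)
  missing_prof <- setdiff(colnames(mat), motif_ids)
  mat <- mat[genes, intersect(colnames(mat), motif_ids), drop = FALSE]
  rows <- lapply(colnames(mat), function(m) {
    p <- profiles[[m]]
    cnt <- mat[, m]
    call <- ifelse(cnt > p$hi_threshold, "enriched",
                   ifelse(cnt < p$lo_threshold, "depleted", "typical"))
    data.frame(gene_id = rownames(mat), motif_id = m,
               count = as.integer(cnt), call = call,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else {
    data.frame(gene_id = character(0), motif_id = character(0),
               count = integer(0), call = character(0))
  }
  rownames(out) <- NULL
  attr(out, "skipped_genes") <- skipped
  if (length(missing_prof) > 0L) {
    warning(sprintf("no background profile for motif(s): %s",
                    paste(missing_prof, collapse = ", ")), call. = FALSE)
  }
  out
}

#' TF-target assignments by expression-direction concordance
#'
#' For each non-typical candidate call (a DE gene whose promoter is
#' enriched, or optionally depleted, for a motif), emits an assignment in
#' every tissue/comparison where both the motif's transcription factor gene
#' and the candidate target gene pass the DE filter.  The assignment is
#' concordant when the two log2-fold-change signs agree; directions are
#' always taken from the same tissue and comparison for TF and target,
#' never across tissues.  The default report keeps only concordant
#' assignments backed by an enriched promoter.
#'
#' @param calls Candidate calls from [call_candidates()].
#' @param de The full DE table (all tissues/comparisons).
#' @param motifs Motif table mapping `motif_id` to `tf_gene_id`.
#' @param config An [analysis_config()].
#' @param include_depleted Also consider depleted promoters as candidates.
#' @param concordant_only Drop discordant assignments (default `TRUE`).
#' @return A data frame with one row per retained assignment: `tf_gene_id`,
#'   `motif_id`, `target_gene_id`, `tissue`, `comparison`, `tf_direction`,
#'   `target_direction`, `candidate_call`, `concordant`.
#' @export
tf_target_concordance <- function(calls, de, motifs,
                                  config = analysis_config(),
                                  include_depleted = FALSE,
                                  concordant_only = TRUE) {
  config <- as_analysis_config(config)
  filtered <- filter_de(de, config)
  keep_calls <- c("enriched", if (include_depleted) "depleted")
  cand <- calls[calls$call %in% keep_calls, , drop = FALSE]
  rows <- list()
  for (j in seq_len(nrow(motifs))) {
    tf <- motifs$tf_gene_id[j]
    mid <- motifs$motif_id[j]
    if (!tf %in% de$gene_id) {
      warning(sprintf(
        "motif '%s': TF gene '%s' absent from the DE table; motif skipped",
        mid, tf), call. = FALSE)
      next
    }
    tf_rows <- filtered[filtered$gene_id == tf &
                          filtered$direction %in% c("up", "down"), ,
                        drop = FALSE]
    if (nrow(tf_rows) == 0L) next
    targets <- cand[cand$motif_id == mid, , drop = FALSE]
    if (nrow(targets) == 0L) next
    for (k in seq_len(nrow(tf_rows))) {
      tis <- tf_rows$tissue[k]
      cmp <- tf_rows$comparison[k]
      tgt <- filtered[filtered$tissue == tis & filtered$comparison == cmp &
                        filtered$gene_id %in% targets$gene_id &
                        filtered$direction %in% c("up", "down"), ,
                      drop = FALSE]
      if (nrow(tgt) == 0L) next
      call_of <- targets$call[match(tgt$gene_id, targets$gene_id)]
      rows[[length(rows) + 1L]] <- data.frame(
        tf_gene_id = tf, motif_id = mid, target_gene_id = tgt$gene_id,
        tissue = tis, comparison = cmp,
        tf_direction = tf_rows$direction[k],
        target_direction = tgt$direction,
        candidate_call = call_of,
        concordant = tgt$direction == tf_rows$direction[k],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else {
    data.frame(tf_gene_id = character(0), motif_id = character(0),
               target_gene_id = character(0), tissue = character(0),
               comparison = character(0), tf_direction = character(0),
               target_direction = character(0),
               candidate_call = character(0), concordant = logical(0))
  }
  if (concordant_only) out <- out[out$concordant, , drop = FALSE]
  out <- out[order(out$tf_gene_id, out$motif_id, out$tissue,
                   out$comparison, out$target_gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
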