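# Differential-expression set analysis: threshold filtering, comparison
# overlaps, category up/down summaries, and signature concordance.

#' Filter a differential-expression table
#'
#' Applies the significance and effect-size thresholds: a record passes when
#' its p-value is at or below `p_cutoff` and its |log2 fold change| is at or
#' above `lfc_cutoff` (both boundaries inclusive).  Direction is the sign of
#' the log2 fold change; a passing record with log2fc exactly 0 (possible
#' only when `lfc_cutoff` is 0) is direction `"none"` and belongs to neither
#' the up nor the down set.
#'
#' @param records A DE table as returned by [read_de_table()].
#' @param config An [analysis_config()]; `use_adjusted_p` selects the
#'   `adj_p` column instead of the raw `p_value`.
#' @return The passing rows with an added `direction` column
#'   (`"up"`/`"down"`/`"none"`).
#' @export
filter_de <- function(records, config = analysis_config()) {
  config <- as_analysis_config(config)
  p <- if (config$use_adjusted_p) {
    if (!"adj_p" %in% names(records)) {
      stop("'use_adjusted_p' requires an 'adj_p' column", call. = FALSE)
    }
    records$adj_p
  } else {
    records$p_value
  }
  pass <- !is.na(p) & !is.na(records$log2fc) &
    p <= config$p_cutoff & abs(records$log2fc) >= config$lfc_cutoff
  out <- records[pass, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up",
                          ifelse(out$log2fc < 0, "down", "none"))
  rownames(out) <- NULL
  out
}

#' Up/down gene sets for one tissue and comparison
#'
#' @param filtered Output of [filter_de()].
#' @param tissue,comparison Labels selecting one stratum.
#' @return A list with `tissue`, `comparison`, `up` and `down` (disjoint
#'   character vectors of gene ids).
#' @export
de_gene_set <- function(filtered, tissue, comparison) {
  sel <- filtered$tissue == tissue & filtered$comparison == comparison
  sub <- filtered[sel, , drop = FALSE]
  list(
    tissue = tissue,
    comparison = comparison,
    up = unique(sub$gene_id[sub$direction == "up"]),
    down = unique(sub$gene_id[sub$direction == "down"])
  )
}

#' Partition two gene sets into exclusive and shared parts
#'
#' The Venn-style partition used to compare differential expression between
#' tissues or age comparisons: genes only in A, only in B, and common to
#' both.  The three parts are pairwise disjoint and conserve the input
#' sizes: |a_only| + |common| = |A| and |b_only| + |common| = |B|.
#'
#' @param a,b Character vectors of gene ids (duplicates ignored).
#' @return A list of class `overlap_partition` with `a_only`, `b_only`,
#'   `common`.
#' @examples
#' overlap_sets(c("a", "b", "c"), c("b", "c", "d"))
#' @export
overlap_sets <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  structure(
    list(
      a_only = setdiff(a, b),
      b_only = setdiff(b, a),
      common = intersect(a, b)
    ),
    class = "overlap_partition"
  )
}

#' @export
print.overlap_partition <- function(x, ...) {
  cat(sprintf("Overlap partition: %d A-only, %d common, %d B-only\n",
              length(x$a_only), length(x$common), length(x$b_only)))
  invisible(x)
}

#' Direction-aware overlap of two DE gene sets
#'
#' Like [overlap_sets()] but a gene is shared only when it is differentially
#' expressed in the same direction in both sets.
#'
#' @param set_a,set_b Lists with `up`/`down` components
#'   (see [de_gene_set()]).
#' @return An `overlap_partition` over direction-tagged gene ids.
#' @export
overlap_sets_directional <- function(set_a, set_b) {
  tag <- function(s) c(paste0(s$up, "|up"), paste0(s$down, "|down"))
  overlap_sets(tag(set_a), tag(set_b))
}

#' Summarize a DE gene set by functional category
#'
#' Counts up- and down-regulated genes per category (optionally split by the
#' regulatory role recorded in the category map, e.g. cell-cycle activators
#' vs. inhibitors) and reports the percentage down.  Genes in the DE set
#' that are absent from the category map are gathered in an `unassigned`
#' bucket.  Because the denominator behind published percent-down summaries
#' can be read either way, two are reported: `pct_down` over the DE genes of
#' the category, and, when `universe` is supplied, `pct_down_universe` over
#' all category genes present on the analyzed expression table.
#'
#' @param de_set A list with `up` and `down` gene-id vectors.
#' @param categories A data frame from [read_categories()].
#' @param universe Optional character vector of all gene ids measured on the
#'   table (enables the second denominator).
#' @return A data frame with one row per (category, role).
#' @export
summarize_categories <- function(de_set, categories, universe = NULL) {
  genes <- data.frame(
    gene_id = c(de_set$up, de_set$down),
    direction = c(rep("up", length(de_set$up)),
                  rep("down", length(de_set$down))),
    stringsAsFactors = FALSE
  )
  if (nrow(genes) == 0L) {
    return(data.frame(category = character(0), role = character(0),
                      n_up = integer(0), n_down = integer(0),
                      pct_down = numeric(0)))
  }
  m <- merge(genes, categories, by = "gene_id", all.x = TRUE)
  m$category[is.na(m$category)] <- "unassigned"
  m$role[is.na(m$role)] <- "na"
  key <- interaction(m$category, m$role, drop = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(k) {
    g <- m[key == k, , drop = FALSE]
    n_up <- sum(g$direction == "up")
    n_down <- sum(g$direction == "down")
    data.frame(category = g$category[1L], role = g$role[1L],
               n_up = n_up, n_down = n_down,
               pct_down = 100 * n_down / (n_up + n_down),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(universe)) {
    n_universe <- vapply(seq_len(nrow(out)), function(i) {
      cat_genes <- categories$gene_id[categories$category == out$category[i] &
                                        categories$role == out$role[i]]
      length(intersect(unique(cat_genes), universe))
    }, integer(1))
    out$n_universe <- n_universe
    out$pct_down_universe <- ifelse(n_universe > 0,
                                    100 * out$n_down / n_universe, NA_real_)
  }
  out <- out[order(out$category, out$role), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Concordance between observed DE directions and a reported signature
#'
#' Evaluates, among the genes that pass the DE filter and have a directional
#' expectation in the signature (`up` or `down`; `na` entries are excluded
#' from the denominator), how many change in the expected direction.  A gene
#' whose log2 fold change is exactly zero is counted as inconsistent with
#' any expected direction.
#'
#' @param records DE records, typically restricted to one tissue and
#'   comparison (pass `tissue`/`comparison` to restrict here).
#' @param signature A data frame from [read_signature()].
#' @param config An [analysis_config()].
#' @param tissue,comparison Optional labels to restrict `records` first.
#' @return A list of class `concordance_result` with `n_consistent`,
#'   `n_evaluated`, `fraction`, and the per-gene `detail` table.
#' @export
signature_concordance <- function(records, signature,
                                  config = analysis_config(),
                                  tissue = NULL, comparison = NULL) {
  if (!is.null(tissue)) records <- records[records$tissue %in% tissue, ,
                                           drop = FALSE]
  if (!is.null(comparison)) records <- records[records$comparison %in%
                                                 comparison, , drop = FALSE]
  filtered <- filter_de(records, config)
  sig <- signature[signature$expected_direction %in% c("up", "down"), ,
                   drop = FALSE]
  m <- merge(filtered, sig, by = "gene_id")
  consistent <- m$direction == m$expected_direction
  res <- list(
    n_consistent = sum(consistent),
    n_evaluated = nrow(m),
    fraction = if (nrow(m) > 0L) sum(consistent) / nrow(m) else NA_real_,
    detail = data.frame(gene_id = m$gene_id, tissue = m$tissue,
                        comparison = m$comparison, log2fc = m$log2fc,
                        observed = m$direction, expected = m$expected_direction,
                        consistent = consistent, stringsAsFactors = FALSE)
  )
  structure(res, class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Signature concordance: %d of %d genes consistent (%.1f%%)\n",
              x$n_consistent, x$n_evaluated,
              if (x$n_evaluated > 0) 100 * x$fraction else NA_real_))
  invisible(x)
}
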