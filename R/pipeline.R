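# End-to-end orchestration: DE filtering -> promoter extraction -> motif
# scanning -> background profiling -> candidate calling -> TF-target
# concordance -> set summaries, under a single JSON configuration with all
# randomness flowing from one seed.  Reports go to files; structured stage
# logs go to standard error.

log_stage <- function(fmt, ...) {
  message(sprintf(paste0("[tfbscan] ", fmt), ...))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in dependency order and writes deterministic
#' reports: identical config and inputs produce byte-identical report
#' files.  Inputs are checked before any stage runs; a stage failure stops
#' with the stage name while earlier outputs remain on disk.
#'
#' Config keys (flat JSON or list): `de_table`, `genome`, `annotation`,
#' `annotation_dialect` (`BED6`/`GFF3`), `motifs`, optional `categories`
#' and `signature`, `out_dir`, plus the [analysis_config()] fields
#' (`p_cutoff`, `use_adjusted_p`, `lfc_cutoff`, `promoter_window`,
#' `strands`, `sd_multiplier`, `seed`).
#'
#' @param config Path to a JSON config file, or an equivalent named list.
#' @return Invisibly, the run manifest (config snapshot, input digests,
#'   stage timings, output paths), also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  required <- c("de_table", "genome", "annotation", "motifs", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0L) {
    stop(sprintf("config missing key(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  acfg <- as_analysis_config(config)
  dialect <- if (is.null(config$annotation_dialect)) "BED6" else
    config$annotation_dialect

  # pre-flight: every configured input must exist before any stage runs
  inputs <- unlist(config[intersect(
    c("de_table", "genome", "annotation", "motifs", "categories",
      "signature"), names(config))])
  absent <- inputs[!file.exists(inputs)]
  if (length(absent) > 0L) {
    stop(sprintf("input file(s) not found: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  meta <- list(tool = "tfbscan", version = pkg_version(),
               seed = acfg$seed, p_cutoff = acfg$p_cutoff,
               use_adjusted_p = acfg$use_adjusted_p,
               lfc_cutoff = acfg$lfc_cutoff,
               promoter_window = acfg$promoter_window,
               strands = acfg$strands, sd_multiplier = acfg$sd_multiplier)
  timings <- list()
  outputs <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  de <- stage("read-inputs", read_de_table(config$de_table))
  genome <- read_genome(config$genome)
  genes <- read_annotation(config$annotation, dialect = dialect)
  motifs <- read_motifs(config$motifs)
  log_stage("read %d DE records, %d genes, %d motifs, %d contigs",
            nrow(de), nrow(genes), nrow(motifs), length(genome))

  filtered <- stage("filter-de", filter_de(de, acfg))
  outputs$de_filtered <- file.path(out_dir, "de_filtered.tsv")
  write_tsv_report(filtered, outputs$de_filtered, metadata = meta)
  log_stage("filter-de: %d of %d records pass", nrow(filtered), nrow(de))

  promoters <- stage("extract-promoters",
                     extract_promoters(genome, genes,
                                       window = acfg$promoter_window))
  outputs$promoters_bed <- file.path(out_dir, "promoters.bed")
  outputs$promoters_fasta <- file.path(out_dir, "promoters.fa")
  write_promoters(promoters, outputs$promoters_fasta, outputs$promoters_bed)
  log_stage("extract-promoters: %d promoters", nrow(promoters))

  counts <- stage("scan", scan_promoters(promoters, motifs,
                                         strands = acfg$strands))
  outputs$counts <- file.path(out_dir, "motif_counts.tsv")
  write_tsv_report(
    data.frame(gene_id = rownames(counts$total), counts$total,
               check.names = FALSE, stringsAsFactors = FALSE),
    outputs$counts, metadata = meta)
  log_stage("scan: %d x %d count matrix", nrow(counts$total),
            ncol(counts$total))

  profiles <- stage("background",
                    background_profiles(counts,
                                        sd_multiplier = acfg$sd_multiplier))
  outputs$profiles <- file.path(out_dir, "background_profiles.tsv")
  write_tsv_report(profile_table(profiles), outputs$profiles,
                   metadata = meta)

  de_genes <- unique(filtered$gene_id)
  calls <- stage("candidates", call_candidates(counts, profiles,
                                               genes = de_genes))
  outputs$candidates <- file.path(out_dir, "candidates.tsv")
  write_tsv_report(calls, outputs$candidates, metadata = c(
    meta, list(skipped_genes = length(attr(calls, "skipped_genes")),
               note = paste("band calling on raw occurrence counts;",
                            "no multiple-testing correction applied"))))
  log_stage("candidates: %d calls (%d genes without promoter skipped)",
            nrow(calls), length(attr(calls, "skipped_genes")))

  targets <- stage("targets",
                   tf_target_concordance(calls, de, motifs, acfg))
  outputs$targets <- file.path(out_dir, "target_assignments.tsv")
  write_tsv_report(targets, outputs$targets, metadata = meta)
  log_stage("targets: %d concordant enriched assignments", nrow(targets))

  summaries <- stage("summarize", {
    out <- list()
    tiss <- unique(de$tissue)
    if (length(tiss) >= 2L) {
      out$overlaps <- do.call(rbind, lapply(unique(de$comparison),
                                            function(cmp) {
        sa <- de_gene_set(filtered, tiss[1L], cmp)
        sb <- de_gene_set(filtered, tiss[2L], cmp)
        part <- overlap_sets(c(sa$up, sa$down), c(sb$up, sb$down))
        data.frame(comparison = cmp, tissue_a = tiss[1L],
                   tissue_b = tiss[2L], a_only = length(part$a_only),
                   common = length(part$common),
                   b_only = length(part$b_only), stringsAsFactors = FALSE)
      }))
    }
    if (!is.null(config$categories)) {
      categories <- read_categories(config$categories)
      out$category_summary <- do.call(rbind, lapply(
        unique(paste(filtered$tissue, filtered$comparison, sep = "\r")),
        function(k) {
          parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
          s <- de_gene_set(filtered, parts[1L], parts[2L])
          cs <- summarize_categories(s, categories,
                                     universe = unique(de$gene_id))
          if (nrow(cs) == 0L) return(NULL)
          cbind(data.frame(tissue = parts[1L], comparison = parts[2L],
                           stringsAsFactors = FALSE), cs)
        }))
    }
    if (!is.null(config$signature)) {
      signature <- read_signature(config$signature)
      out$concordance <- lapply(unique(de$tissue), function(t) {
        r <- signature_concordance(de, signature, acfg, tissue = t)
        list(tissue = t, n_consistent = r$n_consistent,
             n_evaluated = r$n_evaluated, fraction = r$fraction)
      })
    }
    out
  })
  if (!is.null(summaries$overlaps)) {
    outputs$overlaps <- file.path(out_dir, "overlaps.tsv")
    write_tsv_report(summaries$overlaps, outputs$overlaps, metadata = meta)
  }
  if (!is.null(summaries$category_summary)) {
    outputs$category_summary <- file.path(out_dir, "category_summary.tsv")
    write_tsv_report(summaries$category_summary, outputs$category_summary,
                     metadata = meta)
  }
  if (!is.null(summaries$concordance)) {
    outputs$concordance <- file.path(out_dir, "concordance.json")
    write_json_report(list(concordance = summaries$concordance),
                      outputs$concordance, metadata = meta)
  }

  manifest <- list(
    config = meta,
    inputs = as.list(tools::md5sum(inputs)),
    stage_timings_s = timings,
    outputs = outputs
  )
  outputs$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, outputs$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  log_stage("done: %d output files in %s", length(outputs), out_dir)
  invisible(manifest)
}

pkg_version <- function() {
  as.character(utils::packageVersion("tfbscan"))
}
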