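# Synthetic-data generators.  These emulate the statistical structure the
# pipeline assumes — a multi-contig genome with annotated genes whose
# promoters carry Poisson-distributed planted motif occurrences, and a
# group-design expression table with planted log2 effects — so that every
# stage can be validated against recorded truth without external data.

#' Configuration for a synthetic genome
#'
#' @param n_genes Number of genes (>= 2).
#' @param contigs Number of contigs; genes are spread evenly across them.
#' @param promoter_window Promoter width in bases; must be at least the
#'   motif length.
#' @param gc_content Background GC fraction in (0, 1).
#' @param lambda_bg Mean planted motif occurrences per background promoter
#'   (Poisson).
#' @param target_gene_ids Gene ids designated as targets (subset of
#'   `gene_1 ... gene_n`).
#' @param lambda_target Mean planted occurrences per target promoter;
#'   must be >= `lambda_bg`.
#' @param motif A one-row motif definition (`motif_id`, `tf_gene_id`,
#'   `pattern`); the default is an 8-mer chosen to be non-palindromic and
#'   non-self-overlapping so planted copies are counted once each.
#' @param seed Integer seed; all outputs are pure functions of the config.
#' @return A list of class `synth_genome_config`.
#' @export
synth_genome_config <- function(n_genes = 100L,
                                contigs = 2L,
                                promoter_window = 1000L,
                                gc_content = 0.5,
                                lambda_bg = 1,
                                target_gene_ids = character(0),
                                lambda_target = 5,
                                motif = data.frame(
                                  motif_id = "M1",
                                  tf_gene_id = "tf_1",
                                  pattern = "TGACTCAG",
                                  stringsAsFactors = FALSE),
                                seed = 1L) {
  if (n_genes < 2L) stop("'n_genes' must be >= 2", call. = FALSE)
  if (gc_content <= 0 || gc_content >= 1) {
    stop("'gc_content' must be in (0, 1)", call. = FALSE)
  }
  if (lambda_bg < 0) stop("'lambda_bg' must be >= 0", call. = FALSE)
  if (lambda_target < lambda_bg) {
    stop("'lambda_target' must be >= 'lambda_bg'", call. = FALSE)
  }
  validate_iupac(toupper(motif$pattern[1L]), motif$motif_id[1L])
  if (promoter_window < nchar(motif$pattern[1L])) {
    stop("'promoter_window' must be at least the motif length",
         call. = FALSE)
  }
  structure(
    list(n_genes = as.integer(n_genes), contigs = as.integer(contigs),
         promoter_window = as.integer(promoter_window),
         gc_content = gc_content, lambda_bg = lambda_bg,
         target_gene_ids = as.character(target_gene_ids),
         lambda_target = lambda_target, motif = motif,
         seed = as.integer(seed)),
    class = "synth_genome_config"
  )
}

sample_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# realize a degenerate pattern as a concrete instance
realize_pattern <- function(allowed) {
  vapply(allowed, function(s) if (length(s) == 1L) s else sample(s, 1L), "")
}

# non-overlapping 0-based offsets for k instances of length L in [0, w - L]
draw_offsets <- function(k, w, L, max_tries = 200L) {
  if (k == 0L) return(integer(0))
  if (k * L > w) stop("promoter too small to hold planted instances",
                      call. = FALSE)
  for (try in seq_len(max_tries)) {
    off <- sort(sample.int(w - L + 1L, k, replace = FALSE) - 1L)
    if (k == 1L || all(diff(off) >= L)) return(off)
  }
  stop("could not place non-overlapping motif instances", call. = FALSE)
}

#' Generate a synthetic genome with planted motif occurrences
#'
#' Builds a multi-contig genome of i.i.d. bases at the requested GC
#' content, places genes on random strands with full promoter clearance,
#' and implants, per gene, a Poisson-distributed number of concrete motif
#' instances (lambda_bg for background genes, lambda_target for designated
#' targets) at uniform non-overlapping offsets within the promoter window,
#' each on a uniformly chosen strand, with degenerate positions resolved
#' uniformly over their allowed bases.  The truth table records every
#' implant.
#'
#' @param config A [synth_genome_config()].
#' @return A list with `genome` ([Biostrings::DNAStringSet]), `annotation`
#'   (gene-model data frame as from [read_annotation()]), `truth` (one row
#'   per implant: `gene_id`, `offset` within the oriented promoter,
#'   `strand`, `instance`), `n_implanted` (named per-gene counts) and the
#'   `motif` definition.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synth_genome_config"))
  withr::with_seed(config$seed, generate_genome_impl(config))
}

generate_genome_impl <- function(config) {
  w <- config$promoter_window
  cp <- compile_pattern(toupper(config$motif$pattern[1L]),
                        config$motif$motif_id[1L])
  L <- cp$length
  slot <- w + 51L              # promoter + TSS base + 50 bp spacer
  per_contig <- diff(round(seq(0, config$n_genes,
                               length.out = config$contigs + 1L)))
  gene_ids <- paste0("gene_", seq_len(config$n_genes))
  is_target <- gene_ids %in% config$target_gene_ids

  contig_seqs <- character(config$contigs)
  ann <- vector("list", config$n_genes)
  truth <- list()
  n_impl <- integer(config$n_genes)
  gi <- 0L
  for (ci in seq_len(config$contigs)) {
    n_here <- per_contig[ci]
    clen <- n_here * slot + 50L
    bases <- sample_bases(clen, config$gc_content)
    for (k in seq_len(n_here)) {
      gi <- gi + 1L
      o <- (k - 1L) * slot + 25L          # slot-local promoter anchor
      strand <- sample(c("+", "-"), 1L)
      lambda <- if (is_target[gi]) config$lambda_target else config$lambda_bg
      n_inst <- stats::rpois(1L, lambda)
      # oriented promoter: fresh background, then implants
      prom <- sample_bases(w, config$gc_content)
      if (n_inst > 0L) {
        offs <- draw_offsets(n_inst, w, L)
        for (off in offs) {
          inst <- realize_pattern(cp$allowed)
          inst_strand <- sample(c("+", "-"), 1L)
          placed <- if (inst_strand == "+") inst else {
            rev(chartr("ACGT", "TGCA", inst))
          }
          prom[(off + 1L):(off + L)] <- placed
          truth[[length(truth) + 1L]] <- data.frame(
            gene_id = gene_ids[gi], offset = off, strand = inst_strand,
            instance = paste(inst, collapse = ""), stringsAsFactors = FALSE)
        }
        n_impl[gi] <- n_inst
      }
      if (strand == "+") {
        tss <- o + w                       # promoter = [o, o + w)
        bases[(o + 1L):(o + w)] <- prom
      } else {
        tss <- o                           # promoter = [o + 1, o + 1 + w)
        bases[(o + 2L):(o + 1L + w)] <- rev(chartr("ACGT", "TGCA", prom))
      }
      ann[[gi]] <- data.frame(gene_id = gene_ids[gi],
                              contig = paste0("contig_", ci),
                              strand = strand, tss = tss,
                              stringsAsFactors = FALSE)
    }
    contig_seqs[ci] <- paste(bases, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(contig_seqs)
  names(genome) <- paste0("contig_", seq_len(config$contigs))
  truth_df <- if (length(truth) > 0L) do.call(rbind, truth) else {
    data.frame(gene_id = character(0), offset = integer(0),
               strand = character(0), instance = character(0))
  }
  names(n_impl) <- gene_ids
  list(genome = genome, annotation = do.call(rbind, ann), truth = truth_df,
       n_implanted = n_impl, motif = config$motif)
}

#' Configuration for a synthetic expression table
#'
#' @param genes Character vector of gene ids.
#' @param tissues Tissue labels (default `thymus`, `spleen`).
#' @param comparisons Age-comparison labels (default `y-m`, `y-o`, `m-o`:
#'   young vs mature, young vs old, mature vs old).
#' @param planted Data frame with columns `gene_id`, `tissue`,
#'   `comparison`, `direction` (`up`/`down`); every other stratum is null.
#' @param effect_size Planted shift in log2 units (default 1).
#' @param n_per_group Animals per age group (default 3; must be >= 2 when
#'   `noise_sd > 0`).
#' @param noise_sd Per-sample log2 noise SD (default 0.3; 0 gives the
#'   noise-free degenerate table).
#' @param baseline Baseline log2 expression (cancels in the fold change).
#' @param seed Integer seed.
#' @return A list of class `synth_expr_config`.
#' @export
synth_expr_config <- function(genes,
                              tissues = c("thymus", "spleen"),
                              comparisons = c("y-m", "y-o", "m-o"),
                              planted = NULL,
                              effect_size = 1,
                              n_per_group = 3L,
                              noise_sd = 0.3,
                              baseline = 8,
                              seed = 1L) {
  if (effect_size < 0) stop("'effect_size' must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (noise_sd > 0 && n_per_group < 2L) {
    stop("'n_per_group' must be >= 2 when 'noise_sd' > 0", call. = FALSE)
  }
  if (is.null(planted)) {
    planted <- data.frame(gene_id = character(0), tissue = character(0),
                          comparison = character(0), direction = character(0),
                          stringsAsFactors = FALSE)
  }
  bad <- setdiff(unique(planted$direction), c("up", "down"))
  if (length(bad) > 0L) {
    stop(sprintf("planted direction must be up/down (found '%s')", bad[1L]),
         call. = FALSE)
  }
  structure(
    list(genes = as.character(genes), tissues = tissues,
         comparisons = comparisons, planted = planted,
         effect_size = effect_size, n_per_group = as.integer(n_per_group),
         noise_sd = noise_sd, baseline = baseline, seed = as.integer(seed)),
    class = "synth_expr_config"
  )
}

#' Generate a synthetic differential-expression table
#'
#' For every gene x tissue x comparison, simulates two groups of
#' `n_per_group` log2-expression values as Normal(baseline, noise_sd), adds
#' `+effect_size` (up) or `-effect_size` (down) to the second group for
#' planted strata, and reports the difference of group means as `log2fc`
#' with the two-sided two-sample t-test p-value.  With `noise_sd = 0` the
#' table is exact: planted strata get their exact effect and p = 0, null
#' strata get log2fc = 0 and p = 1.
#'
#' @param config A [synth_expr_config()].
#' @return A DE data frame (`gene_id`, `tissue`, `comparison`, `log2fc`,
#'   `p_value`) with the planted truth attached as attribute `"truth"`.
#' @export
generate_de_table <- function(config) {
  stopifnot(inherits(config, "synth_expr_config"))
  withr::with_seed(config$seed, generate_de_table_impl(config))
}

generate_de_table_impl <- function(config) {
  grid <- expand.grid(gene_id = config$genes, tissue = config$tissues,
                      comparison = config$comparisons,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pl_key <- paste(config$planted$gene_id, config$planted$tissue,
                  config$planted$comparison, sep = "\r")
  key <- paste(grid$gene_id, grid$tissue, grid$comparison, sep = "\r")
  dir <- config$planted$direction[match(key, pl_key)]
  delta <- ifelse(is.na(dir), 0,
                  ifelse(dir == "up", config$effect_size,
                         -config$effect_size))
  n <- config$n_per_group
  if (config$noise_sd == 0) {
    grid$log2fc <- delta
    grid$p_value <- ifelse(is.na(dir), 1, 0)
  } else {
    res <- vapply(delta, function(d) {
      g1 <- stats::rnorm(n, config$baseline, config$noise_sd)
      g2 <- stats::rnorm(n, config$baseline + d, config$noise_sd)
      tt <- stats::t.test(g2, g1, var.equal = TRUE)
      c(mean(g2) - mean(g1), tt$p.value)
    }, numeric(2))
    grid$log2fc <- res[1L, ]
    grid$p_value <- res[2L, ]
  }
  attr(grid, "truth") <- data.frame(
    gene_id = grid$gene_id, tissue = grid$tissue,
    comparison = grid$comparison,
    direction = ifelse(is.na(dir), "null", dir),
    stringsAsFactors = FALSE)
  grid
}

#' Materialize a complete synthetic demo dataset on disk
#'
#' Writes, into one directory, every input the pipeline reads: a genome
#' FASTA, a BED6 gene annotation, a motif TSV, a DE TSV, category and
#' signature TSVs, the implant/expression truth tables, and a ready-to-run
#' pipeline `config.json`.  Planted structure: the motif's TF gene and a
#' set of target genes are planted down-regulated in one stratum, the
#' targets' promoters are enriched for the motif, and decoy genes are
#' planted in the opposite direction.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_genes Number of genes in the synthetic genome.
#' @param n_targets Number of planted target genes.
#' @return Invisibly, a named list of the file paths written.
#' @export
make_fixtures <- function(dir, seed = 1L, n_genes = 60L, n_targets = 10L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gene_ids <- paste0("gene_", seq_len(n_genes))
  tf <- "gene_1"
  targets <- paste0("gene_", 1L + seq_len(n_targets))
  decoys <- paste0("gene_", 1L + n_targets + seq_len(n_targets))
  gcfg <- synth_genome_config(
    n_genes = n_genes, contigs = 2L, promoter_window = 500L,
    lambda_bg = 0.5, target_gene_ids = targets, lambda_target = 6,
    motif = data.frame(motif_id = "M1", tf_gene_id = tf,
                       pattern = "TGACTCAG", stringsAsFactors = FALSE),
    seed = seed)
  gen <- generate_genome(gcfg)
  planted <- rbind(
    data.frame(gene_id = c(tf, targets), tissue = "thymus",
               comparison = "y-o", direction = "down",
               stringsAsFactors = FALSE),
    data.frame(gene_id = decoys, tissue = "thymus", comparison = "y-o",
               direction = "up", stringsAsFactors = FALSE),
    data.frame(gene_id = c(tf, targets), tissue = "spleen",
               comparison = "y-o", direction = "up",
               stringsAsFactors = FALSE)
  )
  ecfg <- synth_expr_config(genes = gene_ids, planted = planted,
                            effect_size = 1.5, noise_sd = 0.2,
                            seed = seed + 1L)
  de <- generate_de_table(ecfg)

  paths <- list(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "genes.bed"),
    motifs = file.path(dir, "motifs.tsv"),
    de_table = file.path(dir, "de_table.tsv"),
    categories = file.path(dir, "categories.tsv"),
    signature = file.path(dir, "signature.tsv"),
    genome_truth = file.path(dir, "truth_implants.tsv"),
    de_truth = file.path(dir, "truth_de.tsv"),
    config = file.path(dir, "config.json")
  )
  Biostrings::writeXStringSet(gen$genome, paths$genome)
  ann <- gen$annotation
  # 1-bp features: BED start = TSS on plus, BED end - 1 = TSS on minus,
  # so start = tss, end = tss + 1 encodes the TSS on either strand
  bed <- data.frame(ann$contig, ann$tss, ann$tss + 1L,
                    ann$gene_id, 0L, ann$strand)
  utils::write.table(bed, paths$annotation, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv_report(gen$motif, paths$motifs)
  write_tsv_report(de, paths$de_table)
  write_tsv_report(data.frame(
    gene_id = c(targets, decoys),
    category = rep(c("planted_target", "decoy"), c(n_targets, n_targets)),
    role = "na", stringsAsFactors = FALSE), paths$categories)
  write_tsv_report(data.frame(
    gene_id = c(targets, decoys),
    expected_direction = rep(c("down", "up"), c(n_targets, n_targets)),
    stringsAsFactors = FALSE), paths$signature)
  write_tsv_report(gen$truth, paths$genome_truth)
  write_tsv_report(attr(de, "truth"), paths$de_truth)
  cfg <- list(
    de_table = paths$de_table, genome = paths$genome,
    annotation = paths$annotation, annotation_dialect = "BED6",
    motifs = paths$motifs, categories = paths$categories,
    signature = paths$signature,
    out_dir = file.path(dir, "results"),
    p_cutoff = 0.05, use_adjusted_p = FALSE, lfc_cutoff = 0.4,
    promoter_window = gcfg$promoter_window, strands = "both",
    sd_multiplier = 1, seed = seed)
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
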