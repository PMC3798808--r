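toy_records <- function() {
  data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    tissue = "thymus", comparison = "y-o",
    log2fc = c(0.9, -0.7, 0.4, -0.4, 0.3),
    p_value = c(0.01, 0.2, 0.04, 0.05, 0.01),
    stringsAsFactors = FALSE
  )
}

test_that("DE filtering applies inclusive p and fold-change thresholds", {
  f <- filter_de(toy_records(), analysis_config())
  # g1 clears both; g2 fails p; g3/g4 sit exactly on both boundaries (pass);
  # g5 fails the fold-change cutoff
  expect_setequal(f$gene_id, c("g1", "g3", "g4"))
  expect_equal(f$direction[f$gene_id == "g1"], "up")
  expect_equal(f$direction[f$gene_id == "g4"], "down")
  s <- de_gene_set(f, "thymus", "y-o")
  expect_setequal(s$up, c("g1", "g3"))
  expect_setequal(s$down, "g4")
  expect_length(intersect(s$up, s$down), 0L)
})

test_that("adjusted-p filtering is switchable and off by default", {
  rec <- toy_records()
  rec$adj_p <- c(0.2, 0.01, 0.2, 0.2, 0.2)
  raw <- filter_de(rec, analysis_config())
  adj <- filter_de(rec, analysis_config(use_adjusted_p = TRUE))
  expect_true("g1" %in% raw$gene_id && !"g2" %in% raw$gene_id)
  expect_true("g2" %in% adj$gene_id && !"g1" %in% adj$gene_id)
  expect_error(filter_de(toy_records(),
                         analysis_config(use_adjusted_p = TRUE)),
               "adj_p")
})

test_that("DE filtering is monotone in both thresholds", {
  withr::local_seed(11)
  rec <- data.frame(
    gene_id = paste0("g", 1:300), tissue = "t", comparison = "c",
    log2fc = rnorm(300, 0, 1), p_value = runif(300),
    stringsAsFactors = FALSE
  )
  base <- filter_de(rec, analysis_config(p_cutoff = 0.2, lfc_cutoff = 0.3))
  for (p in c(0.15, 0.05, 0.01)) {
    tighter <- filter_de(rec, analysis_config(p_cutoff = p,
                                              lfc_cutoff = 0.3))
    expect_true(all(tighter$gene_id %in% base$gene_id))
  }
  for (l in c(0.5, 1, 2)) {
    tighter <- filter_de(rec, analysis_config(p_cutoff = 0.2,
                                              lfc_cutoff = l))
    expect_true(all(tighter$gene_id %in% base$gene_id))
  }
})

test_that("overlap partition obeys the set identities", {
  part <- overlap_sets(c("a", "b", "c"), c("b", "c", "d"))
  expect_setequal(part$a_only, "a")
  expect_setequal(part$common, c("b", "c"))
  expect_setequal(part$b_only, "d")

  same <- overlap_sets(letters[1:4], letters[1:4])
  expect_length(same$a_only, 0L)
  expect_length(same$b_only, 0L)
  expect_setequal(same$common, letters[1:4])
})

test_that("overlap conservation holds on random set pairs", {
  withr::local_seed(23)
  for (i in 1:200) {
    a <- sample(paste0("g", 1:60), sample(0:40, 1))
    b <- sample(paste0("g", 1:60), sample(0:40, 1))
    part <- overlap_sets(a, b)
    expect_equal(length(part$a_only) + length(part$common), length(unique(a)))
    expect_equal(length(part$b_only) + length(part$common), length(unique(b)))
    expect_equal(length(part$a_only) + length(part$b_only) +
                   length(part$common), length(union(a, b)))
    expect_length(intersect(part$a_only, part$common), 0L)
    expect_length(intersect(part$b_only, part$common), 0L)
    expect_length(intersect(part$a_only, part$b_only), 0L)
  }
})

test_that("a 1034-gene set sharing 516 genes leaves 518 tissue-specific", {
  thymus <- paste0("t", 1:1034)
  spleen <- c(paste0("t", 1:516), paste0("s", 1:1500))
  part <- overlap_sets(thymus, spleen)
  expect_equal(length(part$common), 516L)
  expect_equal(length(part$a_only), 518L)
  expect_equal(length(part$a_only) + length(part$common), 1034L)
})

test_that("category summaries count directions and percentages", {
  de_set <- list(up = "g1", down = c("g2", "g3"))
  cats <- data.frame(gene_id = c("g1", "g2", "g3"), category = "mitosis",
                     role = "na", stringsAsFactors = FALSE)
  s <- summarize_categories(de_set, cats)
  expect_equal(s$n_up, 1L)
  expect_equal(s$n_down, 2L)
  expect_equal(s$pct_down, 100 * 2 / 3)

  empty <- summarize_categories(list(up = character(0), down = character(0)),
                                cats)
  expect_equal(nrow(empty), 0L)

  # uncategorized genes fall into an unassigned bucket; roles split rows
  de_set2 <- list(up = c("a1", "x1"), down = c("i1", "i2"))
  cats2 <- data.frame(gene_id = c("a1", "i1", "i2", "i3"),
                      category = "cell_cycle",
                      role = c("activator", "inhibitor", "inhibitor",
                               "inhibitor"),
                      stringsAsFactors = FALSE)
  s2 <- summarize_categories(de_set2, cats2,
                             universe = c("a1", "i1", "i2", "i3", "x1"))
  expect_setequal(s2$category, c("cell_cycle", "unassigned"))
  inh <- s2[s2$role == "inhibitor", ]
  expect_equal(inh$n_down, 2L)
  expect_equal(inh$pct_down, 100)
  expect_equal(inh$n_universe, 3L)  # i3 measured but not DE
  expect_equal(inh$pct_down_universe, 100 * 2 / 3)
})

test_that("ten planted-down category genes give a 100 percent-down row", {
  genes <- paste0("sphase_", 1:10)
  cfg <- synth_expr_config(
    genes = genes, tissues = "thymus", comparisons = "y-o",
    planted = data.frame(gene_id = genes, tissue = "thymus",
                         comparison = "y-o", direction = "down",
                         stringsAsFactors = FALSE),
    effect_size = 1, noise_sd = 0, seed = 5)
  de <- generate_de_table(cfg)
  f <- filter_de(de, analysis_config())
  s <- summarize_categories(de_gene_set(f, "thymus", "y-o"),
                            data.frame(gene_id = genes,
                                       category = "S phase progression",
                                       role = "na", stringsAsFactors = FALSE))
  expect_equal(s$n_down, 10L)
  expect_equal(s$pct_down, 100)
})

test_that("signature concordance matches hand counts and published rows", {
  # re-entered fold changes: Ctgf expected up and observed up (consistent),
  # Gfap expected up but observed down (inconsistent)
  rec <- data.frame(
    gene_id = c("Ctgf", "Gfap", "Aaa", "Bbb"),
    tissue = "spleen", comparison = "y-o",
    log2fc = c(1.9, -2.2, 0.8, -0.9),
    p_value = 0.01, stringsAsFactors = FALSE)
  sig <- data.frame(gene_id = c("Ctgf", "Gfap", "Aaa", "Bbb", "Ccc"),
                    expected_direction = c("up", "up", "up", "down", "na"),
                    stringsAsFactors = FALSE)
  res <- signature_concordance(rec, sig, analysis_config())
  expect_equal(res$n_evaluated, 4L)
  expect_equal(res$n_consistent, 3L)
  expect_equal(res$fraction, 0.75)
  detail <- res$detail
  expect_true(detail$consistent[detail$gene_id == "Ctgf"])
  expect_false(detail$consistent[detail$gene_id == "Gfap"])

  # invariant under permutation of input row order
  withr::local_seed(3)
  for (i in 1:5) {
    perm <- rec[sample(nrow(rec)), , drop = FALSE]
    expect_equal(signature_concordance(perm, sig)$fraction, res$fraction)
  }
})

test_that("zero fold change counts as inconsistent with any direction", {
  rec <- data.frame(gene_id = "g0", tissue = "t", comparison = "c",
                    log2fc = 0, p_value = 0.01, stringsAsFactors = FALSE)
  sig <- data.frame(gene_id = "g0", expected_direction = "up",
                    stringsAsFactors = FALSE)
  res <- signature_concordance(rec, sig, analysis_config(lfc_cutoff = 0))
  expect_equal(res$n_evaluated, 1L)
  expect_equal(res$n_consistent, 0L)
})
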