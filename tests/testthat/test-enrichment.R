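test_that("background profiles use the sample standard deviation", {
  p <- background_profile(c(a = 0, b = 1, c = 2, d = 3, e = 4), "m")
  expect_equal(p$mean, 2)
  expect_equal(p$sd, sqrt(2.5))
  expect_equal(p$hi_threshold, 2 + sqrt(2.5))
  expect_equal(p$lo_threshold, 2 - sqrt(2.5))
  expect_equal(p$n_promoters, 5L)

  flat <- background_profile(c(a = 3, b = 3, c = 3), "m")
  expect_equal(flat$sd, 0)
  expect_equal(flat$hi_threshold, 3)
  expect_equal(flat$lo_threshold, 3)

  expect_error(background_profile(c(a = 1), "m"), "at least 2")
})

test_that("Poisson-simulated backgrounds recover the rate", {
  withr::local_seed(83)
  lambda <- 2.5
  n <- 4000
  counts <- rpois(n, lambda)
  names(counts) <- paste0("g", seq_len(n))
  p <- background_profile(counts, "m")
  expect_lt(abs(p$mean - lambda), 3 * sqrt(lambda / n))
  expect_lt(abs(p$sd - sqrt(lambda)), 0.1)
})

test_that("candidate calls use strict inequalities at both thresholds", {
  counts <- matrix(c(4L, 0L, 2L), ncol = 1,
                   dimnames = list(c("gHi", "gLo", "gMid"), "m"))
  prof <- list(m = background_profile(c(a = 0, b = 1, c = 2, d = 3, e = 4),
                                      "m"))
  calls <- call_candidates(counts, prof)
  expect_equal(calls$call[calls$gene_id == "gHi"], "enriched")   # 4 > 3.58
  expect_equal(calls$call[calls$gene_id == "gLo"], "depleted")   # 0 < 0.42
  expect_equal(calls$call[calls$gene_id == "gMid"], "typical")   # equals mean

  # counts exactly on a threshold are typical
  flat <- list(m = background_profile(c(a = 3, b = 3, c = 3), "m"))
  on_band <- call_candidates(matrix(3L, 1, 1,
                                    dimnames = list("g", "m")), flat)
  expect_equal(on_band$call, "typical")

  # DE genes without a promoter are skipped, not fatal
  calls2 <- call_candidates(counts, prof, genes = c("gHi", "ghost"))
  expect_equal(attr(calls2, "skipped_genes"), "ghost")
  expect_equal(nrow(calls2), 1L)
})

test_that("raising the SD multiplier never adds non-typical calls", {
  withr::local_seed(89)
  counts <- matrix(rpois(400, 2), ncol = 2,
                   dimnames = list(paste0("g", 1:200), c("m1", "m2")))
  prev <- NULL
  for (k in c(0.5, 1, 1.5, 2, 3)) {
    profs <- background_profiles(counts, sd_multiplier = k)
    calls <- call_candidates(counts, profs)
    nt <- calls[calls$call != "typical", c("gene_id", "motif_id")]
    if (!is.null(prev)) {
      expect_lte(nrow(nt), nrow(prev))
      expect_true(all(paste(nt$gene_id, nt$motif_id) %in%
                        paste(prev$gene_id, prev$motif_id)))
    }
    prev <- nt
  }
})

test_that("strand-resolved calls are stable under promoter reorientation", {
  withr::local_seed(97)
  seqs <- vapply(1:40, function(i) random_dna(300), "")
  proms <- data.frame(gene_id = paste0("g", 1:40), sequence = seqs,
                      stringsAsFactors = FALSE)
  flipped <- proms
  flipped$sequence <- vapply(seqs, oracle_revcomp_seq, "")
  motifs <- data.frame(motif_id = "M", tf_gene_id = "tf",
                       pattern = "GATTA", stringsAsFactors = FALSE)
  plus_counts <- scan_promoters(proms, motifs, strands = "plus")$plus
  minus_counts <- scan_promoters(flipped, motifs, strands = "minus")$minus
  expect_equal(unname(plus_counts), unname(minus_counts))
  calls_a <- call_candidates(plus_counts,
                             list(M = background_profile(plus_counts, "M")))
  calls_b <- call_candidates(minus_counts,
                             list(M = background_profile(minus_counts, "M")))
  expect_equal(calls_a$call, calls_b$call)
})

test_that("TF-target assignments keep concordant enriched pairs", {
  de <- data.frame(
    gene_id = c("tf1", "tgtDown", "tgtUp", "tgtNS"),
    tissue = "thymus", comparison = "y-o",
    log2fc = c(-1.0, -0.8, 0.9, -0.9),
    p_value = c(0.01, 0.01, 0.01, 0.5),
    stringsAsFactors = FALSE)
  motifs <- data.frame(motif_id = "M1", tf_gene_id = "tf1",
                       pattern = "TGACTCAG", stringsAsFactors = FALSE)
  calls <- data.frame(
    gene_id = c("tgtDown", "tgtUp", "tgtNS"),
    motif_id = "M1", count = c(5L, 5L, 5L),
    call = "enriched", stringsAsFactors = FALSE)
  res <- tf_target_concordance(calls, de, motifs)
  expect_equal(res$target_gene_id, "tgtDown")
  expect_equal(res$tf_direction, "down")
  expect_true(res$concordant)
  # discordant pairs available under the flag
  all_pairs <- tf_target_concordance(calls, de, motifs,
                                     concordant_only = FALSE)
  expect_setequal(all_pairs$target_gene_id, c("tgtDown", "tgtUp"))
  expect_false(all_pairs$concordant[all_pairs$target_gene_id == "tgtUp"])
})

test_that("a motif whose TF is absent from the DE table is skipped", {
  de <- data.frame(gene_id = "g1", tissue = "t", comparison = "c",
                   log2fc = -1, p_value = 0.01, stringsAsFactors = FALSE)
  motifs <- data.frame(motif_id = "M9", tf_gene_id = "ghost_tf",
                       pattern = "ACGT", stringsAsFactors = FALSE)
  calls <- data.frame(gene_id = "g1", motif_id = "M9", count = 5L,
                      call = "enriched", stringsAsFactors = FALSE)
  expect_warning(res <- tf_target_concordance(calls, de, motifs),
                 "ghost_tf")
  expect_equal(nrow(res), 0L)
})

test_that("directions never cross tissues: opposite per-tissue TF signs", {
  # a TF down in thymus but up in spleen must pair with thymus-down and
  # spleen-up targets only
  de <- data.frame(
    gene_id = rep(c("tf1", "tA", "tB"), each = 2),
    tissue = rep(c("thymus", "spleen"), 3),
    comparison = "y-o",
    log2fc = c(-1.2, 1.1, -0.9, -0.8, 0.7, 0.9),
    p_value = 0.01, stringsAsFactors = FALSE)
  motifs <- data.frame(motif_id = "M1", tf_gene_id = "tf1",
                       pattern = "TGACTCAG", stringsAsFactors = FALSE)
  calls <- data.frame(gene_id = c("tA", "tB"), motif_id = "M1",
                      count = 9L, call = "enriched",
                      stringsAsFactors = FALSE)
  res <- tf_target_concordance(calls, de, motifs)
  thy <- res[res$tissue == "thymus", ]
  spl <- res[res$tissue == "spleen", ]
  expect_equal(thy$target_gene_id, "tA")   # down with the TF in thymus
  expect_equal(spl$target_gene_id, "tB")   # up with the TF in spleen
})

test_that("planted concordant targets are recovered exactly", {
  withr::local_seed(101)
  n_t <- 60
  targets <- paste0("tgt_", seq_len(n_t))
  decoys <- paste0("dec_", seq_len(n_t))
  de <- rbind(
    data.frame(gene_id = "tf1", tissue = "thymus", comparison = "y-o",
               log2fc = -1, p_value = 0, stringsAsFactors = FALSE),
    data.frame(gene_id = targets, tissue = "thymus", comparison = "y-o",
               log2fc = -1, p_value = 0, stringsAsFactors = FALSE),
    data.frame(gene_id = decoys, tissue = "thymus", comparison = "y-o",
               log2fc = 1, p_value = 0, stringsAsFactors = FALSE))
  calls <- data.frame(gene_id = c(targets, decoys), motif_id = "M1",
                      count = 9L, call = "enriched",
                      stringsAsFactors = FALSE)
  motifs <- data.frame(motif_id = "M1", tf_gene_id = "tf1",
                       pattern = "TGACTCAG", stringsAsFactors = FALSE)
  res <- tf_target_concordance(calls, de, motifs)
  expect_setequal(res$target_gene_id, targets)
})
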