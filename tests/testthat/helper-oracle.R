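# Independent oracles used across the suite.  These deliberately share no
# code with the package: the scanner oracle enumerates every offset and
# checks character-set membership directly, and reverse complements are
# built by naive string manipulation.

oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp_seq <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1L]]),
        collapse = "")
}

oracle_revcomp_pattern <- function(p) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(p, "")[[1L]]]), collapse = "")
}

# all 0-based offsets where the pattern matches on the given strand of the
# sequence (minus strand = plus-strand match of the reverse-complemented
# pattern), by brute-force enumeration
oracle_match_offsets <- function(sequence, pattern, strand = "+") {
  if (strand == "-") pattern <- oracle_revcomp_pattern(pattern)
  seq_chars <- strsplit(toupper(sequence), "")[[1L]]
  pat_chars <- strsplit(toupper(pattern), "")[[1L]]
  L <- length(pat_chars)
  n <- length(seq_chars)
  hits <- integer(0)
  if (n < L) return(hits)
  for (i in 0:(n - L)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      if (!(seq_chars[i + j] %in% oracle_iupac[[pat_chars[j]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

oracle_count <- function(sequence, pattern, strands = "both") {
  n_plus <- length(oracle_match_offsets(sequence, pattern, "+"))
  n_minus <- length(oracle_match_offsets(sequence, pattern, "-"))
  switch(strands, plus = n_plus, minus = n_minus, both = n_plus + n_minus)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_iupac_pattern <- function(len) {
  alphabet <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N")
  # bias toward concrete bases so random patterns still have few matches
  paste(sample(alphabet, len, replace = TRUE,
               prob = c(rep(4, 4), rep(1, 11))), collapse = "")
}

# small DE table used by several io / de_analysis tests
write_toy_de <- function(path, rows) {
  writeLines(c("gene_id\ttissue\tcomparison\tlog2fc\tp_value", rows), path)
}
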