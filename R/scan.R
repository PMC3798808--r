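# Exact (no-mismatch) matching of IUPAC degenerate consensus patterns
# against nucleotide sequences.  This is the analytical core of the package
# and is implemented directly: each IUPAC symbol is compiled to a 4-bit mask
# over {A,C,G,T}, sequences are encoded the same way (with anything outside
# A/C/G/T, including N, encoded as the empty mask that matches nothing), and
# a window matches iff the bitwise AND is non-zero at every position.  All
# overlapping occurrences are reported.

IUPAC_MASKS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# swap A<->T and C<->G bits of a 4-bit base mask
complement_mask <- function(m) {
  bitwOr(
    bitwOr(bitwShiftL(bitwAnd(m, 1L), 3L), bitwShiftR(bitwAnd(m, 8L), 3L)),
    bitwOr(bitwShiftL(bitwAnd(m, 2L), 1L), bitwShiftR(bitwAnd(m, 4L), 1L))
  )
}

encode_sequence <- function(sequence) {
  v <- utf8ToInt(toupper(sequence))
  m <- integer(length(v))
  m[v == 65L] <- 1L   # A
  m[v == 67L] <- 2L   # C
  m[v == 71L] <- 4L   # G
  m[v == 84L] <- 8L   # T
  m
}

#' Compile an IUPAC consensus pattern
#'
#' Expands each IUPAC symbol to its allowed-base set (e.g. `R` -> {A,G},
#' `N` -> {A,C,G,T}) and precomputes the bit masks used by the scanner for
#' both the pattern and its reverse complement.
#'
#' @param pattern A string over the 15-letter IUPAC nucleotide alphabet.
#' @param motif_id Identifier carried through to scan results.
#' @return An object of class `compiled_pattern` with fields `motif_id`,
#'   `pattern`, `length`, `allowed` (list of per-position base sets) and the
#'   internal masks.
#' @examples
#' compile_pattern("TGASTCA")$allowed[[4]]  # the S position: C or G
#' @export
compile_pattern <- function(pattern, motif_id = pattern) {
  pattern <- toupper(pattern)
  validate_iupac(pattern, motif_id)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  masks <- unname(IUPAC_MASKS[chars])
  structure(
    list(
      motif_id = motif_id,
      pattern = pattern,
      length = length(chars),
      allowed = unname(IUPAC_SETS[chars]),
      masks = masks,
      rc_masks = rev(complement_mask(masks))
    ),
    class = "compiled_pattern"
  )
}

#' @export
print.compiled_pattern <- function(x, ...) {
  cat(sprintf("Compiled pattern '%s' (%s), %d positions\n",
              x$motif_id, x$pattern, x$length))
  invisible(x)
}

# 0-based offsets at which every pattern position is compatible
match_offsets <- function(seq_masks, pat_masks) {
  L <- length(pat_masks)
  n <- length(seq_masks)
  if (n < L) return(integer(0))
  k <- n - L + 1L
  ok <- bitwAnd(seq_masks[seq_len(k)], pat_masks[1L]) > 0L
  j <- 1L
  while (j < L && any(ok)) {
    ok <- ok & bitwAnd(seq_masks[(1L + j):(k + j)], pat_masks[j + 1L]) > 0L
    j <- j + 1L
  }
  which(ok) - 1L
}

#' Scan a sequence for a degenerate pattern
#'
#' Counts all (overlapping) exact occurrences of the pattern in the
#' sequence.  A plus-strand hit at offset `i` requires the sequence base at
#' `i + j` to lie in the pattern's allowed set at every position `j`;
#' sequence characters outside A/C/G/T (e.g. masking `N`) match nothing.  A
#' minus-strand hit is a plus-strand hit of the reverse-complemented pattern
#' on the same sequence, reported at the offset of its leftmost base.
#'
#' @param sequence A nucleotide string.
#' @param pattern A `compiled_pattern` (or an IUPAC string, compiled on the
#'   fly).
#' @param strands `"both"`, `"plus"` or `"minus"`.
#' @return A list with `plus_count`, `minus_count`, `total` and the 0-based
#'   `plus_positions` / `minus_positions`.
#' @examples
#' scan_sequence("TTATCT", "GATA")$minus_count  # revcomp TATC at offset 1
#' @export
scan_sequence <- function(sequence, pattern,
                          strands = c("both", "plus", "minus")) {
  strands <- match.arg(strands)
  if (!inherits(pattern, "compiled_pattern")) {
    pattern <- compile_pattern(pattern)
  }
  sm <- encode_sequence(sequence)
  plus_pos <- if (strands %in% c("both", "plus")) {
    match_offsets(sm, pattern$masks)
  } else {
    integer(0)
  }
  minus_pos <- if (strands %in% c("both", "minus")) {
    match_offsets(sm, pattern$rc_masks)
  } else {
    integer(0)
  }
  list(
    plus_count = length(plus_pos),
    minus_count = length(minus_pos),
    total = length(plus_pos) + length(minus_pos),
    plus_positions = plus_pos,
    minus_positions = minus_pos
  )
}

#' Count motif occurrences across promoters
#'
#' Builds the genes x motifs occurrence-count matrix by scanning every
#' promoter with every motif.  Counts are strand-resolved internally;
#' `total = plus + minus` always holds, so either a per-strand or a combined
#' convention can be reported downstream.  Note that a palindromic pattern
#' (equal to its reverse complement) matches each site once per strand, so
#' its both-strand totals count every site twice.
#'
#' @param promoters A promoter table from [extract_promoters()] (or any
#'   data frame with `gene_id` and `sequence` columns).
#' @param motifs A motif table from [read_motifs()].
#' @param strands `"both"`, `"plus"` or `"minus"`.
#' @return An object of class `count_matrix`: a list of integer matrices
#'   `total`, `plus`, `minus` (rows = genes, columns = motifs).
#' @export
scan_promoters <- function(promoters, motifs,
                           strands = c("both", "plus", "minus")) {
  strands <- match.arg(strands)
  if (anyDuplicated(promoters$gene_id)) {
    stop(sprintf("duplicate promoter gene_id: %s",
                 promoters$gene_id[duplicated(promoters$gene_id)][1L]),
         call. = FALSE)
  }
  compiled <- lapply(seq_len(nrow(motifs)), function(i) {
    compile_pattern(motifs$pattern[i], motifs$motif_id[i])
  })
  n_g <- nrow(promoters)
  n_m <- nrow(motifs)
  dn <- list(promoters$gene_id, motifs$motif_id)
  plus <- matrix(0L, n_g, n_m, dimnames = dn)
  minus <- matrix(0L, n_g, n_m, dimnames = dn)
  encoded <- lapply(promoters$sequence, encode_sequence)
  for (j in seq_len(n_m)) {
    cp <- compiled[[j]]
    for (i in seq_len(n_g)) {
      if (strands %in% c("both", "plus")) {
        plus[i, j] <- length(match_offsets(encoded[[i]], cp$masks))
      }
      if (strands %in% c("both", "minus")) {
        minus[i, j] <- length(match_offsets(encoded[[i]], cp$rc_masks))
      }
    }
  }
  structure(
    list(total = plus + minus, plus = plus, minus = minus,
         strands = strands),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("Occurrence counts: %d promoters x %d motifs (%s strand%s)\n",
              nrow(x$total), ncol(x$total), x$strands,
              if (x$strands == "both") "s" else " only"))
  invisible(x)
}

#' Hit-level scan report
#'
#' @param promoters,motifs,strands As in [scan_promoters()].
#' @return A data frame of individual hits: `gene_id`, `motif_id`, `offset`
#'   (0-based within the oriented promoter) and `strand`.
#' @export
scan_hits <- function(promoters, motifs,
                      strands = c("both", "plus", "minus")) {
  strands <- match.arg(strands)
  rows <- list()
  for (i in seq_len(nrow(promoters))) {
    for (j in seq_len(nrow(motifs))) {
      cp <- compile_pattern(motifs$pattern[j], motifs$motif_id[j])
      res <- scan_sequence(promoters$sequence[i], cp, strands)
      if (res$plus_count > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = promoters$gene_id[i], motif_id = motifs$motif_id[j],
          offset = res$plus_positions, strand = "+",
          stringsAsFactors = FALSE)
      }
      if (res$minus_count > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = promoters$gene_id[i], motif_id = motifs$motif_id[j],
          offset = res$minus_positions, strand = "-",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(0), motif_id = character(0),
                      offset = integer(0), strand = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$gene_id, out$motif_id, out$offset, out$strand), ,
      drop = FALSE]
}

#' Reverse complement of an IUPAC pattern string
#'
#' @param pattern An IUPAC nucleotide string.
#' @return The reverse complement, with ambiguity codes complemented
#'   (R<->Y, K<->M, B<->V, D<->H; A<->T, C<->G; S, W, N unchanged).
#' @export
reverse_complement_pattern <- function(pattern) {
  pattern <- toupper(pattern)
  validate_iupac(pattern, pattern)
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", pattern)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}
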