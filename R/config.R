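#' Analysis configuration
#'
#' Bundles the thresholds that drive every stage of the pipeline.  Defaults
#' encode the standard analysis: genes are differentially expressed when
#' p <= 0.05 and |log2 fold change| >= 0.4; promoters are the 1000 bases
#' upstream of the transcription start site; a promoter is enriched/depleted
#' for a motif when its occurrence count is strictly above/below the
#' genome-background mean plus/minus one sample standard deviation.
#'
#' @param p_cutoff Significance threshold on the p-value (inclusive).
#' @param use_adjusted_p If `TRUE`, filter on the `adj_p` column instead of
#'   the raw `p_value`.
#' @param lfc_cutoff Minimum absolute log2 fold change (inclusive).
#' @param promoter_window Promoter width in bases upstream of the TSS.
#' @param strands Which strands the scanner counts: `"both"`, `"plus"`, or
#'   `"minus"`.
#' @param sd_multiplier Width of the background band in standard deviations;
#'   1 gives the mean +/- SD band.
#' @param seed Integer seed governing all randomness in a run.
#' @return A list of class `analysis_config`.
#' @examples
#' cfg <- analysis_config()
#' cfg$lfc_cutoff
#' @export
analysis_config <- function(p_cutoff = 0.05,
                            use_adjusted_p = FALSE,
                            lfc_cutoff = 0.4,
                            promoter_window = 1000L,
                            strands = c("both", "plus", "minus"),
                            sd_multiplier = 1,
                            seed = 1L) {
  strands <- match.arg(strands)
  if (!is.numeric(p_cutoff) || length(p_cutoff) != 1L ||
      p_cutoff <= 0 || p_cutoff > 1) {
    stop("'p_cutoff' must be a single value in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(lfc_cutoff) || length(lfc_cutoff) != 1L || lfc_cutoff < 0) {
    stop("'lfc_cutoff' must be a single non-negative value", call. = FALSE)
  }
  if (!is.numeric(promoter_window) || length(promoter_window) != 1L ||
      promoter_window < 1) {
    stop("'promoter_window' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(sd_multiplier) || length(sd_multiplier) != 1L ||
      sd_multiplier <= 0) {
    stop("'sd_multiplier' must be > 0", call. = FALSE)
  }
  structure(
    list(
      p_cutoff = as.numeric(p_cutoff),
      use_adjusted_p = isTRUE(use_adjusted_p),
      lfc_cutoff = as.numeric(lfc_cutoff),
      promoter_window = as.integer(promoter_window),
      strands = strands,
      sd_multiplier = as.numeric(sd_multiplier),
      seed = as.integer(seed)
    ),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  p cutoff        : %g (%s p)\n", x$p_cutoff,
              if (x$use_adjusted_p) "adjusted" else "raw"))
  cat(sprintf("  |log2FC| cutoff : %g\n", x$lfc_cutoff))
  cat(sprintf("  promoter window : %d bp upstream of TSS\n",
              x$promoter_window))
  cat(sprintf("  scan strands    : %s\n", x$strands))
  cat(sprintf("  background band : mean +/- %g SD\n", x$sd_multiplier))
  cat(sprintf("  seed            : %d\n", x$seed))
  invisible(x)
}

as_analysis_config <- function(x) {
  if (inherits(x, "analysis_config")) return(x)
  if (!is.list(x)) stop("cannot interpret 'config'", call. = FALSE)
  keep <- intersect(names(x), names(formals(analysis_config)))
  do.call(analysis_config, x[keep])
}
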