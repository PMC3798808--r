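---
title: "Methods: promoter TFBS scanning and DE set analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter TFBS scanning and DE set analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfbscan)
```

## The model

The package asks a deliberately simple question: among genes whose
expression changes between conditions, which ones carry an unusual number
of binding sites for a transcription factor whose own expression changes
in the same direction? It combines four ingredients.

**Promoters.** The promoter of a gene is the fixed window of
`promoter_window` bases (default 1000) immediately upstream of the
transcription start site. The TSS is the first transcribed base and is
*excluded* from the window; on the minus strand the window lies to the
right of the TSS in genomic coordinates and is emitted
reverse-complemented, so every promoter reads 5'→3' relative to its gene.
Both choices are contracts pinned by tests rather than biological claims:
inclusion of the TSS base or genomic-orientation output would be equally
defensible conventions, and fixing them explicitly removes a class of
off-by-one ambiguity. Promoters truncated by a contig edge are kept with
their shortened `effective_length` recorded — dropping them silently
would bias the background statistics; a `min_length` filter on
`background_profile()` makes exclusion available and auditable.

**Exact degenerate scanning.** Binding sites are IUPAC consensus words;
each symbol denotes a subset of `{A,C,G,T}` and a window matches when
every position's sequence base lies in the pattern's set — no mismatches,
no scoring. Internally each symbol is a 4-bit mask and a match is a
non-zero bitwise AND at every position; the contract, enforced against a
naive per-offset oracle, is position-complete exactness. All overlapping
occurrences count. Sequence characters outside `A/C/G/T` (assembly gaps,
hard-masked runs) match nothing, including against `N` in a pattern:
non-ACGT sequence is missing information, not wildcard information.
Soft-masked lower-case bases are upper-cased before scanning, since
repeat-masking is not evidence of absence. Both strands are scanned by
default (a binding site is meaningful on either strand); strand-resolved
counts are always retained, which makes one consequence explicit: a
palindromic consensus matches each site once per strand, so its
both-strand totals double-count sites. Reporting per-strand counts keeps
either convention recoverable.

**Background band.** For each motif, the per-promoter count over *all*
annotated genes — including the DE genes themselves, which are genes of
the genome; a flag excludes them — gives a mean μ and sample standard
deviation s (n−1 denominator). A DE gene's promoter is `enriched` when
its count is strictly greater than μ + k·s and `depleted` when strictly
less than μ − k·s, with `sd_multiplier` k = 1 by default; counts exactly
on a threshold are typical, reading "higher or lower than" strictly. This
is a dispersion band, not a hypothesis test: counts are small integers,
the band is typically asymmetric around zero, and no multiple-testing
correction applies (the candidate report's header carries this caveat).
Raw counts are banded by default; a per-kilobase normalization would
interact with the truncated-promoter policy and is deliberately not the
default. Depleted promoters are carried as a separate candidate class but
left out of the default target report, which is defined by presence of
binding sites; `include_depleted = TRUE` restores them.

**Direction concordance.** A candidate becomes a target assignment only
in a tissue and comparison where both the TF gene and the target pass the
DE filter, and it is concordant when their log2-fold-change signs agree.
The filter is `p ≤ p_cutoff` (default 0.05, raw p; an `adj_p` switch
exists because published threshold language often leaves the
adjusted-vs-raw question open) and `|log2FC| ≥ lfc_cutoff` (default 0.4),
both boundaries inclusive — the conventional reading of a "cutoff", again
pinned by tests. Directions are never transferred across tissues: a TF
down-regulated in one organ and up-regulated in another is paired with
targets organ by organ. A log2FC of exactly 0 is neither up nor down and
is inconsistent with any expected direction.

## Set summaries

`overlap_sets()` partitions two DE gene sets into exclusive and common
parts; the partition always satisfies |A-only| + |common| = |A| (a
conservation law that also serves as a sanity check on published Venn
counts, which do not always sum). Overlaps are gene-identity based by
default, with a direction-aware variant. `summarize_categories()` counts
up/down DE genes per functional category and role and reports the
percentage down twice — over the category's DE genes and, when a measured
universe is supplied, over all category genes on the table — because
published percent-down tables rarely state their denominator.
`signature_concordance()` evaluates, among filtered genes with a
directional expectation (`na` entries drop out of the denominator), the
fraction changing in the expected direction.

## Synthetic data and what it shows

`generate_genome()` emits i.i.d. bases at a chosen GC content, places
genes on random strands with full promoter clearance, and implants per
promoter a Poisson(λ) number of concrete motif instances — λ_bg
(default 1) for background genes, λ_target (default 5) for designated
targets, the defaults used throughout the validation runs — at uniform
non-overlapping offsets, on a uniformly chosen strand, degenerate
positions resolved uniformly; every implant is recorded in a truth table.
Implants may collide with chance background matches (the truth table plus
an oracle pre-scan resolves this in tests), but never with each other, so
implant counts stay interpretable. The default validation motif
`TGACTCAG` is non-palindromic and non-self-overlapping, so each planted
copy contributes exactly one count.

`generate_de_table()` simulates log2 expression directly — two groups of
`n_per_group` values at Normal(baseline 8, noise_sd), with ±effect_size
added to the second group for planted strata — and reports the difference
of group means with a two-sided pooled-variance t-test p-value. Defaults
(3 per group, noise SD 0.3 log2 units, effect 1.0) give per-gene power
near 0.86, a realistic regime for small-group tissue contrasts. With
`noise_sd = 0` the table degenerates to exact effects with p = 0/1, which
is what makes "the filter returns exactly the planted set" a meaningful
test. The baseline cancels in every downstream quantity.

What passing these tests does *not* show: real promoters are not i.i.d.
sequence (CpG islands, repeats), real binding sites are not exact
consensus words, microarray fold changes are not homoscedastic Gaussians,
and one TSS per gene ignores alternative promoters. The synthetic runs
validate the machinery and its statistics, not the biology.

## Numerical and validation choices

Validation problem sizes were chosen so the full suite runs in a couple
of minutes while keeping Monte-Carlo error well inside the asserted
tolerances: 200 random sequence/pattern pairs for scanner–oracle
equivalence, 50 genomes for promoter duality, 20 replicates of
2,000-promoter genomes (promoter width 500, which leaves the chance-match
rate of an 8-mer near 0.015 per promoter) for planted-target recovery,
and 1,000 genes for DE calibration. For the recovery check, the empirical
enriched-call sensitivity and background false-call rate are compared as
means over the replicates against Poisson tail probabilities evaluated at
each replicate's realized thresholds — a single 100-gene replicate has a
binomial standard error of ≈3 percentage points, so per-replicate bounds
at ±5 points would fail a correct implementation by chance. The
planted-detection oracle is the noncentral-t power of the two-sample
pooled t-test; the additional |log2FC| ≥ 0.4 requirement removes less
than one percentage point at the default effect and noise.

Reports are deterministic by construction: numeric fields are written
with the shortest decimal representation that parses back to the
identical double, all randomness flows from a single seed through
isolated RNG scopes, and iteration orders are fixed. Degenerate inputs
have defined behavior: zero-variance backgrounds collapse the band to the
mean (everything off the mean is a call), empty result sets yield
header-only reports, and a DE gene without a promoter is recorded as
skipped rather than failing the run.

## Known limitations

Exact matching cannot rank candidates by affinity; the band criterion
has no error-rate control; concordance of signs is weak evidence of
regulation on its own; and gene-identifier matching across tables is
exact and case-sensitive by design, so upstream identifier hygiene is the
user's responsibility.
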