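#' Numeric criteria for the gene-loss screen
#'
#' Bundles every tunable cutoff used across the pipeline. Defaults are the
#' criteria of the original avian gene-loss screen: a run of missing genes
#' qualifies as a syntenic deletion block when it holds at least three
#' adjacent genes, or (for singlets/doublets) spans at least 80,000 bp from
#' the start of its first gene to the end of its last; very large doublets
#' spanning at least 34,000 bp form a lowest-confidence tier. Alignment
#' hits are accepted only with score strictly greater than 50; permutation
#' nulls use 1,000 resamples; significance is declared at alpha = 0.05 with
#' Benjamini-Hochberg q < 0.05; "short" genes are those with CDS < 500 bp.
#'
#' @param min_block_span Minimum block span in bp for singlet/doublet
#'   blocks (default 80,000).
#' @param min_block_genes Gene count at which a run qualifies
#'   unconditionally (default 3).
#' @param doublet_min_span Span in bp admitting a doublet into the
#'   lowest-confidence tier (default 34,000).
#' @param min_hit_score Alignment-score cutoff; hits with score less than
#'   or equal to this are discarded (default 50, strict inequality).
#' @param n_permutations Number of matched control sets for permutation
#'   tests (default 1,000).
#' @param alpha Per-test significance level (default 0.05).
#' @param fdr_q Benjamini-Hochberg q-value cutoff (default 0.05).
#' @param short_gene_bp CDS length below which a gene counts as short
#'   (default 500).
#' @param distant_flank_bp Separation on the same focal chromosome beyond
#'   which flanking blocks are called "distant" (default 5 Mb).
#' @param n_random_repeats Number of random gene-set draws averaged into
#'   the empirical expected chromosomal distribution (default 10).
#' @param near_block_gap Maximum number of intervening present genes for a
#'   non-qualifying run to be reported as "near-block" rather than dropped
#'   (default 5).
#' @param span_tolerance Relative tolerance when matching control-block
#'   spans to target spans (default 0.2, i.e. +/-20%).
#' @return An object of class `loss_thresholds` (a validated named list).
#' @examples
#' loss_thresholds()
#' loss_thresholds(min_hit_score = 80)
#' @export
loss_thresholds <- function(min_block_span = 80000,
                            min_block_genes = 3L,
                            doublet_min_span = 34000,
                            min_hit_score = 50,
                            n_permutations = 1000L,
                            alpha = 0.05,
                            fdr_q = 0.05,
                            short_gene_bp = 500,
                            distant_flank_bp = 5e6,
                            n_random_repeats = 10L,
                            near_block_gap = 5L,
                            span_tolerance = 0.2) {
  th <- list(
    min_block_span = min_block_span,
    min_block_genes = as.integer(min_block_genes),
    doublet_min_span = doublet_min_span,
    min_hit_score = min_hit_score,
    n_permutations = as.integer(n_permutations),
    alpha = alpha,
    fdr_q = fdr_q,
    short_gene_bp = short_gene_bp,
    distant_flank_bp = distant_flank_bp,
    n_random_repeats = as.integer(n_random_repeats),
    near_block_gap = as.integer(near_block_gap),
    span_tolerance = span_tolerance
  )
  num <- vapply(th, is.numeric, logical(1))
  if (!all(num)) abort_synloss("all thresholds must be numeric")
  pos <- vapply(th, function(x) x > 0, logical(1))
  pos["near_block_gap"] <- th$near_block_gap >= 0
  if (!all(pos)) {
    abort_synloss(paste0(
      "thresholds must be positive; offending: ",
      paste(names(th)[!pos], collapse = ", ")
    ))
  }
  if (alpha <= 0 || alpha >= 1) abort_synloss("`alpha` must lie in (0, 1)")
  if (fdr_q <= 0 || fdr_q >= 1) abort_synloss("`fdr_q` must lie in (0, 1)")
  structure(th, class = "loss_thresholds")
}

#' @export
print.loss_thresholds <- function(x, ...) {
  cat("<loss_thresholds>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_thresholds <- function(x) {
  if (inherits(x, "loss_thresholds")) return(x)
  if (is.null(x)) return(loss_thresholds())
  if (is.list(x)) return(do.call(loss_thresholds, x))
  abort_synloss("`thresholds` must be a loss_thresholds object or a list")
}
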