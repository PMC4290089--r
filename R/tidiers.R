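# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname identify_candidates
#' @param x A `candidate_set`.
#' @param ... Unused.
#' @export
tidy.candidate_set <- function(x, ...) x$genes

#' @rdname identify_candidates
#' @export
glance.candidate_set <- function(x, ...) x$counts

#' @rdname chisq_uniformity
#' @param x A `chrom_dist`.
#' @param ... Unused.
#' @export
tidy.chrom_dist <- function(x, ...) x$table

#' @rdname chisq_uniformity
#' @export
glance.chrom_dist <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 mode = x$mode)
}

#' @rdname wilcoxon_paired
#' @param x A `wilcoxon_paired`.
#' @param ... Unused.
#' @export
glance.wilcoxon_paired <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, n = x$n, p_value = x$p_value,
                 method = x$method)
}

#' @rdname size_bias_report
#' @param x A `size_bias`.
#' @param ... Unused.
#' @export
glance.size_bias <- function(x, ...) {
  tibble::tibble(
    f_statistic = x$f_statistic, p_value = x$p_value,
    short_fraction_missing = x$short_fraction_missing,
    short_fraction_background = x$short_fraction_background,
    cor_estimate = if (is.null(x$correlation)) NA_real_ else
      x$correlation$estimate,
    cor_p_value = if (is.null(x$correlation)) NA_real_ else
      x$correlation$p_value
  )
}

#' @rdname detect_missing_blocks
#' @param x A `block_set`.
#' @param ... Unused.
#' @export
tidy.block_set <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$members <- vapply(out$members, paste, character(1), collapse = ",")
  out
}

#' @rdname detect_missing_blocks
#' @export
glance.block_set <- function(x, ...) {
  tibble::tibble(
    n_blocks = nrow(x),
    n_genes_in_blocks = length(unlist(x$members)),
    n_near_block = nrow(near_block_genes(x)),
    n_multi_gene = sum(x$tier == "multi_gene"),
    total_span = sum(x$span)
  )
}

#' @rdname permutation_test
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @export
tidy.permutation_result <- function(x, ...) {
  x$terms %||% tibble::tibble(term_id = character(), label = character(),
                              observed = numeric(), expected = numeric(),
                              p_value = numeric(), q_value = numeric())
}

#' @rdname permutation_test
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(observed = x$observed, null_mean = x$null_mean,
                 null_sd = x$null_sd, n_permutations = x$n_permutations,
                 p_value = x$p_value)
}

#' @rdname venn_group_classify
#' @param x A `venn_groups`.
#' @param ... Unused.
#' @export
tidy.venn_groups <- function(x, ...) x$terms
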