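# Chromosomal-distribution and size-bias statistics.

#' Chi-squared test of chromosomal distribution against a weighted expectation
#'
#' Tests whether per-chromosome counts of blocks or genes depart from the
#' distribution expected under random, uniform assignment proportional to
#' a per-chromosome basis: chromosome length (`by_size`), gene count
#' (`by_gene_count`), 1-to-1 ortholog count (`by_ortholog_count`), or an
#' empirical baseline averaged over random same-size gene sets
#' (`empirical_random`; see [random_set_weights()]). Although phrased as
#' an independence test in the original analysis, with a single observed
#' vector this is a goodness-of-fit test with `df = k - 1` (23 human
#' chromosomes give df = 22). Expected counts are
#' `total * weight / sum(weight)`; the statistic is `sum((O - E)^2 / E)`
#' with no continuity correction; a warning is emitted when any expected
#' count falls below 5.
#'
#' @param observed Named numeric vector (or 2-column data frame of
#'   category/count) of per-chromosome counts.
#' @param weights Positive numeric vector, one basis value per category,
#'   aligned with `observed` (matched by name when both are named).
#' @param mode Label recording the expectation basis.
#' @return Object of class `chrom_dist`: list with `table` (tibble:
#'   `category`, `observed`, `expected`), `statistic`, `df`, `p_value`,
#'   `mode`. `tidy()` returns the table, `glance()` the test summary.
#' @examples
#' chisq_uniformity(c(chr1 = 10, chr2 = 0), c(chr1 = 1, chr2 = 1))
#' @export
chisq_uniformity <- function(observed, weights,
                             mode = c("by_size", "by_gene_count",
                                      "by_ortholog_count", "empirical_random")) {
  mode <- match.arg(mode)
  if (is.data.frame(observed)) {
    obs <- observed[[2]]
    names(obs) <- observed[[1]]
    observed <- obs
  }
  if (length(observed) < 2) abort_synloss("need at least two categories")
  if (length(weights) != length(observed)) {
    abort_synloss("`weights` must align with `observed`")
  }
  if (!is.null(names(observed)) && !is.null(names(weights))) {
    if (!setequal(names(observed), names(weights))) {
      abort_synloss("`observed` and `weights` name different categories")
    }
    weights <- weights[names(observed)]
  }
  if (any(weights <= 0) || any(is.na(weights))) {
    abort_synloss("`weights` must be positive")
  }
  total <- sum(observed)
  if (total == 0) abort_synloss("total observed count is zero")
  expected <- total * weights / sum(weights)
  if (any(expected < 5)) {
    warning("some expected counts are below 5; chi-squared approximation may be poor",
            call. = FALSE)
  }
  fit <- suppressWarnings(stats::chisq.test(observed, p = weights / sum(weights)))
  structure(list(
    table = tibble::tibble(
      category = names(observed) %||% as.character(seq_along(observed)),
      observed = as.numeric(observed),
      expected = as.numeric(expected)
    ),
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = unname(fit$p.value),
    mode = mode
  ), class = "chrom_dist")
}

#' @export
print.chrom_dist <- function(x, ...) {
  cat(sprintf("<chrom_dist (%s): X^2 = %.4g, df = %d, p = %.3g>\n",
              x$mode, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Empirical expected chromosomal distribution from random gene sets
#'
#' Builds the baseline used by the `empirical_random` mode: the average
#' per-chromosome counts of `n_repeats` seeded random draws of
#' `set_size` genes from the table's gene universe.
#'
#' @param tbl An `ortholog_tbl`.
#' @param species Species whose chromosome assignment is counted.
#' @param set_size Genes per random draw.
#' @param n_repeats Number of draws to average (default 10).
#' @param seed Integer seed; the result is exactly reproducible.
#' @param universe Optional character vector restricting the draw to a
#'   subset of gene ids (e.g. the three-species 1:1:1 ortholog set).
#' @return Named numeric vector of average counts per chromosome.
#' @export
random_set_weights <- function(tbl, species, set_size, n_repeats = 10L,
                               seed = 1L, universe = NULL) {
  check_species(tbl, species)
  v <- species_view(tbl, species)
  if (!is.null(universe)) v <- v[v$gene_id %in% universe, , drop = FALSE]
  v <- v[!is.na(v$chr), , drop = FALSE]
  chr <- v$chr
  chr[!v$placed] <- "Un"  # pool unplaced scaffolds into one category
  lev <- unique(chr[order(match(chr, c(chromosome_levels(v$chr, v$placed), "Un")))])
  if (set_size > length(chr)) abort_synloss("`set_size` exceeds the universe")
  counts <- withr::with_seed(seed, {
    rowSums(vapply(seq_len(n_repeats), function(i) {
      tabulate(match(chr[sample.int(length(chr), set_size)], lev),
               nbins = length(lev))
    }, numeric(length(lev))))
  }) / n_repeats
  stats::setNames(counts, lev)
}

#' Per-chromosome counts with unplaced scaffolds pooled
#'
#' Counts items (genes or blocks) per chromosome of `species`, pooling
#' all unplaced scaffolds into a single `"Un"` category, mirroring the
#' screen's distribution plots.
#'
#' @param tbl An `ortholog_tbl`.
#' @param species Species whose chromosomes are counted.
#' @param genes Gene ids to count; defaults to all genes with
#'   coordinates.
#' @return Named numeric vector of counts in canonical chromosome order.
#' @export
chromosome_counts <- function(tbl, species, genes = NULL) {
  check_species(tbl, species)
  v <- species_view(tbl, species)
  if (!is.null(genes)) v <- v[v$gene_id %in% genes, , drop = FALSE]
  v <- v[!is.na(v$chr), , drop = FALSE]
  chr <- v$chr
  chr[!v$placed] <- "Un"
  lev <- c(chromosome_levels(v$chr[v$placed], v$placed[v$placed]),
           if (any(!v$placed)) "Un")
  stats::setNames(tabulate(match(chr, lev), nbins = length(lev)), lev)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided matched-pairs signed-ranks test for paired block sizes in
#' two species. Zero differences are dropped; tied absolute differences
#' receive midranks. For n <= 12 remaining pairs the p-value is exact,
#' computed by full enumeration of all 2^n sign assignments (valid under
#' ties); for larger n a normal approximation with tie correction and no
#' continuity correction is used.
#'
#' @param a,b Equal-length numeric vectors of paired observations.
#' @return List of class `wilcoxon_paired` with `statistic` (W, the sum
#'   of positive-difference ranks), `n` (non-zero pairs), `p_value`,
#'   `method`.
#' @export
wilcoxon_paired <- function(a, b) {
  if (length(a) != length(b)) abort_synloss("`a` and `b` must have equal length")
  d <- a - b
  d <- d[!is.na(d) & d != 0]
  if (length(d) == 0) abort_synloss("no non-zero pairs")
  n <- length(d)
  if (n < 5) abort_synloss("need at least 5 non-zero pairs")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= 12) {
    # exact: enumerate every sign assignment of the midranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    wsim <- as.numeric(signs %*% r)
    p <- mean(abs(wsim - mu) >= abs(w - mu) - 1e-9)
    method <- "exact_enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approximation"
  }
  structure(list(statistic = w, n = n, p_value = min(1, p), method = method),
            class = "wilcoxon_paired")
}

#' @export
print.wilcoxon_paired <- function(x, ...) {
  cat(sprintf("<wilcoxon_paired: W = %.1f, n = %d, two-sided p = %.4g (%s)>\n",
              x$statistic, x$n, x$p_value, x$method))
  invisible(x)
}

#' Gene-size bias diagnostics
#'
#' Checks whether a missing-gene set is biased towards short (or long)
#' genes relative to the background of retained genes: a one-way ANOVA
#' on log-transformed CDS lengths, the fraction of short genes
#' (CDS < `short_gene_bp`) per group, and the correlation between CDS
#' length and cross-species percent amino-acid identity within the
#' missing set (Pearson by default; a linear relationship is what the
#' diagnostic looks for, Spearman available as an option).
#'
#' @param missing_lengths Positive CDS lengths (bp) of the missing set.
#' @param background_lengths Positive CDS lengths of the background set.
#' @param identities Optional percent amino-acid identities aligned with
#'   `missing_lengths`.
#' @param short_gene_bp Cutoff defining a short gene (default 500).
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @return Object of class `size_bias` with the ANOVA F and p, per-group
#'   short fractions, group sizes, and (when identities are supplied) the
#'   correlation estimate and p-value.
#' @export
size_bias_report <- function(missing_lengths, background_lengths,
                             identities = NULL, short_gene_bp = 500,
                             cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  if (length(missing_lengths) < 2 || length(background_lengths) < 2) {
    abort_synloss("each group needs at least 2 values")
  }
  if (any(c(missing_lengths, background_lengths) <= 0)) {
    abort_synloss("lengths must be positive")
  }
  dat <- data.frame(
    loglen = log(c(missing_lengths, background_lengths)),
    group = factor(rep(c("missing", "background"),
                       c(length(missing_lengths), length(background_lengths))))
  )
  fit <- stats::anova(stats::lm(loglen ~ group, data = dat))
  res <- list(
    f_statistic = fit$`F value`[1],
    p_value = fit$`Pr(>F)`[1],
    short_fraction_missing = mean(missing_lengths < short_gene_bp),
    short_fraction_background = mean(background_lengths < short_gene_bp),
    short_gene_bp = short_gene_bp,
    n_missing = length(missing_lengths),
    n_background = length(background_lengths),
    correlation = NULL
  )
  if (!is.null(identities)) {
    if (length(identities) != length(missing_lengths)) {
      abort_synloss("`identities` must align with `missing_lengths`")
    }
    ct <- stats::cor.test(missing_lengths, identities, method = cor_method)
    res$correlation <- list(estimate = unname(ct$estimate),
                            p_value = ct$p.value, method = cor_method)
  }
  structure(res, class = "size_bias")
}

#' @export
print.size_bias <- function(x, ...) {
  cat(sprintf(
    "<size_bias: log-ANOVA F = %.4g, p = %.3g; short (<%g bp) %.1f%% vs %.1f%%>\n",
    x$f_statistic, x$p_value, x$short_gene_bp,
    100 * x$short_fraction_missing, 100 * x$short_fraction_background))
  if (!is.null(x$correlation)) {
    cat(sprintf("  length vs %%AA identity: %s r = %.3f, p = %.3g\n",
                x$correlation$method, x$correlation$estimate,
                x$correlation$p_value))
  }
  invisible(x)
}
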