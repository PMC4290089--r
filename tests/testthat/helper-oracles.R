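# Independent brute-force oracles. Each re-derives the expected result by
# a different route than the implementation (exhaustive enumeration or
# textbook closed forms) so implementation defects cannot cancel out.

# exhaustive maximal-run enumeration of qualifying deletion blocks: try
# every (i, j) window, keep windows that are all-missing, on one
# chromosome, maximal, and pass the tier criteria
oracle_blocks <- function(chr, start, end, missing, th = loss_thresholds()) {
  n <- length(chr)
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      idx <- i:j
      if (!all(missing[idx])) next
      if (length(unique(chr[idx])) != 1L) next
      left_open <- i == 1 || chr[i - 1] != chr[i] || !missing[i - 1]
      right_open <- j == n || chr[j + 1] != chr[j] || !missing[j + 1]
      if (!left_open || !right_open) next
      span <- max(end[idx]) - min(start[idx])
      k <- length(idx)
      tier <- if (k >= th$min_block_genes) "multi_gene"
      else if (span >= th$min_block_span) "large_singlet_or_doublet"
      else if (k == 2 && span >= th$doublet_min_span) "small_doublet"
      else NA_character_
      if (!is.na(tier)) {
        out[[length(out) + 1L]] <- list(members = idx, n = k, span = span,
                                        tier = tier, chromosome = chr[i])
      }
    }
  }
  out
}

# exact two-sided signed-rank p-value by explicit bitmask enumeration of
# sign assignments (counts assignments at least as extreme about the mean)
oracle_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    pos <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    w <- sum(r[pos])
    if (abs(w - mu) >= abs(w_obs - mu) - 1e-9) count <- count + 1L
  }
  count / 2^n
}

# two-tailed Fisher p by hypergeometric enumeration: sum probabilities of
# all tables (same margins) no more probable than the observed one
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + c_          # set size
  k <- a + b           # term carriers
  nn <- a + b + c_ + d
  p_obs <- stats::dhyper(a, k, nn - k, m)
  xs <- max(0, k + m - nn):min(k, m)
  sum(vapply(xs, function(x) {
    p <- stats::dhyper(x, k, nn - k, m)
    if (p <= p_obs * (1 + 1e-7)) p else 0
  }, numeric(1)))
}

# textbook Benjamini-Hochberg step-up adjusted p-values
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# one-way ANOVA F from first principles (sums of squares)
oracle_anova_f <- function(x, g) {
  g <- factor(g)
  grand <- mean(x)
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(g) - 1
  df2 <- length(x) - nlevels(g)
  (ssb / df1) / (ssw / df2)
}

# random single-chromosome-set block instance for property tests
random_block_instance <- function(n_genes = NULL) {
  n <- n_genes %||% sample(5:50, 1)
  n_chr <- sample(1:3, 1)
  chr <- as.character(sort(sample.int(n_chr, n, replace = TRUE)))
  lay <- gene_layout(n, chr = chr,
                     gene_len = sample(c(2000, 20000, 60000), n, replace = TRUE),
                     gap = 5000)
  missing <- stats::runif(n) < 0.35
  list(layout = lay, missing = missing)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
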