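# Matched-control generation, permutation enrichment, Fisher tests and
# cross-species Venn classification.

#' Control-set requirements matching a block set
#'
#' Converts detected blocks into the per-block requirements a matched
#' control set must satisfy: same chromosome, same gene count, same span
#' (up to the configured tolerance).
#'
#' @param blocks A `block_set`.
#' @return Tibble with columns `chromosome`, `n_genes`, `span`.
#' @export
control_spec_from_blocks <- function(blocks) {
  tibble::tibble(chromosome = blocks$chromosome,
                 n_genes = blocks$n_genes,
                 span = blocks$span)
}

#' Generate block-structure-matched control gene sets
#'
#' Emulates the matched-control construction of the screen: for each
#' required block of N genes on a given chromosome, a random seed gene is
#' drawn from that chromosome and the run of N consecutive 1-to-1
#' orthologs starting there is accepted only if all N genes lie on the
#' required chromosome and appear in the same syntenic order in both
#' reference species (colinear: one chromosome in the second species with
#' monotone coordinates). When a target span is given, the run's span
#' must match it within `span_tolerance`. Draws are seeded
#' (Mersenne-Twister): the same seed reproduces the same sets exactly.
#'
#' @param tbl An `ortholog_tbl`; the first two species (or
#'   `species_pair`) define the orderings.
#' @param requirements Tibble with columns `chromosome`, `n_genes` and
#'   optionally `span` (NA disables span matching); see
#'   [control_spec_from_blocks()].
#' @param n_sets Number of independent control sets.
#' @param seed Integer seed.
#' @param species_pair The two reference species (default: first two of
#'   the table).
#' @param exclude Gene ids control blocks may never contain (typically
#'   the missing set); `NULL` to disable.
#' @param allow_overlap Allow control blocks within one set to share
#'   genes (default `FALSE`).
#' @param max_attempts Rejection-sampling budget per requirement; an
#'   unsatisfiable requirement raises an error naming it.
#' @param thresholds A [loss_thresholds()] object or list (supplies
#'   `span_tolerance`).
#' @return Object of class `control_sets`: a list of character vectors
#'   of gene ids, with an `audit` attribute (tibble: `set`,
#'   `requirement`, `attempts`).
#' @export
generate_control_sets <- function(tbl, requirements, n_sets, seed,
                                  species_pair = ortholog_species(tbl)[1:2],
                                  exclude = NULL, allow_overlap = FALSE,
                                  max_attempts = 1000L,
                                  thresholds = loss_thresholds()) {
  thresholds <- as_thresholds(thresholds)
  check_species(tbl, species_pair)
  requirements <- tibble::as_tibble(requirements)
  if (!("span" %in% names(requirements))) requirements$span <- NA_real_
  if (nrow(requirements) == 0) {
    return(structure(rep(list(character()), n_sets),
                     audit = tibble::tibble(set = integer(),
                                            requirement = integer(),
                                            attempts = integer()),
                     class = "control_sets"))
  }
  sa <- species_pair[1]; sb <- species_pair[2]
  tbl <- sort_ortholog_table(tbl, sa)
  va <- species_view(tbl, sa)
  vb <- species_view(tbl, sb)
  eligible <- !is.na(va$chr) & va$placed & !is.na(vb$chr) & vb$placed &
    tbl[[sp_col(sb, "class")]] %in% ONE2ONE_CLASSES
  va <- va[eligible, , drop = FALSE]
  vb <- vb[eligible, , drop = FALSE]
  bad_chr <- setdiff(requirements$chromosome, va$chr)
  if (length(bad_chr) > 0) {
    abort_synloss(paste0("requirement chromosome(s) absent from eligible genes: ",
                         paste(bad_chr, collapse = ", ")))
  }
  chr_idx <- split(seq_len(nrow(va)), va$chr)

  draw_block <- function(req, used) {
    pool <- chr_idx[[req$chromosome]]
    m <- length(pool)
    if (m < req$n_genes) return(NULL)
    starts <- seq_len(m - req$n_genes + 1L)
    for (att in seq_len(max_attempts)) {
      s <- starts[sample.int(length(starts), 1L)]
      idx <- pool[s:(s + req$n_genes - 1L)]
      genes <- va$gene_id[idx]
      if (!allow_overlap && any(genes %in% used)) next
      if (!is.null(exclude) && any(genes %in% exclude)) next
      # colinear in the second species: one chromosome, monotone order
      bchr <- vb$chr[idx]
      if (length(unique(bchr)) != 1L) next
      bst <- vb$start[idx]
      if (length(idx) > 1L &&
          !(all(diff(bst) > 0) || all(diff(bst) < 0))) next
      if (!is.na(req$span)) {
        span <- max(va$end[idx]) - min(va$start[idx])
        if (abs(span - req$span) > thresholds$span_tolerance * req$span) next
      }
      return(list(genes = genes, attempts = att))
    }
    NULL
  }

  audit <- list()
  sets <- withr::with_seed(seed, {
    lapply(seq_len(n_sets), function(k) {
      used <- character()
      out <- character()
      for (j in seq_len(nrow(requirements))) {
        blk <- draw_block(requirements[j, ], used)
        if (is.null(blk)) {
          abort_synloss(sprintf(
            "requirement %d (chromosome %s, %d genes) unsatisfiable after %d attempts",
            j, requirements$chromosome[j], requirements$n_genes[j],
            max_attempts))
        }
        audit[[length(audit) + 1L]] <<- tibble::tibble(
          set = k, requirement = j, attempts = blk$attempts)
        used <- c(used, blk$genes)
        out <- c(out, blk$genes)
      }
      out
    })
  })
  structure(sets,
            audit = dplyr::bind_rows(audit),
            class = "control_sets")
}

#' @export
print.control_sets <- function(x, ...) {
  cat(sprintf("<control_sets: %d sets of %s gene(s)>\n", length(x),
              if (length(x) > 0) length(x[[1]]) else 0))
  invisible(x)
}

# logical gene x term membership matrix over a universe
membership_matrix <- function(ann, universe, exclude_terms = character()) {
  ann <- tibble::as_tibble(ann)
  catalog <- attr(ann, "catalog")
  drop <- unique(c(
    exclude_terms,
    catalog$term_id[catalog$label %in% exclude_terms]
  ))
  ann <- ann[ann$gene_id %in% universe & !(ann$term_id %in% drop), ,
             drop = FALSE]
  terms <- sort(unique(ann$term_id))
  m <- matrix(FALSE, nrow = length(universe), ncol = length(terms),
              dimnames = list(universe, terms))
  if (nrow(ann) > 0) {
    m[cbind(match(ann$gene_id, universe), match(ann$term_id, terms))] <- TRUE
  }
  m
}

perm_p <- function(null, obs, n, exhaustive) {
  ge <- sum(null >= obs)
  le <- sum(null <= obs)
  if (exhaustive) min(1, 2 * max(min(ge, le), 1) / n)
  else min(1, 2 * min(ge + 1, le + 1) / (n + 1))
}

#' Permutation enrichment test against matched control sets
#'
#' Compares a gene set's annotation burden with its distribution over
#' control sets: the total statistic is the number of genes carrying at
#' least one term; the per-term statistic is the number of genes carrying
#' that term. Two-sided p-values double the smaller tail; by default the
#' add-one correction `(b + 1) / (n + 1)` is applied (so
#' `p >= 1/(n + 1)`), capped at 1. Per-term p-values receive
#' Benjamini-Hochberg FDR correction across all tested terms. For
#' phenotype-sourced annotations the catch-all term labelled
#' "No abnormal phenotype detected" is excluded from all statistics.
#'
#' @param genes Character vector, the observed gene set (non-empty).
#' @param annotation An `annotation_tbl` covering the gene universe.
#' @param universe Character vector of all eligible gene ids (the set
#'   must be drawn from it).
#' @param controls Optional `control_sets` (or list of gene-id vectors)
#'   supplying the null; when `NULL`, simple random sets of the same size
#'   are drawn from `universe`.
#' @param n_permutations Number of random sets when `controls` is `NULL`.
#' @param seed Integer seed for random null sets.
#' @param per_term Also compute the per-term table (default `TRUE`).
#' @param exhaustive Set to `TRUE` when `controls` enumerate the complete
#'   null (e.g. all subsets of a toy universe): tail probabilities are
#'   then exact proportions without the add-one correction.
#' @param exclude_terms Term ids or labels to drop; defaults to
#'   "No abnormal phenotype detected" for phenotype annotations.
#' @return Object of class `permutation_result`: list with `observed`,
#'   `null_mean`, `null_sd`, `n_permutations`, `p_value` and, when
#'   `per_term`, a `terms` tibble (`term_id`, `label`, `observed`,
#'   `expected`, `p_value`, `q_value`). `tidy()` returns the per-term
#'   table, `glance()` the set-level test.
#' @export
permutation_test <- function(genes, annotation, universe, controls = NULL,
                             n_permutations = 1000L, seed = 1L,
                             per_term = TRUE, exhaustive = FALSE,
                             exclude_terms = NULL) {
  if (length(genes) == 0) abort_synloss("`genes` must be non-empty")
  if (!all(genes %in% universe)) {
    abort_synloss("`genes` must be a subset of `universe`")
  }
  if (is.null(exclude_terms)) {
    exclude_terms <- if (identical(attr(annotation, "source"), "phenotype"))
      "No abnormal phenotype detected" else character()
  }
  m <- membership_matrix(annotation, universe, exclude_terms)
  has_any <- rowSums(m) > 0
  set_idx <- match(genes, universe)
  obs_total <- sum(has_any[set_idx])

  if (is.null(controls)) {
    controls <- withr::with_seed(seed, {
      lapply(seq_len(n_permutations), function(i) {
        sample.int(length(universe), length(genes))
      })
    })
  } else {
    controls <- lapply(controls, function(g) match(g, universe))
    if (any(vapply(controls, anyNA, logical(1)))) {
      abort_synloss("control sets contain genes outside `universe`")
    }
  }
  nperm <- length(controls)
  null_total <- vapply(controls, function(idx) sum(has_any[idx]), numeric(1))
  p_total <- perm_p(null_total, obs_total, nperm, exhaustive)

  terms_tbl <- NULL
  if (per_term && ncol(m) > 0) {
    obs_term <- colSums(m[set_idx, , drop = FALSE])
    null_term <- vapply(controls, function(idx) {
      colSums(m[idx, , drop = FALSE])
    }, numeric(ncol(m)))
    null_term <- matrix(null_term, nrow = ncol(m))  # terms x perms
    p_term <- vapply(seq_len(ncol(m)), function(j) {
      perm_p(null_term[j, ], obs_term[j], nperm, exhaustive)
    }, numeric(1))
    catalog <- attr(annotation, "catalog")
    terms_tbl <- tibble::tibble(
      term_id = colnames(m),
      label = catalog$label[match(colnames(m), catalog$term_id)],
      observed = as.numeric(obs_term),
      expected = rowMeans(null_term),
      p_value = p_term,
      q_value = stats::p.adjust(p_term, method = "BH")
    )
  }
  structure(list(
    observed = obs_total,
    null_mean = mean(null_total),
    null_sd = stats::sd(null_total),
    n_permutations = nperm,
    p_value = p_total,
    terms = terms_tbl,
    excluded_terms = exclude_terms,
    null_total = null_total
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result: observed %g vs null %.2f +/- %.2f (%d permutations), two-sided p = %.4g>\n",
    x$observed, x$null_mean, x$null_sd, x$n_permutations, x$p_value))
  if (!is.null(x$terms)) {
    cat(sprintf("  %d term(s) tested; %d with q < 0.05\n",
                nrow(x$terms), sum(x$terms$q_value < 0.05)))
  }
  invisible(x)
}

#' Fisher's exact term enrichment
#'
#' Two-tailed Fisher's exact test per term on the 2x2 table
#' (in set & term, in set & no term; background-only & term,
#' background-only & no term). Terms with no carrier in the background
#' are skipped and recorded in the `skipped` attribute.
#'
#' @param set_genes Character vector, the gene set (must be a subset of
#'   the background).
#' @param background_genes Character vector, the full gene universe
#'   including the set.
#' @param annotation An `annotation_tbl`.
#' @param alpha Significance cutoff for the `enriched` flag (default
#'   0.05; the flag is `p < alpha`, with a `direction` column
#'   distinguishing over- from under-representation).
#' @return Tibble of class `fisher_enrichment` with columns `term_id`,
#'   `label`, `set_with`, `set_without`, `bg_with`, `bg_without`,
#'   `odds_ratio`, `p_value`, `direction`, `enriched`.
#' @export
fisher_term_enrichment <- function(set_genes, background_genes, annotation,
                                   alpha = 0.05) {
  if (!all(set_genes %in% background_genes)) {
    abort_synloss("`set_genes` must be a subset of `background_genes`")
  }
  m <- membership_matrix(annotation, background_genes)
  in_set <- background_genes %in% set_genes
  catalog <- attr(annotation, "catalog")
  all_terms <- unique(tibble::as_tibble(annotation)$term_id)
  skipped <- setdiff(all_terms, colnames(m))
  rows <- lapply(colnames(m), function(t) {
    carrier <- m[, t]
    a <- sum(carrier & in_set)
    b <- sum(carrier & !in_set)
    c_ <- sum(!carrier & in_set)
    d <- sum(!carrier & !in_set)
    ft <- stats::fisher.test(matrix(c(a, c_, b, d), nrow = 2),
                             alternative = "two.sided")
    exp_a <- sum(carrier) * sum(in_set) / length(in_set)
    tibble::tibble(
      term_id = t,
      label = catalog$label[match(t, catalog$term_id)],
      set_with = a, set_without = c_, bg_with = b, bg_without = d,
      odds_ratio = unname(ft$estimate),
      p_value = ft$p.value,
      direction = ifelse(a >= exp_a, "over", "under"),
      enriched = ft$p.value < alpha
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(term_id = character(), label = character(),
                          set_with = numeric(), set_without = numeric(),
                          bg_with = numeric(), bg_without = numeric(),
                          odds_ratio = numeric(), p_value = numeric(),
                          direction = character(), enriched = logical())
  }
  if (length(skipped) > 0) {
    message(sprintf("skipped %d term(s) absent from the background",
                    length(skipped)))
  }
  structure(out, alpha = alpha, skipped = skipped,
            class = c("fisher_enrichment", class(tibble::tibble())))
}

# most species-inclusive first, used for conflict resolution
VENN_GROUP_RANK <- c(B2 = 4, A = 3, C = 2, B1 = 1, none = 0)

venn_region_group <- function(in_chicken, in_human, in_lizard) {
  dplyr::case_when(
    !in_chicken & in_human            ~ "A",   # human only, human+lizard
    in_chicken & in_human             ~ "B2",  # chicken+human(, +lizard)
    in_chicken & !in_human & !in_lizard ~ "B1",
    !in_human & in_lizard             ~ "C",   # lizard only, chicken+lizard
    .default = "none"
  )
}

#' Classify enriched terms into cross-species Venn groups
#'
#' Maps the seven regions of the chicken/human/lizard enrichment Venn
#' diagram onto interpretation groups: terms enriched in non-avian
#' species but not birds (human only, or human and lizard) form Group A
#' (losses plausibly compensated in birds); terms enriched in birds only
#' form Group B1; terms enriched in birds plus humans and/or lizard form
#' Group B2 (no apparent compensation anywhere); terms enriched in lizard
#' only or chicken and lizard but not humans form Group C. Terms enriched
#' nowhere map to `none`.
#'
#' When a gene-to-term map is supplied, genes associated with terms from
#' several groups are resolved by the screen's rule: if the conflicting
#' terms are descriptively similar (judged by the `similar` hook), the
#' gene goes to the most species-inclusive group (B2 over A over C over
#' B1); if they describe different functions, the gene is listed in every
#' group. The default hook treats only identical term ids as similar — a
#' stand-in for ontology-aware ancestor matching, not a claim of
#' equivalence.
#'
#' @param chicken,human,lizard Character vectors of enriched term ids per
#'   species context (the bird, the mammal, the non-avian sauropsid).
#' @param gene_terms Optional tibble (`gene_id`, `term_id`) restricted to
#'   enriched terms, enabling per-gene group membership.
#' @param similar Optional `function(term_a, term_b)` returning `TRUE`
#'   when two terms describe the same function.
#' @return Object of class `venn_groups`: list with `terms` (tibble:
#'   `term_id`, `in_chicken`, `in_human`, `in_lizard`, `group`) and
#'   `genes` (tibble: `gene_id`, `groups` list column, `resolution`; or
#'   `NULL`).
#' @export
venn_group_classify <- function(chicken, human, lizard,
                                gene_terms = NULL, similar = NULL) {
  vocab <- sort(unique(c(chicken, human, lizard)))
  terms <- tibble::tibble(
    term_id = vocab,
    in_chicken = vocab %in% chicken,
    in_human = vocab %in% human,
    in_lizard = vocab %in% lizard
  )
  terms$group <- venn_region_group(terms$in_chicken, terms$in_human,
                                   terms$in_lizard)
  genes <- NULL
  if (!is.null(gene_terms)) {
    if (is.null(similar)) similar <- function(a, b) identical(a, b)
    gene_terms <- tibble::as_tibble(gene_terms)
    gene_terms$group <- terms$group[match(gene_terms$term_id, terms$term_id)]
    gene_terms <- gene_terms[!is.na(gene_terms$group) &
                               gene_terms$group != "none", , drop = FALSE]
    genes <- dplyr::bind_rows(lapply(split(gene_terms, gene_terms$gene_id),
                                     function(d) {
      grp <- unique(d$group)
      if (length(grp) == 1L) {
        return(tibble::tibble(gene_id = d$gene_id[1], groups = list(grp),
                              resolution = "single_group"))
      }
      # any cross-group pair of similar terms -> collapse to the most
      # species-inclusive group
      pairs <- expand.grid(a = seq_len(nrow(d)), b = seq_len(nrow(d)))
      pairs <- pairs[d$group[pairs$a] != d$group[pairs$b], , drop = FALSE]
      any_similar <- any(mapply(function(i, j) {
        isTRUE(similar(d$term_id[i], d$term_id[j]))
      }, pairs$a, pairs$b))
      if (any_similar) {
        best <- grp[which.max(VENN_GROUP_RANK[grp])]
        tibble::tibble(gene_id = d$gene_id[1], groups = list(best),
                       resolution = "similar_terms_most_inclusive")
      } else {
        tibble::tibble(gene_id = d$gene_id[1],
                       groups = list(sort(grp)),
                       resolution = "dissimilar_terms_listed_in_each")
      }
    }))
  }
  structure(list(terms = terms, genes = genes), class = "venn_groups")
}

#' @export
print.venn_groups <- function(x, ...) {
  tab <- table(factor(x$terms$group, levels = c("A", "B1", "B2", "C", "none")))
  cat("<venn_groups: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ">\n",
      sep = "")
  invisible(x)
}
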