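#' Identify candidate lineage-missing genes
#'
#' Restricts the ortholog table to genes with a strict or apparent
#' 1-to-1 ortholog between the two reference species (the apparent class
#' is pooled with strict 1-to-1), then flags as candidates the genes with
#' no ortholog of any class in any focal species. The resulting counts
#' satisfy `n_candidates = n_reference_1to1 - n_with_focal_ortholog`.
#'
#' @param tbl An `ortholog_tbl` whose defining species is the first
#'   element of `reference_pair`.
#' @param reference_pair Character vector of the two reference species.
#' @param focal Character vector of one or more focal (screened) species.
#' @return An object of class `candidate_set`: a list with `genes` (a
#'   tibble of candidate rows with a per-focal-species presence matrix for
#'   the restricted gene set), `counts`, `reference_pair` and `focal`.
#'   `tidy()` returns the per-gene tibble, `glance()` the counts.
#' @export
identify_candidates <- function(tbl, reference_pair, focal) {
  if (length(reference_pair) != 2) {
    abort_synloss("`reference_pair` must name exactly two species")
  }
  check_species(tbl, c(reference_pair, focal))
  if (reference_pair[1] != ortholog_species(tbl)[1]) {
    abort_synloss("first reference species must be the table's defining species")
  }
  cls2 <- tbl[[sp_col(reference_pair[2], "class")]]
  ref <- tbl[!is.na(tbl[[sp_col(reference_pair[2], "id")]]) &
               cls2 %in% ONE2ONE_CLASSES, , drop = FALSE]
  presence <- vapply(focal, function(s) {
    !is.na(ref[[sp_col(s, "id")]])
  }, logical(nrow(ref)))
  presence <- matrix(presence, nrow = nrow(ref),
                     dimnames = list(NULL, focal))
  has_focal <- rowSums(presence) > 0
  genes <- tibble::tibble(gene_id = ref$gene_id, candidate = !has_focal)
  for (s in focal) genes[[paste0("present_", s)]] <- presence[, s]
  counts <- tibble::tibble(
    n_reference_1to1 = nrow(ref),
    n_with_focal_ortholog = sum(has_focal),
    n_candidates = sum(!has_focal)
  )
  structure(
    list(genes = genes, counts = counts,
         reference_pair = reference_pair, focal = focal),
    class = "candidate_set"
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf(
    "<candidate_set: %d of %d reference 1-to-1 genes lack any ortholog in {%s}>\n",
    x$counts$n_candidates, x$counts$n_reference_1to1,
    paste(x$focal, collapse = ", ")))
  invisible(x)
}

#' Candidate gene ids of a candidate set
#' @param x A `candidate_set`.
#' @return Character vector of candidate gene ids.
#' @export
candidate_genes <- function(x) x$genes$gene_id[x$genes$candidate]

#' Flag candidate genes in an ortholog table
#'
#' Adds (or overwrites) a logical `missing` column marking the given
#' genes, ready for block detection.
#'
#' @param tbl An `ortholog_tbl`.
#' @param genes Character vector of missing gene ids, or a
#'   `candidate_set`.
#' @return The `ortholog_tbl` with a `missing` column.
#' @export
flag_missing <- function(tbl, genes) {
  if (inherits(genes, "candidate_set")) genes <- candidate_genes(genes)
  tbl$missing <- tbl$gene_id %in% genes
  tbl
}

#' Build and apply a curation ledger
#'
#' A curation ledger records the manual verification campaign that turns
#' an initial candidate count into a final confirmed count: each
#' adjustment adds newly recognised genes (e.g. loci present in the
#' genome but lacking a gene model) or removes candidates shown to exist
#' in the focal lineage. The running total may never go negative.
#'
#' @param start Starting count (non-negative integer).
#' @param labels Character vector describing each adjustment.
#' @param deltas Signed integer vector, same length as `labels`.
#' @return `curation_ledger()` returns a `curation_ledger` object;
#'   `apply_curation_ledger()` returns a `curation_audit`: a list with
#'   `final` (the closing count) and `audit` (a tibble of running
#'   totals, one row per step including the opening balance).
#' @examples
#' led <- curation_ledger(537,
#'   c("no-model additions", "reannotated models", "database hits",
#'     "alignment hits", "WGS hits"),
#'   c(25, 50, -89, -75, -174))
#' apply_curation_ledger(led)$final  # 274
#' @export
curation_ledger <- function(start, labels = character(), deltas = integer()) {
  if (length(labels) != length(deltas)) {
    abort_synloss("`labels` and `deltas` must have the same length")
  }
  if (is.na(start) || start < 0) abort_synloss("`start` must be non-negative")
  structure(list(start = as.integer(start),
                 adjustments = tibble::tibble(label = as.character(labels),
                                              delta = as.integer(deltas))),
            class = "curation_ledger")
}

#' @rdname curation_ledger
#' @param ledger A `curation_ledger`.
#' @export
apply_curation_ledger <- function(ledger) {
  stopifnot(inherits(ledger, "curation_ledger"))
  totals <- ledger$start + cumsum(c(0L, ledger$adjustments$delta))
  if (any(totals < 0)) {
    first <- which(totals < 0)[1] - 1L
    abort_synloss(sprintf(
      "running total becomes negative (%d) after adjustment %d (%s)",
      totals[first + 1L], first, ledger$adjustments$label[first]),
      class = "synloss_record_error")
  }
  audit <- tibble::tibble(
    step = seq_along(totals) - 1L,
    label = c("start", ledger$adjustments$label),
    delta = c(NA_integer_, ledger$adjustments$delta),
    running_total = totals
  )
  structure(list(final = totals[length(totals)], audit = audit),
            class = "curation_audit")
}

#' @export
print.curation_audit <- function(x, ...) {
  cat(sprintf("<curation_audit: final count %d>\n", x$final))
  print(x$audit, ...)
  invisible(x)
}

#' Classify alignment hits for one query gene
#'
#' Applies the hit-acceptance rules of the screen: hits with alignment
#' score less than or equal to `min_hit_score` are discarded (the cutoff
#' is a strict "greater than" rule). Among surviving hits, a hit whose
#' reciprocal best alignment maps back to the query gene itself is taken
#' as evidence the gene is present in the focal genome
#' (`found_in_focal`); a reciprocal best mapping to a different gene
#' marks a related family member or paralog
#' (`family_member_or_paralog`); a hit landing on an unplaced segment
#' with no synteny evidence is `unresolved_unplaced` (conservatively
#' treated as "present" downstream, i.e. removed from the missing list);
#' otherwise the verdict is `not_found`. The verdict is invariant to the
#' order of the hit list.
#'
#' @param query_gene_id The query gene.
#' @param hits Data frame of hits for this query (see
#'   [read_alignment_hits()] for columns); may be empty.
#' @param thresholds A [loss_thresholds()] object or list.
#' @return A one-row tibble of class `hit_verdict` with columns
#'   `query_gene_id`, `verdict`, `n_hits_considered`, `supporting_hits`
#'   (list column of row indices into the score-filtered hit list, in
#'   input order).
#' @export
classify_alignment_hits <- function(query_gene_id, hits,
                                    thresholds = loss_thresholds()) {
  thresholds <- as_thresholds(thresholds)
  hits <- validate_hits(hits[hits$query_gene_id == query_gene_id |
                               is.na(hits$query_gene_id), , drop = FALSE])
  keep <- hits[!is.na(hits$score) & hits$score > thresholds$min_hit_score, ,
               drop = FALSE]
  verdict <- "not_found"
  supporting <- integer()
  if (nrow(keep) > 0) {
    self_hit <- !is.na(keep$reciprocal_best) & keep$reciprocal_best == query_gene_id
    other_hit <- !is.na(keep$reciprocal_best) & keep$reciprocal_best != query_gene_id
    unplaced <- !keep$target_placed & !(keep$synteny_ok %in% TRUE)
    if (any(self_hit)) {
      verdict <- "found_in_focal"
      supporting <- which(self_hit)
    } else if (any(other_hit)) {
      verdict <- "family_member_or_paralog"
      supporting <- which(other_hit)
    } else if (any(unplaced)) {
      verdict <- "unresolved_unplaced"
      supporting <- which(unplaced)
    }
  }
  out <- tibble::tibble(
    query_gene_id = query_gene_id,
    verdict = verdict,
    n_hits_considered = nrow(keep),
    supporting_hits = list(supporting)
  )
  class(out) <- c("hit_verdict", class(out))
  out
}

#' Remove candidates contradicted by alignment evidence
#'
#' Runs [classify_alignment_hits()] for every candidate with hits and
#' drops from the missing list genes found in the focal genome. By
#' default the conservative rule is applied: unresolved hits on unplaced
#' segments also count as removals.
#'
#' @param genes Character vector of candidate gene ids.
#' @param hits Hit table covering any subset of the candidates.
#' @param thresholds A [loss_thresholds()] object or list.
#' @param drop_unresolved_unplaced Treat `unresolved_unplaced` verdicts as
#'   evidence of presence (default `TRUE`).
#' @return List with `missing` (surviving gene ids) and `verdicts`
#'   (tibble of per-gene verdicts).
#' @export
screen_hits <- function(genes, hits, thresholds = loss_thresholds(),
                        drop_unresolved_unplaced = TRUE) {
  hits <- validate_hits(hits)
  verdicts <- dplyr::bind_rows(lapply(genes, function(g) {
    classify_alignment_hits(g, hits, thresholds)
  }))
  removed <- c("found_in_focal",
               if (drop_unresolved_unplaced) "unresolved_unplaced")
  list(missing = verdicts$query_gene_id[!(verdicts$verdict %in% removed)],
       verdicts = verdicts)
}
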