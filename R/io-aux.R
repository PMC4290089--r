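#' Gene-to-term annotation table
#'
#' A deduplicated multimap from gene ids to functional terms (MGI-style
#' mouse phenotypes, OMIM-style disease terms, or GO terms). Duplicate
#' (gene, term) pairs are collapsed with a message rather than an error.
#'
#' @param entries Data frame with columns `gene_id` and `term_id`.
#' @param catalog Optional data frame with columns `term_id` and `label`;
#'   defaults to labels equal to the term ids. Every term used in
#'   `entries` must appear in the catalog.
#' @param source One of `"phenotype"`, `"disease"`, `"go"`; tags the
#'   vocabulary so that source-specific rules (such as excluding the
#'   "No abnormal phenotype detected" term from permutation statistics)
#'   can be applied downstream.
#' @return A tibble of class `annotation_tbl` with `catalog` and `source`
#'   attributes.
#' @export
annotation_table <- function(entries, catalog = NULL,
                             source = c("phenotype", "disease", "go")) {
  source <- match.arg(source)
  entries <- tibble::as_tibble(entries)
  if (!all(c("gene_id", "term_id") %in% names(entries))) {
    abort_synloss("`entries` needs columns gene_id and term_id",
                  class = "synloss_format_error")
  }
  entries <- entries[c("gene_id", "term_id")]
  ndup <- sum(duplicated(entries))
  if (ndup > 0) {
    message(sprintf("collapsed %d duplicate (gene, term) pair(s)", ndup))
    entries <- dplyr::distinct(entries)
  }
  if (is.null(catalog)) {
    catalog <- tibble::tibble(term_id = sort(unique(entries$term_id)))
    catalog$label <- catalog$term_id
  } else {
    catalog <- tibble::as_tibble(catalog)
    if (!all(c("term_id", "label") %in% names(catalog))) {
      abort_synloss("`catalog` needs columns term_id and label",
                    class = "synloss_format_error")
    }
    orphan <- setdiff(entries$term_id, catalog$term_id)
    if (length(orphan) > 0) {
      abort_synloss(paste0("term(s) missing from catalog: ",
                           paste(utils::head(orphan, 5), collapse = ", ")),
                    class = "synloss_format_error")
    }
  }
  structure(entries,
            catalog = catalog, source = source,
            class = c("annotation_tbl", class(tibble::tibble())))
}

#' @export
print.annotation_tbl <- function(x, ...) {
  cat(sprintf("<annotation_tbl (%s): %d pairs, %d genes, %d terms>\n",
              attr(x, "source"), nrow(x),
              dplyr::n_distinct(x$gene_id), dplyr::n_distinct(x$term_id)))
  NextMethod()
}

#' Per-gene term counts of an annotation table
#' @param ann An `annotation_tbl`.
#' @return Tibble with columns `gene_id`, `n_terms`.
#' @export
annotation_counts <- function(ann) {
  dplyr::count(tibble::as_tibble(ann), .data$gene_id, name = "n_terms")
}

#' Read / write annotation tables as TSV
#'
#' The entries file is a two-column TSV (`gene_id`, `term_id`); an
#' optional label file is a two-column TSV (`term_id`, `label`). An empty
#' or header-only file yields an empty table.
#'
#' @param path Path to the entries TSV.
#' @param catalog_path Optional path to the term-label TSV.
#' @param source Vocabulary tag, see [annotation_table()].
#' @return An `annotation_tbl`.
#' @export
read_annotation_table <- function(path, catalog_path = NULL,
                                  source = c("phenotype", "disease", "go")) {
  empty <- tibble::tibble(gene_id = character(), term_id = character())
  if (file.size(path) == 0) {
    return(annotation_table(empty, source = source))
  }
  dat <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(dat))) {
    abort_synloss("annotation TSV must have header: gene_id, term_id",
                  class = "synloss_format_error")
  }
  catalog <- NULL
  if (!is.null(catalog_path)) {
    catalog <- readr::read_tsv(catalog_path, col_types = "cc", progress = FALSE)
  }
  annotation_table(dat, catalog = catalog, source = source)
}

#' @rdname read_annotation_table
#' @param ann An `annotation_tbl` to write.
#' @export
write_annotation_table <- function(ann, path) {
  readr::write_tsv(tibble::as_tibble(ann), path, progress = FALSE)
  invisible(path)
}

#' Assembly metadata: chromosome lengths and placement
#'
#' @param data Data frame with columns `chromosome`, `length` and
#'   optionally `placed` (defaults to `TRUE`). Lengths must be positive.
#' @return A tibble of class `assembly_meta`; the attribute
#'   `total_placed` holds the summed length of placed chromosomes.
#' @export
assembly_metadata <- function(data) {
  data <- tibble::as_tibble(data)
  if (!all(c("chromosome", "length") %in% names(data))) {
    abort_synloss("`data` needs columns chromosome and length",
                  class = "synloss_format_error")
  }
  if (!("placed" %in% names(data))) data$placed <- TRUE
  if (any(is.na(data$length) | data$length <= 0)) {
    abort_synloss("chromosome lengths must be positive",
                  class = "synloss_record_error")
  }
  if (anyDuplicated(data$chromosome)) {
    abort_synloss("duplicate chromosome names", class = "synloss_record_error")
  }
  structure(data[c("chromosome", "length", "placed")],
            total_placed = sum(data$length[data$placed]),
            class = c("assembly_meta", class(tibble::tibble())))
}

#' @rdname assembly_metadata
#' @param path Path to a TSV with columns `chromosome`, `length` and
#'   optionally `placed`.
#' @export
read_assembly_metadata <- function(path) {
  dat <- readr::read_tsv(path, col_types = readr::cols(
    chromosome = readr::col_character(),
    length = readr::col_double(),
    .default = readr::col_logical()
  ), progress = FALSE)
  assembly_metadata(dat)
}

#' Derive assembly metadata from an ortholog table
#'
#' Chromosome length is approximated by the maximum gene end coordinate
#' observed on each chromosome; useful when no assembly report is
#' available and only relative sizes matter (e.g. size-proportional
#' expected distributions).
#'
#' @param tbl An `ortholog_tbl`.
#' @param species Species whose chromosomes to summarise.
#' @return An `assembly_meta` tibble.
#' @export
assembly_from_table <- function(tbl, species = ortholog_species(tbl)[1]) {
  check_species(tbl, species)
  d <- tibble::tibble(
    chromosome = tbl[[sp_col(species, "chr")]],
    end = tbl[[sp_col(species, "end")]],
    placed = tbl[[sp_col(species, "placed")]]
  )
  d <- dplyr::filter(d, !is.na(.data$chromosome))
  d <- dplyr::summarise(dplyr::group_by(d, .data$chromosome),
                        length = max(.data$end, na.rm = TRUE),
                        placed = any(.data$placed), .groups = "drop")
  assembly_metadata(d)
}

#' Read an alignment-hit table from TSV
#'
#' Pre-computed BLAT/BLAST-style hits of query genes against a target
#' genome. Required columns: `query_gene_id`, `target_species`,
#' `target_chr`, `target_start`, `target_end`, `score`, `pct_identity`.
#' Optional columns used by hit classification: `reciprocal_best` (gene id
#' in the query genome that the hit aligns back to best, `NA` when
#' unresolved), `target_placed`, `synteny_ok`.
#'
#' @param path Path to a TSV file.
#' @return A tibble of hits, validated (score >= 0, start <= end,
#'   identity within 0..100).
#' @export
read_alignment_hits <- function(path) {
  dat <- readr::read_tsv(path, col_types = readr::cols(
    query_gene_id = readr::col_character(),
    target_species = readr::col_character(),
    target_chr = readr::col_character(),
    target_start = readr::col_double(),
    target_end = readr::col_double(),
    score = readr::col_double(),
    pct_identity = readr::col_double(),
    .default = readr::col_guess()
  ), progress = FALSE)
  validate_hits(dat)
}

validate_hits <- function(dat) {
  dat <- tibble::as_tibble(dat)
  need <- c("query_gene_id", "score")
  miss <- setdiff(need, names(dat))
  if (length(miss) > 0) {
    abort_synloss(paste0("hit table lacks column(s): ", paste(miss, collapse = ", ")),
                  class = "synloss_format_error")
  }
  if (any(dat$score < 0, na.rm = TRUE)) {
    abort_synloss("hit scores must be >= 0", class = "synloss_record_error")
  }
  if (all(c("target_start", "target_end") %in% names(dat)) &&
      any(dat$target_end < dat$target_start, na.rm = TRUE)) {
    abort_synloss("hit target_end < target_start", class = "synloss_record_error")
  }
  if ("pct_identity" %in% names(dat) &&
      any(dat$pct_identity < 0 | dat$pct_identity > 100, na.rm = TRUE)) {
    abort_synloss("pct_identity must lie in [0, 100]", class = "synloss_record_error")
  }
  if (!("reciprocal_best" %in% names(dat))) dat$reciprocal_best <- NA_character_
  if (!("target_placed" %in% names(dat))) dat$target_placed <- TRUE
  if (!("synteny_ok" %in% names(dat))) dat$synteny_ok <- NA
  dat
}
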