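#' Multi-species ortholog table
#'
#' The pipeline's central object: one row per gene of the defining
#' (first-listed) species, with chromosomal coordinates for every species
#' carried side by side, BioMart-style. For each species `s` the tibble
#' holds columns `s_id`, `s_chr`, `s_start`, `s_end`, `s_strand`,
#' `s_placed` and `s_class` (orthology class relative to the defining
#' species: one of `one2one`, `apparent_one2one`, `one2many`, `many2many`,
#' `none`). Coordinates are 1-based inclusive, Ensembl-style; spans are
#' computed as end minus start throughout. An optional `cds_length`
#' column holds the defining species' coding-sequence length in bp.
#'
#' @param data A data frame with a `gene_id` column (the defining species'
#'   gene id, unique) and the per-species columns described above.
#' @param species Character vector of species names, the defining species
#'   first; at least two.
#' @return A tibble of class `ortholog_tbl` with a `species` attribute.
#' @examples
#' tbl <- ortholog_table(
#'   tibble::tibble(
#'     gene_id = c("g1", "g2"),
#'     lizard_id = c("g1", "g2"), lizard_chr = "1",
#'     lizard_start = c(1, 30001), lizard_end = c(20000, 52000),
#'     lizard_strand = "+", lizard_placed = TRUE, lizard_class = "one2one",
#'     chicken_id = c("c1", NA), chicken_chr = c("1", NA),
#'     chicken_start = c(1, NA), chicken_end = c(9000, NA),
#'     chicken_strand = c("+", NA), chicken_placed = c(TRUE, NA),
#'     chicken_class = c("one2one", "none")
#'   ),
#'   species = c("lizard", "chicken")
#' )
#' @export
ortholog_table <- function(data, species) {
  if (length(species) < 2) abort_synloss("need at least two species")
  data <- tibble::as_tibble(data)
  required <- c("gene_id", unlist(lapply(species, function(s) {
    sp_col(s, c("id", "chr", "start", "end", "strand", "placed", "class"))
  })))
  miss <- setdiff(required, names(data))
  if (length(miss) > 0) {
    abort_synloss(
      paste0("missing required column(s): ", paste(miss, collapse = ", ")),
      class = "synloss_format_error"
    )
  }
  for (s in species) {
    id <- data[[sp_col(s, "id")]]
    # absent ortholog: id NA <=> class "none"
    cls <- data[[sp_col(s, "class")]]
    cls[is.na(id)] <- "none"
    bad_cls <- setdiff(unique(cls), ORTHOLOGY_CLASSES)
    if (length(bad_cls) > 0) {
      abort_synloss(
        paste0("unknown orthology class(es) for ", s, ": ",
               paste(bad_cls, collapse = ", ")),
        class = "synloss_format_error"
      )
    }
    data[[sp_col(s, "class")]] <- cls
    dup <- unique(id[!is.na(id)][duplicated(id[!is.na(id)])])
    if (length(dup) > 0) {
      abort_synloss(
        paste0("duplicate ", s, " gene id(s): ",
               paste(utils::head(dup, 5), collapse = ", ")),
        class = "synloss_record_error"
      )
    }
    st <- data[[sp_col(s, "start")]]
    en <- data[[sp_col(s, "end")]]
    bad <- which(!is.na(st) & !is.na(en) & (en < st | st < 1))
    if (length(bad) > 0) {
      abort_synloss(
        paste0("invalid coordinates (end < start or start < 1) for gene(s): ",
               paste(utils::head(data$gene_id[bad], 5), collapse = ", ")),
        class = "synloss_record_error"
      )
    }
    pl <- data[[sp_col(s, "placed")]]
    pl[is.na(pl) & !is.na(id)] <- TRUE
    data[[sp_col(s, "placed")]] <- as.logical(pl)
  }
  if (anyDuplicated(data$gene_id)) {
    abort_synloss("`gene_id` must be unique", class = "synloss_record_error")
  }
  if ("cds_length" %in% names(data)) {
    bad <- which(!is.na(data$cds_length) & data$cds_length < 0)
    if (length(bad) > 0) {
      abort_synloss(paste0("negative cds_length for gene(s): ",
                           paste(utils::head(data$gene_id[bad], 5), collapse = ", ")),
                    class = "synloss_record_error")
    }
  }
  new_ortholog_table(data, species)
}

new_ortholog_table <- function(data, species) {
  structure(tibble::as_tibble(data),
            species = species,
            class = c("ortholog_tbl", class(tibble::tibble())))
}

#' @export
print.ortholog_tbl <- function(x, ...) {
  cat(sprintf("<ortholog_tbl: %d genes; species: %s>\n",
              nrow(x), paste(attr(x, "species"), collapse = ", ")))
  NextMethod()
}

#' Species stored in an ortholog table
#' @param tbl An `ortholog_tbl`.
#' @return Character vector of species names, defining species first.
#' @export
ortholog_species <- function(tbl) attr(tbl, "species")

#' Sort an ortholog table by one species' genome coordinates
#'
#' Orders rows by the canonical chromosome ordering of `species` (see
#' [chromosome_levels()]) then by start position, with `gene_id` as the
#' final tie-break so the sort is total and idempotent. Rows with no
#' coordinates in `species` sort last.
#'
#' @param tbl An `ortholog_tbl`.
#' @param species Species whose coordinates define the ordering; defaults
#'   to the defining (first) species.
#' @return The sorted `ortholog_tbl`.
#' @export
sort_ortholog_table <- function(tbl, species = ortholog_species(tbl)[1]) {
  check_species(tbl, species)
  chr <- tbl[[sp_col(species, "chr")]]
  lev <- chromosome_levels(chr, tbl[[sp_col(species, "placed")]])
  o <- order(match(chr, lev), tbl[[sp_col(species, "start")]], tbl$gene_id,
             na.last = TRUE, method = "radix")
  new_ortholog_table(tbl[o, , drop = FALSE], ortholog_species(tbl))
}

is_sorted_by <- function(tbl, species) {
  identical(tbl$gene_id, sort_ortholog_table(tbl, species)$gene_id)
}

check_species <- function(tbl, species) {
  absent <- setdiff(species, ortholog_species(tbl))
  if (length(absent) > 0) {
    abort_synloss(paste0("species not in table: ", paste(absent, collapse = ", ")))
  }
  invisible(TRUE)
}

ortholog_cols <- function(species) {
  c("gene_id", unlist(lapply(species, function(s) {
    sp_col(s, c("id", "chr", "start", "end", "strand", "placed", "class"))
  })))
}

#' Read an ortholog table from TSV
#'
#' Expects a tab-separated file with a header naming `gene_id` and, for
#' every species, the columns `<species>_id`, `<species>_chr`,
#' `<species>_start`, `<species>_end`, `<species>_strand`,
#' `<species>_placed`, `<species>_class` (an optional `cds_length` column
#' is kept). A header-only file yields an empty table with the species
#' list preserved.
#'
#' @param path Path to a TSV file.
#' @param species Character vector of species names, defining species first.
#' @return An `ortholog_tbl`.
#' @export
read_ortholog_table <- function(path, species) {
  dat <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- ortholog_cols(species)
  miss <- setdiff(need, names(dat))
  if (length(miss) > 0) {
    abort_synloss(paste0("file ", path, " lacks column(s): ",
                         paste(miss, collapse = ", ")),
                  class = "synloss_format_error")
  }
  for (s in species) {
    for (f in c("start", "end")) {
      dat[[sp_col(s, f)]] <- as.numeric(dat[[sp_col(s, f)]])
    }
    dat[[sp_col(s, "placed")]] <- as.logical(dat[[sp_col(s, "placed")]])
  }
  if ("cds_length" %in% names(dat)) dat$cds_length <- as.numeric(dat$cds_length)
  ortholog_table(dat, species)
}

#' Write an ortholog table to TSV
#'
#' Inverse of [read_ortholog_table()]: `read_ortholog_table(write_ortholog_table(x, f), species)`
#' reproduces `x`.
#'
#' @param tbl An `ortholog_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_table <- function(tbl, path) {
  readr::write_tsv(tibble::as_tibble(tbl), path, progress = FALSE)
  invisible(path)
}
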