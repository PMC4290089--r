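# Syntenic deletion-block detection and cross-species verification.

# species-specific coordinate view of an ortholog table, keyed by gene_id
species_view <- function(tbl, species) {
  tibble::tibble(
    gene_id = tbl$gene_id,
    id = tbl[[sp_col(species, "id")]],
    chr = tbl[[sp_col(species, "chr")]],
    start = tbl[[sp_col(species, "start")]],
    end = tbl[[sp_col(species, "end")]],
    strand = tbl[[sp_col(species, "strand")]],
    placed = tbl[[sp_col(species, "placed")]]
  )
}

# tier under the block criteria; NA when the run does not qualify
block_tier <- function(n, span, th) {
  if (n >= th$min_block_genes) return("multi_gene")
  if (span >= th$min_block_span) return("large_singlet_or_doublet")
  if (n == 2 && span >= th$doublet_min_span) return("small_doublet")
  NA_character_
}

new_block_set <- function(blocks, species, near_block, thresholds) {
  blocks <- tibble::as_tibble(blocks)
  structure(blocks,
            species = species,
            near_block = near_block,
            thresholds = thresholds,
            class = c("block_set", class(tibble::tibble())))
}

#' @export
print.block_set <- function(x, ...) {
  cat(sprintf("<block_set: %d blocks in %s ordering; %d near-block gene(s)>\n",
              nrow(x), attr(x, "species"), nrow(attr(x, "near_block"))))
  NextMethod()
}

#' Near-block genes of a block set
#'
#' Missing genes that did not meet the block criteria but lie within
#' `near_block_gap` present genes of a qualifying block, plus genes
#' demoted by cross-species re-filtering.
#'
#' @param blocks A `block_set`.
#' @return Tibble with columns `gene_id`, `chromosome`, `reason`.
#' @export
near_block_genes <- function(blocks) attr(blocks, "near_block")

#' Detect syntenic blocks of missing genes
#'
#' Scans one species' gene ordering for maximal runs of consecutive
#' missing-flagged genes (runs never cross chromosome boundaries; any
#' intervening gene present in the focal lineage breaks a run) and keeps
#' runs meeting the block criteria: at least `min_block_genes` adjacent
#' genes (unconditionally), or a singlet/doublet spanning at least
#' `min_block_span` bp, or a doublet spanning at least
#' `doublet_min_span` bp (the lowest-confidence tier). Span is the end of
#' the last gene minus the start of the first. Non-qualifying runs within
#' `near_block_gap` present genes of a qualifying block are reported as
#' near-block genes; other non-qualifying runs are dropped from the block
#' output.
#'
#' @param tbl An `ortholog_tbl` with a logical `missing` column (see
#'   [flag_missing()]), sorted by `species` (see
#'   [sort_ortholog_table()]); unsorted input is an error.
#' @param species Species whose ordering defines adjacency; defaults to
#'   the defining species.
#' @param thresholds A [loss_thresholds()] object or list.
#' @return A `block_set`: a tibble with one row per block (`block_id`,
#'   `chromosome`, `n_genes`, `start`, `end`, `span`, `tier`, `members`
#'   list column, `flank_up`, `flank_down`, `verified_in_both`) plus a
#'   `near_block` attribute, see [near_block_genes()].
#' @export
detect_missing_blocks <- function(tbl, species = ortholog_species(tbl)[1],
                                  thresholds = loss_thresholds()) {
  thresholds <- as_thresholds(thresholds)
  if (!("missing" %in% names(tbl))) {
    abort_synloss("`tbl` needs a logical `missing` column; see flag_missing()")
  }
  check_species(tbl, species)
  if (!is_sorted_by(tbl, species)) {
    abort_synloss(paste0("`tbl` must be sorted by ", species,
                         "; see sort_ortholog_table()"))
  }
  v <- species_view(tbl, species)
  v$missing <- tbl$missing
  v <- v[!is.na(v$chr), , drop = FALSE]

  blocks <- list()
  near <- list()
  for (ch in unique(v$chr)) {
    d <- v[v$chr == ch, , drop = FALSE]
    rid <- run_ids(d$missing)
    if (all(is.na(rid))) next
    runs <- lapply(split(seq_len(nrow(d)), rid), function(idx) {
      span <- max(d$end[idx]) - min(d$start[idx])
      list(idx = idx, n = length(idx), span = span,
           tier = block_tier(length(idx), span, thresholds))
    })
    ok <- vapply(runs, function(r) !is.na(r$tier), logical(1))
    for (r in runs[ok]) {
      i0 <- min(r$idx); i1 <- max(r$idx)
      blocks[[length(blocks) + 1L]] <- tibble::tibble(
        chromosome = ch, n_genes = r$n,
        start = min(d$start[r$idx]), end = max(d$end[r$idx]), span = r$span,
        tier = r$tier, members = list(d$gene_id[r$idx]),
        flank_up = if (i0 > 1) d$gene_id[i0 - 1L] else NA_character_,
        flank_down = if (i1 < nrow(d)) d$gene_id[i1 + 1L] else NA_character_,
        verified_in_both = NA
      )
    }
    # near-block: non-qualifying runs close to a qualifying block
    if (any(ok) && any(!ok)) {
      qual_idx <- lapply(runs[ok], `[[`, "idx")
      for (r in runs[!ok]) {
        gaps <- vapply(qual_idx, function(q) {
          if (min(q) > max(r$idx)) min(q) - max(r$idx) - 1L
          else if (min(r$idx) > max(q)) min(r$idx) - max(q) - 1L
          else 0L
        }, integer(1))
        if (min(gaps) <= thresholds$near_block_gap) {
          near[[length(near) + 1L]] <- tibble::tibble(
            gene_id = d$gene_id[r$idx], chromosome = ch, reason = "near_block")
        }
      }
    }
  }
  empty_blocks <- tibble::tibble(
    block_id = integer(), chromosome = character(), n_genes = integer(),
    start = double(), end = double(), span = double(), tier = character(),
    members = list(), flank_up = character(), flank_down = character(),
    verified_in_both = logical()
  )
  blk <- if (length(blocks) > 0) dplyr::bind_rows(blocks) else empty_blocks
  if (nrow(blk) > 0) blk <- dplyr::mutate(blk, block_id = dplyr::row_number(),
                                          .before = 1)
  nb <- if (length(near) > 0) dplyr::bind_rows(near) else
    tibble::tibble(gene_id = character(), chromosome = character(),
                   reason = character())
  new_block_set(if (nrow(blk) > 0) blk else empty_blocks,
                species, nb, thresholds)
}

#' Re-verify blocks after re-ordering by a second reference species
#'
#' Mirrors the realignment step of the screen: the whole gene list is
#' re-ordered by the second reference species and every block is
#' re-tested against the inclusion criteria. A block whose members stay
#' contiguous (no intervening present gene) on one chromosome of the
#' second species is kept with `verified_in_both = TRUE`. A block whose
#' members are split or interleaved is partitioned into maximal
#' second-species runs; each part is re-tested (gene count plus span in
#' both species) and parts that fail are demoted to the near-block list.
#' Blocks with any member on an unplaced second-species scaffold cannot
#' be verified and are retained with `verified_in_both = FALSE`.
#' The operation is idempotent.
#'
#' @param blocks A `block_set` from [detect_missing_blocks()].
#' @param tbl The `ortholog_tbl` (with its `missing` column) the blocks
#'   were detected on.
#' @param species_b The second reference species.
#' @param thresholds A [loss_thresholds()] object or list; defaults to
#'   the thresholds stored in `blocks`.
#' @return A `block_set` in the original species' ordering with
#'   `verified_in_both` filled in and block ids renumbered along the
#'   genome.
#' @export
refilter_blocks <- function(blocks, tbl, species_b,
                            thresholds = attr(blocks, "thresholds")) {
  thresholds <- as_thresholds(thresholds)
  species_a <- attr(blocks, "species")
  check_species(tbl, c(species_a, species_b))
  if (!("missing" %in% names(tbl))) {
    abort_synloss("`tbl` needs a logical `missing` column")
  }
  tblb <- sort_ortholog_table(tbl, species_b)
  vb <- species_view(tblb, species_b)
  vb$missing <- tblb$missing
  # run ids among missing genes in the B ordering, per B chromosome
  vb$run <- NA_integer_
  off <- 0L
  for (ch in unique(vb$chr[!is.na(vb$chr)])) {
    sel <- which(!is.na(vb$chr) & vb$chr == ch)
    r <- run_ids(vb$missing[sel])
    vb$run[sel] <- r + off
    off <- off + max(c(r, 0L), na.rm = TRUE)
  }
  va <- species_view(tbl, species_a)
  lookup_b <- vb[match(va$gene_id, vb$gene_id), ]

  kept <- list()
  demoted <- list()
  for (i in seq_len(nrow(blocks))) {
    members <- blocks$members[[i]]
    mb <- vb[match(members, vb$gene_id), , drop = FALSE]
    if (any(is.na(mb$chr)) || any(!mb$placed)) {
      row <- blocks[i, , drop = FALSE]
      row$verified_in_both <- FALSE
      kept[[length(kept) + 1L]] <- row
      next
    }
    parts <- split(members, mb$run)
    intact <- length(parts) == 1L
    for (part in parts) {
      ma <- va[match(part, va$gene_id), , drop = FALSE]
      mpb <- vb[match(part, vb$gene_id), , drop = FALSE]
      span_a <- max(ma$end) - min(ma$start)
      span_b <- max(mpb$end) - min(mpb$start)
      tier_a <- block_tier(length(part), span_a, thresholds)
      tier_b <- block_tier(length(part), span_b, thresholds)
      if (!is.na(tier_a) && !is.na(tier_b)) {
        kept[[length(kept) + 1L]] <- tibble::tibble(
          block_id = NA_integer_, chromosome = ma$chr[1],
          n_genes = length(part),
          start = min(ma$start), end = max(ma$end), span = span_a,
          tier = tier_a, members = list(part[order(ma$start)]),
          flank_up = NA_character_, flank_down = NA_character_,
          verified_in_both = intact
        )
      } else {
        demoted[[length(demoted) + 1L]] <- tibble::tibble(
          gene_id = part, chromosome = ma$chr[1], reason = "refiltered_out")
      }
    }
  }
  out <- if (length(kept) > 0) dplyr::bind_rows(kept) else blocks[0, ]
  # renumber along the genome and recompute flanks in the A ordering
  lev <- chromosome_levels(va$chr, va$placed)
  out <- out[order(match(out$chromosome, lev), out$start), , drop = FALSE]
  if (nrow(out) > 0) {
    out$block_id <- seq_len(nrow(out))
    present <- !tbl$missing & !is.na(va$chr)
    for (i in seq_len(nrow(out))) {
      idx <- match(out$members[[i]], va$gene_id)
      same_chr <- which(va$chr == out$chromosome[i])
      before <- same_chr[same_chr < min(idx) & present[same_chr]]
      after <- same_chr[same_chr > max(idx) & present[same_chr]]
      out$flank_up[i] <- if (length(before) > 0) va$gene_id[max(before)] else NA
      out$flank_down[i] <- if (length(after) > 0) va$gene_id[min(after)] else NA
    }
  }
  nb <- dplyr::bind_rows(attr(blocks, "near_block"),
                         if (length(demoted) > 0) dplyr::bind_rows(demoted))
  nb <- dplyr::distinct(nb)
  new_block_set(out, species_a, nb, thresholds)
}

#' Block spans in a given species
#'
#' Recomputes each block's span (maximum member end minus minimum member
#' start) from that species' coordinates, and the cumulative span.
#' Following the screen's convention, the cumulative sum includes only
#' blocks of at least `min_block_genes` genes unless `include_all` is
#' set. Blocks with a member lacking coordinates in `species`, or with
#' members scattered over several chromosomes there, are skipped with a
#' warning.
#'
#' @param blocks A `block_set`.
#' @param tbl The `ortholog_tbl` the blocks were detected on.
#' @param species Species in whose coordinates to measure.
#' @param include_all Include singlet/doublet tiers in the cumulative sum
#'   (default `FALSE`).
#' @param thresholds A [loss_thresholds()] object or list.
#' @return A list with `per_block` (tibble: `block_id`, `chromosome`,
#'   `start`, `end`, `span`, `n_genes`, `in_cumulative`) and `cumulative`
#'   (total bp).
#' @export
block_spans <- function(blocks, tbl, species,
                        include_all = FALSE,
                        thresholds = attr(blocks, "thresholds")) {
  thresholds <- as_thresholds(thresholds)
  check_species(tbl, species)
  v <- species_view(tbl, species)
  rows <- lapply(seq_len(nrow(blocks)), function(i) {
    m <- v[match(blocks$members[[i]], v$gene_id), , drop = FALSE]
    if (any(is.na(m$start)) || any(is.na(m$chr)) ||
        length(unique(m$chr)) != 1L) {
      warning(sprintf("block %d skipped: incomplete %s anchors",
                      blocks$block_id[i], species), call. = FALSE)
      return(NULL)
    }
    tibble::tibble(block_id = blocks$block_id[i], chromosome = m$chr[1],
                   start = min(m$start), end = max(m$end),
                   span = max(m$end) - min(m$start),
                   n_genes = blocks$n_genes[i])
  })
  per_block <- dplyr::bind_rows(rows)
  if (nrow(per_block) == 0) {
    per_block <- tibble::tibble(block_id = integer(), chromosome = character(),
                                start = double(), end = double(),
                                span = double(), n_genes = integer())
  }
  per_block$in_cumulative <- include_all |
    per_block$n_genes >= thresholds$min_block_genes
  list(per_block = per_block,
       cumulative = sum(per_block$span[per_block$in_cumulative]))
}

#' Classify rearrangement of a block's flanking genes in a focal genome
#'
#' For each block, locates the two reference genes immediately flanking
#' the deleted run and compares their relative arrangement in the focal
#' genome with the reference arrangement. Calls, in order of precedence:
#' `unresolved` (a flank is absent or unplaced in the focal genome),
#' `different_chromosome`, `same_chr_reversed` (both flanks strand-flipped
#' relative to the reference, an inversion signature),
#' `same_chr_reordered` (upstream/downstream order swapped without the
#' strand flip), `same_chr_distant` (separation greater than
#' `distant_flank_bp`), else `colinear`.
#'
#' @param blocks A `block_set`.
#' @param tbl The `ortholog_tbl` the blocks were detected on.
#' @param focal Focal species name.
#' @param thresholds A [loss_thresholds()] object or list.
#' @return Tibble with one row per block: `block_id`, `focal_species`,
#'   `call`, `distance_bp` (gap between the flank loci when on the same
#'   focal chromosome, else `NA`).
#' @export
classify_flanking_rearrangements <- function(blocks, tbl, focal,
                                             thresholds = attr(blocks, "thresholds")) {
  thresholds <- as_thresholds(thresholds)
  species_a <- attr(blocks, "species")
  check_species(tbl, c(species_a, focal))
  va <- species_view(tbl, species_a)
  vf <- species_view(tbl, focal)
  out <- lapply(seq_len(nrow(blocks)), function(i) {
    up <- blocks$flank_up[i]; dn <- blocks$flank_down[i]
    res <- function(call, dist = NA_real_) {
      tibble::tibble(block_id = blocks$block_id[i], focal_species = focal,
                     call = call, distance_bp = dist)
    }
    if (is.na(up) || is.na(dn)) return(res("unresolved"))
    fu <- vf[match(up, vf$gene_id), ]; fd <- vf[match(dn, vf$gene_id), ]
    if (is.na(fu$chr) || is.na(fd$chr) || !fu$placed || !fd$placed) {
      return(res("unresolved"))
    }
    if (fu$chr != fd$chr) return(res("different_chromosome"))
    gap <- max(0, max(fu$start, fd$start) - min(fu$end, fd$end))
    au <- va[match(up, va$gene_id), ]; ad <- va[match(dn, va$gene_id), ]
    flipped <- !is.na(fu$strand) && !is.na(fd$strand) &&
      !is.na(au$strand) && !is.na(ad$strand) &&
      fu$strand != au$strand && fd$strand != ad$strand
    swapped <- fu$start > fd$start
    if (flipped && swapped) return(res("same_chr_reversed", gap))
    if (swapped) return(res("same_chr_reordered", gap))
    if (flipped) return(res("same_chr_reversed", gap))
    if (gap > thresholds$distant_flank_bp) return(res("same_chr_distant", gap))
    res("colinear", gap)
  })
  dplyr::bind_rows(out)
}

#' Export blocks as BED
#'
#' Writes one BED line per block in the given species' coordinates. BED
#' uses 0-based half-open intervals, so exported starts are the 1-based
#' inclusive block starts minus one; this conversion happens on export
#' only.
#'
#' @param blocks A `block_set`.
#' @param tbl The `ortholog_tbl` the blocks were detected on.
#' @param species Species whose coordinates to export.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_blocks_bed <- function(blocks, tbl, species, path) {
  sp <- suppressWarnings(block_spans(blocks, tbl, species, include_all = TRUE))
  bed <- tibble::tibble(
    chrom = sp$per_block$chromosome,
    chromStart = as.integer(sp$per_block$start - 1),
    chromEnd = as.integer(sp$per_block$end),
    name = sprintf("block_%d", sp$per_block$block_id),
    score = sp$per_block$n_genes,
    strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Export a block report as JSON
#'
#' @param blocks A `block_set`.
#' @param path Output path.
#' @param rearrangements Optional tibble from
#'   [classify_flanking_rearrangements()].
#' @return `path`, invisibly.
#' @export
export_blocks_json <- function(blocks, path, rearrangements = NULL) {
  payload <- list(
    species = attr(blocks, "species"),
    thresholds = unclass(attr(blocks, "thresholds")),
    blocks = tibble::as_tibble(blocks),
    near_block = near_block_genes(blocks)
  )
  if (!is.null(rearrangements)) payload$rearrangements <- rearrangements
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
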