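# Seeded simulators: multi-species ortholog tables with planted syntenic
# deletions and rearrangements, and annotation tables with planted term
# enrichments. Every generator is deterministic given its seed.

#' Specification of a simulated multi-species genome
#'
#' Describes the genome the ortholog-table simulator emits: two reference
#' species sharing gene order, and a focal species that has lost the
#' planted deletion blocks (plus optional random singleton dropouts) and
#' may carry chromosomal rearrangements and unplaced contigs. Gene and
#' intergenic lengths are log-normal; reference genes default to a median
#' of 20 kb and focal genes to a compact-genome 10 kb median.
#'
#' @param n_chromosomes Number of chromosomes (default 6).
#' @param genes_per_chromosome Genes on each chromosome (default 80).
#' @param species Names of the two reference species then the focal
#'   species (default `c("lizard", "human", "chicken")`).
#' @param gene_length_meanlog,gene_length_sdlog Log-normal parameters for
#'   reference gene lengths (default median 20,000 bp, sdlog 0.6).
#' @param focal_gene_length_meanlog Log-normal meanlog for focal gene
#'   lengths (default median 10,000 bp).
#' @param intergenic_meanlog,intergenic_sdlog Log-normal parameters for
#'   intergenic gaps (default median 10,000 bp, sdlog 0.8).
#' @param planted_blocks Tibble with columns `n_genes` and optionally
#'   `chromosome`; one row per deletion block to plant (default five
#'   blocks of 3-6 genes). Blocks are placed without overlap and
#'   separated by at least one retained gene.
#' @param dropout_rate Probability that a gene outside any planted block
#'   is independently lost in the focal species (default 0).
#' @param translocation_rate,inversion_rate,transposition_rate Per-
#'   chromosome probability of one focal-lineage event of each type
#'   (defaults 0).
#' @param unplaced_fraction Probability a focal gene is relocated to its
#'   own unplaced scaffold (default 0).
#' @param seed Integer seed.
#' @return Object of class `genome_sim_spec`.
#' @export
genome_sim_spec <- function(n_chromosomes = 6L,
                            genes_per_chromosome = 80L,
                            species = c("lizard", "human", "chicken"),
                            gene_length_meanlog = log(20000),
                            gene_length_sdlog = 0.6,
                            focal_gene_length_meanlog = log(10000),
                            intergenic_meanlog = log(10000),
                            intergenic_sdlog = 0.8,
                            planted_blocks = default_planted_blocks(),
                            dropout_rate = 0,
                            translocation_rate = 0,
                            inversion_rate = 0,
                            transposition_rate = 0,
                            unplaced_fraction = 0,
                            seed = 1L) {
  if (length(species) != 3) abort_synloss("`species` must name 3 species")
  rates <- c(dropout_rate, translocation_rate, inversion_rate,
             transposition_rate, unplaced_fraction)
  if (any(rates < 0 | rates > 1)) abort_synloss("rates must lie in [0, 1]")
  planted_blocks <- tibble::as_tibble(planted_blocks)
  if (nrow(planted_blocks) > 0 && !("n_genes" %in% names(planted_blocks))) {
    abort_synloss("`planted_blocks` needs an n_genes column")
  }
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    species = species,
    gene_length_meanlog = gene_length_meanlog,
    gene_length_sdlog = gene_length_sdlog,
    focal_gene_length_meanlog = focal_gene_length_meanlog,
    intergenic_meanlog = intergenic_meanlog,
    intergenic_sdlog = intergenic_sdlog,
    planted_blocks = planted_blocks,
    dropout_rate = dropout_rate,
    translocation_rate = translocation_rate,
    inversion_rate = inversion_rate,
    transposition_rate = transposition_rate,
    unplaced_fraction = unplaced_fraction,
    seed = as.integer(seed)
  ), class = "genome_sim_spec")
}

#' @rdname genome_sim_spec
#' @export
default_planted_blocks <- function() {
  tibble::tibble(n_genes = c(3L, 4L, 5L, 3L, 6L))
}

# lay genes of given lengths along a chromosome with sampled gaps
lay_coordinates <- function(lengths, gaps) {
  start <- cumsum(c(1, lengths[-length(lengths)] + gaps)) |> round()
  tibble::tibble(start = start, end = round(start + lengths - 1))
}

#' Simulate a multi-species ortholog table with planted deletions
#'
#' Generates an `ortholog_tbl` for two reference species sharing gene
#' order plus a focal species from which the planted blocks (and random
#' dropout singletons) are deleted. Rearrangements (inversion,
#' transposition, translocation) are applied to the focal lineage after
#' deletion, so flanking-rearrangement classification has planted truth.
#' Identical seeds yield identical tables.
#'
#' @param spec A [genome_sim_spec()].
#' @return List with `table` (an `ortholog_tbl`, sorted by the defining
#'   reference species) and `truth` (list: `planted_blocks` tibble with
#'   member ids, `dropout_genes`, `events` tibble of rearrangements).
#' @export
simulate_ortholog_tables <- function(spec) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  withr::with_seed(spec$seed, simulate_ortholog_tables_impl(spec))
}

simulate_ortholog_tables_impl <- function(spec) {
  n_chr <- spec$n_chromosomes
  gpc <- spec$genes_per_chromosome
  n <- n_chr * gpc
  sp <- spec$species
  ref1 <- sp[1]; ref2 <- sp[2]; focal <- sp[3]

  genes <- tibble::tibble(
    gene_id = sprintf("g%05d", seq_len(n)),
    chromosome = as.character(rep(seq_len(n_chr), each = gpc)),
    pos = rep(seq_len(gpc), n_chr)
  )

  # plant deletion blocks: non-overlapping, non-adjacent runs
  pb <- spec$planted_blocks
  planted <- vector("list", nrow(pb))
  taken <- rep(FALSE, n)  # includes 1-gene buffer around each block
  if (nrow(pb) > 0) {
    if (!("chromosome" %in% names(pb))) {
      pb$chromosome <- as.character(rep_len(seq_len(n_chr), nrow(pb)))
    }
    for (i in seq_len(nrow(pb))) {
      k <- pb$n_genes[i]
      on_chr <- which(genes$chromosome == pb$chromosome[i])
      # keep away from chromosome edges so flanks exist
      cand <- on_chr[seq(2, length(on_chr) - k)]
      cand <- cand[vapply(cand, function(s) {
        !any(taken[(s - 1):(s + k)])
      }, logical(1))]
      if (length(cand) == 0) {
        abort_synloss(sprintf("cannot place planted block %d without overlap", i))
      }
      s <- cand[sample.int(length(cand), 1L)]
      planted[[i]] <- genes$gene_id[s:(s + k - 1L)]
      taken[(s - 1L):(s + k)] <- TRUE
    }
  }
  planted_ids <- unlist(planted)

  # random singleton dropouts outside planted blocks and their buffers
  droppable <- which(!taken)
  dropout <- genes$gene_id[droppable[stats::runif(length(droppable)) <
                                       spec$dropout_rate]]
  absent <- genes$gene_id %in% c(planted_ids, dropout)

  strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_len <- list(
    ref1 = stats::rlnorm(n, spec$gene_length_meanlog, spec$gene_length_sdlog),
    ref2 = stats::rlnorm(n, spec$gene_length_meanlog, spec$gene_length_sdlog),
    focal = stats::rlnorm(n, spec$focal_gene_length_meanlog,
                          spec$gene_length_sdlog)
  )

  per_species_coords <- function(order_idx, chrom, lengths) {
    out <- tibble::tibble(idx = order_idx, chr = chrom,
                          start = NA_real_, end = NA_real_)
    for (ch in unique(chrom)) {
      sel <- which(chrom == ch)
      gaps <- stats::rlnorm(length(sel), spec$intergenic_meanlog,
                            spec$intergenic_sdlog)
      cc <- lay_coordinates(lengths[order_idx[sel]], gaps[-length(gaps)])
      out$start[sel] <- cc$start
      out$end[sel] <- cc$end
    }
    out
  }

  ref_order <- seq_len(n)
  c1 <- per_species_coords(ref_order, genes$chromosome, gene_len$ref1)
  c2 <- per_species_coords(ref_order, genes$chromosome, gene_len$ref2)

  # focal lineage: delete, then rearrange
  f_idx <- which(!absent)
  f_chr <- genes$chromosome[f_idx]
  f_strand <- strand[f_idx]
  events <- list()
  seg_bounds <- function(len) {
    if (len < 3) return(NULL)
    w <- min(len - 1L, sample(2:10, 1L))
    s <- sample.int(len - w + 1L, 1L)
    c(s, s + w - 1L)
  }
  for (ch in unique(f_chr)) {
    sel <- which(f_chr == ch)
    if (stats::runif(1) < spec$inversion_rate) {
      b <- seg_bounds(length(sel))
      if (!is.null(b)) {
        rng <- sel[b[1]:b[2]]
        f_idx[rng] <- rev(f_idx[rng])
        f_strand[rng] <- rev(ifelse(f_strand[rng] == "+", "-", "+"))
        events[[length(events) + 1L]] <- tibble::tibble(
          type = "inversion", chromosome = ch, n_genes = length(rng))
      }
    }
    if (stats::runif(1) < spec$transposition_rate) {
      b <- seg_bounds(length(sel))
      if (!is.null(b)) {
        rng <- b[1]:b[2]
        rest <- setdiff(seq_along(sel), rng)
        at <- sample.int(length(rest) + 1L, 1L) - 1L
        neworder <- append(rest, rng, after = at)
        f_idx[sel] <- f_idx[sel][neworder]
        f_strand[sel] <- f_strand[sel][neworder]
        events[[length(events) + 1L]] <- tibble::tibble(
          type = "transposition", chromosome = ch, n_genes = length(rng))
      }
    }
    if (stats::runif(1) < spec$translocation_rate && length(unique(f_chr)) > 1) {
      b <- seg_bounds(length(sel))
      if (!is.null(b)) {
        rng <- sel[b[1]:b[2]]
        dest <- sample(setdiff(unique(f_chr), ch), 1L)
        f_chr[rng] <- dest
        events[[length(events) + 1L]] <- tibble::tibble(
          type = "translocation", chromosome = ch, n_genes = length(rng),
          destination = dest)
      }
    }
  }
  # unplaced contigs: relocate individual focal genes to own scaffolds
  f_placed <- rep(TRUE, length(f_idx))
  if (spec$unplaced_fraction > 0) {
    un <- stats::runif(length(f_idx)) < spec$unplaced_fraction
    f_chr[un] <- paste0("scaf_", genes$gene_id[f_idx[un]])
    f_placed[un] <- FALSE
  }
  # focal coordinates follow the final per-chromosome order
  ord <- order(match(f_chr, unique(f_chr)))
  f_idx <- f_idx[ord]; f_chr <- f_chr[ord]
  f_strand <- f_strand[ord]; f_placed <- f_placed[ord]
  cf <- per_species_coords(f_idx, f_chr, gene_len$focal)

  dat <- tibble::tibble(gene_id = genes$gene_id)
  dat[[sp_col(ref1, "id")]] <- genes$gene_id
  dat[[sp_col(ref1, "chr")]] <- genes$chromosome
  dat[[sp_col(ref1, "start")]] <- c1$start
  dat[[sp_col(ref1, "end")]] <- c1$end
  dat[[sp_col(ref1, "strand")]] <- strand
  dat[[sp_col(ref1, "placed")]] <- TRUE
  dat[[sp_col(ref1, "class")]] <- "one2one"
  dat[[sp_col(ref2, "id")]] <- paste0(substr(ref2, 1, 1), "_", genes$gene_id)
  dat[[sp_col(ref2, "chr")]] <- genes$chromosome
  dat[[sp_col(ref2, "start")]] <- c2$start
  dat[[sp_col(ref2, "end")]] <- c2$end
  dat[[sp_col(ref2, "strand")]] <- strand
  dat[[sp_col(ref2, "placed")]] <- TRUE
  dat[[sp_col(ref2, "class")]] <- "one2one"

  fmap <- match(seq_len(n), f_idx)
  dat[[sp_col(focal, "id")]] <- ifelse(is.na(fmap), NA_character_,
                                       paste0(substr(focal, 1, 1), "_",
                                              genes$gene_id))
  dat[[sp_col(focal, "chr")]] <- f_chr[fmap]
  dat[[sp_col(focal, "start")]] <- cf$start[fmap]
  dat[[sp_col(focal, "end")]] <- cf$end[fmap]
  dat[[sp_col(focal, "strand")]] <- f_strand[fmap]
  dat[[sp_col(focal, "placed")]] <- f_placed[fmap]
  dat[[sp_col(focal, "class")]] <- ifelse(is.na(fmap), "none", "one2one")
  dat$cds_length <- round(pmin(gene_len$ref1, 60000) * 0.1)

  tbl <- sort_ortholog_table(ortholog_table(dat, sp), ref1)
  truth <- list(
    planted_blocks = tibble::tibble(
      block = seq_along(planted),
      chromosome = vapply(planted, function(g) {
        genes$chromosome[match(g[1], genes$gene_id)]
      }, character(1)),
      n_genes = lengths(planted),
      members = planted
    ),
    dropout_genes = dropout,
    events = if (length(events) > 0) dplyr::bind_rows(events) else
      tibble::tibble(type = character(), chromosome = character(),
                     n_genes = integer())
  )
  list(table = tbl, truth = truth)
}

#' Simulate a gene-to-term annotation table with planted enrichments
#'
#' Each gene carries each term independently with probability
#' `base_rate`, multiplied by the planted relative risk inside the
#' target gene set (capped at 1 with a warning).
#'
#' @param genes Character vector of gene ids (the universe).
#' @param terms Character vector of term ids.
#' @param planted Optional tibble with columns `term_id`,
#'   `relative_risk` and a `set` list column of target gene ids (one row
#'   per planted enrichment; risks must be >= 0).
#' @param base_rate Baseline carrier probability in (0, 1).
#' @param seed Integer seed.
#' @param source Vocabulary tag, see [annotation_table()].
#' @return List with `annotation` (an `annotation_tbl`) and `truth`
#'   (the planted tibble).
#' @export
simulate_annotations <- function(genes, terms, planted = NULL,
                                 base_rate = 0.1, seed = 1L,
                                 source = "phenotype") {
  if (base_rate <= 0 || base_rate >= 1) {
    abort_synloss("`base_rate` must lie in (0, 1)")
  }
  if (!is.null(planted)) {
    planted <- tibble::as_tibble(planted)
    if (any(planted$relative_risk < 0)) {
      abort_synloss("`relative_risk` must be >= 0")
    }
    if (!all(planted$term_id %in% terms)) {
      abort_synloss("planted terms must appear in `terms`")
    }
  }
  prob <- matrix(base_rate, nrow = length(genes), ncol = length(terms),
                 dimnames = list(genes, terms))
  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      p <- base_rate * planted$relative_risk[i]
      if (p > 1) {
        warning("planted carrier probability exceeds 1; capped", call. = FALSE)
        p <- 1
      }
      prob[match(planted$set[[i]], genes), planted$term_id[i]] <- p
    }
  }
  carrier <- withr::with_seed(seed, {
    matrix(stats::runif(length(prob)) < prob, nrow = nrow(prob),
           dimnames = dimnames(prob))
  })
  idx <- which(carrier, arr.ind = TRUE)
  entries <- tibble::tibble(gene_id = genes[idx[, 1]],
                            term_id = terms[idx[, 2]])
  catalog <- tibble::tibble(term_id = terms, label = terms)
  list(annotation = annotation_table(entries, catalog = catalog,
                                     source = source),
       truth = planted)
}
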