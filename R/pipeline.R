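# End-to-end orchestration: screen -> blocks -> stats -> enrichment.

#' Pipeline run configuration
#'
#' Validates and bundles everything a full run needs: the input ortholog
#' table (a path plus species list, an `ortholog_tbl`, or a
#' [genome_sim_spec()] to simulate one), the species roles, thresholds
#' and seeds. Missing input paths fail here, before any computation.
#'
#' @param input Path to an ortholog TSV, an `ortholog_tbl`, or a
#'   `genome_sim_spec`.
#' @param reference_pair The two reference species (for simulated input,
#'   defaults to the spec's first two species).
#' @param focal Character vector of focal species (>= 1).
#' @param annotation Optional `annotation_tbl` (or path to one) for the
#'   enrichment stage.
#' @param thresholds A [loss_thresholds()] object or list.
#' @param seed Integer seed governing every stochastic stage.
#' @param n_control_sets Number of matched control sets for the
#'   permutation stage (default: `thresholds$n_permutations`).
#' @param species Species names (defining species first) when `input` is
#'   a path.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input, reference_pair = NULL, focal = NULL,
                       annotation = NULL, thresholds = loss_thresholds(),
                       seed = 1L, n_control_sets = NULL, species = NULL) {
  thresholds <- as_thresholds(thresholds)
  if (inherits(input, "genome_sim_spec")) {
    reference_pair <- reference_pair %||% input$species[1:2]
    focal <- focal %||% input$species[3]
  } else if (is.character(input)) {
    if (!file.exists(input)) {
      abort_synloss(paste0("input path does not exist: ", input))
    }
    if (is.null(species)) abort_synloss("`species` required for path input")
  } else if (!inherits(input, "ortholog_tbl")) {
    abort_synloss("`input` must be a path, ortholog_tbl or genome_sim_spec")
  }
  if (length(reference_pair %||% character()) != 2) {
    abort_synloss("`reference_pair` must name two species")
  }
  if (length(focal %||% character()) < 1) {
    abort_synloss("at least one focal species is required")
  }
  if (is.character(annotation)) {
    if (!file.exists(annotation)) {
      abort_synloss(paste0("annotation path does not exist: ", annotation))
    }
  }
  structure(list(input = input, reference_pair = reference_pair,
                 focal = focal, annotation = annotation,
                 thresholds = thresholds, seed = as.integer(seed),
                 n_control_sets = n_control_sets, species = species),
            class = "run_config")
}

#' Run the full gene-loss pipeline
#'
#' Executes screen, block detection, cross-species re-filtering, span
#' and chromosomal-distribution statistics, flanking-rearrangement
#' classification and (when annotations are supplied) matched-control
#' permutation enrichment, and assembles a report. Re-running the same
#' configuration reproduces the report exactly.
#'
#' @param config A [run_config()].
#' @return Object of class `loss_report`: list with `counts` (screening
#'   ledger tibble), `candidates`, `blocks`, `spans` (per reference
#'   species), `chrom_dist` (per reference species), `rearrangements`,
#'   `enrichment` (or `NULL`), `truth` (for simulated input), `seeds`
#'   and `thresholds`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  th <- config$thresholds
  truth <- NULL
  if (inherits(config$input, "genome_sim_spec")) {
    sim <- simulate_ortholog_tables(config$input)
    tbl <- sim$table
    truth <- sim$truth
  } else if (is.character(config$input)) {
    tbl <- read_ortholog_table(config$input, config$species)
  } else {
    tbl <- config$input
  }
  ref1 <- config$reference_pair[1]
  ref2 <- config$reference_pair[2]
  tbl <- sort_ortholog_table(tbl, ref1)

  cand <- identify_candidates(tbl, config$reference_pair, config$focal)
  tbl <- flag_missing(tbl, cand)
  blocks <- detect_missing_blocks(tbl, ref1, th)
  blocks <- refilter_blocks(blocks, tbl, ref2, th)
  in_block <- unlist(blocks$members)
  near <- near_block_genes(blocks)

  spans <- list()
  chrom_dist <- list()
  for (s in config$reference_pair) {
    spans[[s]] <- suppressWarnings(block_spans(blocks, tbl, s,
                                               thresholds = th))
    obs <- chromosome_counts(tbl, s, genes = in_block)
    meta <- assembly_from_table(tbl, s)
    w <- meta$length[match(names(obs), meta$chromosome)]
    if ("Un" %in% names(obs)) {
      w[names(obs) == "Un"] <- sum(meta$length[!meta$placed])
    }
    keep <- !is.na(w) & w > 0
    chrom_dist[[s]] <- if (sum(keep) >= 2 && sum(obs[keep]) > 0) {
      suppressWarnings(chisq_uniformity(obs[keep], w[keep], mode = "by_size"))
    } else NULL
  }

  rearr <- classify_flanking_rearrangements(blocks, tbl, config$focal[1], th)

  enrichment <- NULL
  if (!is.null(config$annotation)) {
    ann <- config$annotation
    if (is.character(ann)) ann <- read_annotation_table(ann)
    missing_set <- unique(c(in_block, near$gene_id))
    if (length(missing_set) > 0 && nrow(blocks) > 0) {
      controls <- generate_control_sets(
        tbl, control_spec_from_blocks(blocks),
        n_sets = config$n_control_sets %||% th$n_permutations,
        seed = config$seed, species_pair = config$reference_pair,
        exclude = missing_set, thresholds = th)
      # controls match the in-block structure; pad with random singles for
      # near-block genes so control sets have the full missing-set size
      universe <- tbl$gene_id
      extra <- length(missing_set) - length(controls[[1]])
      if (extra > 0) {
        pool <- setdiff(universe, missing_set)
        controls <- withr::with_seed(config$seed + 1L, {
          lapply(controls, function(g) {
            c(g, sample(setdiff(pool, g), extra))
          })
        })
        class(controls) <- "control_sets"
      }
      enrichment <- permutation_test(missing_set, ann, universe,
                                     controls = controls,
                                     seed = config$seed)
    }
  }

  counts <- tibble::tibble(
    stage = c("reference_1to1", "with_focal_ortholog", "candidates",
              "in_block", "near_block", "confirmed_missing"),
    n = c(cand$counts$n_reference_1to1,
          cand$counts$n_with_focal_ortholog,
          cand$counts$n_candidates,
          length(in_block), nrow(near),
          length(in_block) + nrow(near))
  )
  structure(list(
    counts = counts, candidates = cand, blocks = blocks,
    spans = spans, chrom_dist = chrom_dist,
    rearrangements = rearr, enrichment = enrichment,
    truth = truth,
    seeds = list(pipeline = config$seed),
    thresholds = th
  ), class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat("<loss_report>\n")
  print(x$counts)
  cat(sprintf("  %d block(s)", nrow(x$blocks)))
  if (!is.null(x$enrichment)) {
    cat(sprintf("; permutation p = %.3g", x$enrichment$p_value))
  }
  cat("\n")
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' Serialises the counts ledger, blocks, spans, chromosomal-distribution
#' tests, rearrangement calls, enrichment summary, seeds and thresholds.
#'
#' @param report A `loss_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  blocks <- tibble::as_tibble(report$blocks)
  blocks$members <- vapply(blocks$members, paste, character(1), collapse = ",")
  payload <- list(
    counts = report$counts,
    blocks = blocks,
    near_block = near_block_genes(report$blocks),
    spans = lapply(report$spans, function(s) {
      list(per_block = s$per_block, cumulative = s$cumulative)
    }),
    chrom_dist = lapply(report$chrom_dist, function(cd) {
      if (is.null(cd)) return(NULL)
      list(statistic = cd$statistic, df = cd$df, p_value = cd$p_value,
           mode = cd$mode, table = cd$table)
    }),
    rearrangements = report$rearrangements,
    enrichment = if (!is.null(report$enrichment)) {
      list(observed = report$enrichment$observed,
           null_mean = report$enrichment$null_mean,
           n_permutations = report$enrichment$n_permutations,
           p_value = report$enrichment$p_value,
           terms = report$enrichment$terms)
    },
    seeds = report$seeds,
    thresholds = unclass(report$thresholds)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
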