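make_flagged <- function(layout, missing_ids, ...) {
  tbl <- make_tbl(layout, focal = drop_genes(layout, missing_ids), ...)
  flag_missing(tbl, missing_ids)
}

test_that("block criteria admit the stated run shapes", {
  th <- loss_thresholds()
  # no missing flags -> no blocks
  lay <- gene_layout(10)
  expect_equal(nrow(detect_missing_blocks(make_flagged(lay, character()))), 0L)
  # three adjacent genes spanning only ~10 kb: gene-count rule is unconditional
  small <- gene_layout(6, gene_len = 3000, gap = 500)
  b <- detect_missing_blocks(make_flagged(small, c("g002", "g003", "g004")))
  expect_equal(nrow(b), 1L)
  expect_equal(b$tier, "multi_gene")
  expect_lt(b$span, th$min_block_span)
  # large doublet (>= 80 kb) and small doublet (>= 34 kb) tiers
  big <- gene_layout(6, gene_len = 45000, gap = 2000)
  b2 <- detect_missing_blocks(make_flagged(big, c("g003", "g004")))
  expect_equal(b2$tier, "large_singlet_or_doublet")
  mid <- gene_layout(6, gene_len = 18000, gap = 1000)
  b3 <- detect_missing_blocks(make_flagged(mid, c("g003", "g004")))
  expect_equal(b3$tier, "small_doublet")
  # sub-threshold doublet yields nothing
  tiny <- gene_layout(6, gene_len = 12000, gap = 1000)
  expect_equal(nrow(detect_missing_blocks(make_flagged(tiny, c("g003", "g004")))),
               0L)
  # span is end-of-last minus start-of-first: a lone 94 kb gene qualifies
  one <- gene_layout(3, gene_len = c(5000, 94001, 5000), gap = 2000)
  b4 <- detect_missing_blocks(make_flagged(one, "g002"))
  expect_equal(b4$span, 94000)
  expect_equal(b4$tier, "large_singlet_or_doublet")
})

test_that("unsorted input is rejected", {
  lay <- gene_layout(5)
  tbl <- make_flagged(lay, "g002")
  shuffled <- new_tbl <- tbl[c(3, 1, 2, 4, 5), ]
  attr(shuffled, "species") <- attr(tbl, "species")
  class(shuffled) <- class(tbl)
  expect_error(detect_missing_blocks(shuffled), "sorted")
})

test_that("detection equals exhaustive maximal-run enumeration on random instances", {
  th <- loss_thresholds()
  withr::with_seed(42, {
    for (i in 1:200) {
      inst <- random_block_instance()
      tbl <- flag_missing(make_tbl(inst$layout,
                                   focal = inst$layout[!inst$missing, ]),
                          inst$layout$gene_id[inst$missing])
      got <- detect_missing_blocks(tbl, thresholds = th)
      v <- tibble::as_tibble(tbl)
      exp <- oracle_blocks(v$lizard_chr, v$lizard_start, v$lizard_end,
                           v$missing, th)
      got_key <- vapply(got$members, function(m) paste(sort(m), collapse = ","),
                        character(1))
      exp_key <- vapply(exp, function(e) {
        paste(sort(v$gene_id[e$members]), collapse = ",")
      }, character(1))
      expect_setequal(got_key, exp_key)
      expect_equal(nrow(got), length(exp))
      if (length(exp) > 0) {
        m <- match(got_key, exp_key)
        expect_equal(got$span, vapply(exp, `[[`, numeric(1), "span")[m])
        expect_equal(got$tier, vapply(exp, `[[`, character(1), "tier")[m])
      }
      # structural invariants: no gene in two blocks, no cross-chromosome block
      all_members <- unlist(got$members)
      expect_equal(anyDuplicated(all_members), 0L)
      for (k in seq_len(nrow(got))) {
        expect_equal(length(unique(v$lizard_chr[match(got$members[[k]],
                                                      v$gene_id)])), 1L)
      }
    }
  })
})

test_that("near-block genes are reported only next to qualifying blocks", {
  lay <- gene_layout(30, gene_len = 20000, gap = 5000)
  # qualifying triple at g005-g007; lone singleton at g010 (2 genes away);
  # remote singleton at g025 (far from any block)
  tbl <- make_flagged(lay, c("g005", "g006", "g007", "g010", "g025"))
  b <- detect_missing_blocks(tbl)
  expect_equal(nrow(b), 1L)
  nb <- near_block_genes(b)
  expect_identical(nb$gene_id, "g010")
})

test_that("cross-species refiltering verifies, splits or demotes blocks", {
  lay <- gene_layout(12, gene_len = 20000, gap = 5000)
  missing <- c("g004", "g005", "g006", "g007")
  # identical order in both species: verified intact
  tbl <- make_flagged(lay, missing)
  b <- detect_missing_blocks(tbl)
  rb <- refilter_blocks(b, tbl, "human")
  expect_equal(nrow(rb), 1L)
  expect_true(rb$verified_in_both)
  expect_identical(tibble::as_tibble(rb)[names(rb) != "verified_in_both"],
                   tibble::as_tibble(b)[names(b) != "verified_in_both"])
  # species B interleaves a present gene between the two halves, and each
  # 2-gene half spans < 34 kb in B: both halves demoted
  lay_b <- gene_layout(12, gene_len = 12000, gap = 1000,
                       ids = lay$gene_id[c(1:5, 9, 6:8, 10:12)])
  tbl2 <- flag_missing(make_tbl(lay, ref2 = lay_b,
                                focal = drop_genes(lay, missing)), missing)
  b2 <- detect_missing_blocks(tbl2)
  expect_equal(nrow(b2), 1L)
  rb2 <- refilter_blocks(b2, tbl2, "human")
  expect_equal(nrow(rb2), 0L)
  expect_setequal(near_block_genes(rb2)$gene_id, missing)
  expect_equal(unique(near_block_genes(rb2)$reason), "refiltered_out")
  # members on an unplaced scaffold in B: retained but unverified
  lay_un <- lay
  lay_un$chr[5] <- "scafZ"
  lay_un$placed[5] <- FALSE
  tbl3 <- flag_missing(make_tbl(lay, ref2 = lay_un,
                                focal = drop_genes(lay, missing)), missing)
  b3 <- detect_missing_blocks(tbl3)
  rb3 <- refilter_blocks(b3, tbl3, "human")
  expect_equal(nrow(rb3), 1L)
  expect_false(rb3$verified_in_both)
})

test_that("refiltering is idempotent", {
  withr::with_seed(5, {
    inst <- random_block_instance(40)
    tbl <- flag_missing(make_tbl(inst$layout,
                                 focal = inst$layout[!inst$missing, ]),
                        inst$layout$gene_id[inst$missing])
    b <- detect_missing_blocks(tbl)
    r1 <- refilter_blocks(b, tbl, "human")
    r2 <- refilter_blocks(r1, tbl, "human")
    expect_equal(tibble::as_tibble(r1), tibble::as_tibble(r2))
    expect_equal(near_block_genes(r1), near_block_genes(r2))
  })
})

test_that("block spans follow end-minus-start and cumulative rules", {
  lay <- gene_layout(12, gene_len = 20000, gap = 5000)
  tbl <- make_flagged(lay, c("g002", "g003", "g004", "g008", "g009", "g010"))
  b <- detect_missing_blocks(tbl)
  sp <- block_spans(b, tbl, "lizard")
  # brute-force per-gene min/max recomputation
  v <- tibble::as_tibble(tbl)
  for (k in seq_len(nrow(b))) {
    idx <- match(b$members[[k]], v$gene_id)
    expect_equal(sp$per_block$span[k],
                 max(v$lizard_end[idx]) - min(v$lizard_start[idx]))
  }
  expect_equal(sp$cumulative, sum(sp$per_block$span))
  # two known blocks: cumulative is their sum
  expect_equal(sp$cumulative, sp$per_block$span[1] + sp$per_block$span[2])
  # a block with incomplete anchors in the target species is skipped
  v2 <- v
  v2$human_start[match("g003", v2$gene_id)] <- NA
  v2$human_end[match("g003", v2$gene_id)] <- NA
  v2$human_chr[match("g003", v2$gene_id)] <- NA
  tbl2 <- flag_missing(
    sort_ortholog_table(ortholog_table(v2, ortholog_species(tbl)), "lizard"),
    c("g002", "g003", "g004", "g008", "g009", "g010"))
  expect_warning(sp2 <- block_spans(b, tbl2, "human"), "skipped")
  expect_equal(nrow(sp2$per_block), 1L)
})

test_that("flanking-block rearrangement calls follow the precedence rules", {
  lay <- gene_layout(10, gene_len = 20000, gap = 5000)
  missing <- c("g004", "g005")
  base_focal <- drop_genes(lay, missing)

  run_call <- function(focal_layout) {
    tbl <- flag_missing(make_tbl(lay, focal = focal_layout), missing)
    b <- detect_missing_blocks(tbl, thresholds = loss_thresholds(
      doublet_min_span = 30000))
    classify_flanking_rearrangements(b, tbl, "chicken")$call
  }
  # adjacent, same order, same chromosome -> colinear
  expect_equal(run_call(base_focal), "colinear")
  # flanks on different focal chromosomes
  diff_chr <- base_focal
  diff_chr$chr[diff_chr$gene_id >= "g006"] <- "5"
  expect_equal(run_call(diff_chr), "different_chromosome")
  # same chromosome but 8 Mb apart (threshold 5 Mb)
  distant <- base_focal
  late <- distant$gene_id >= "g006"
  distant$start[late] <- distant$start[late] + 8e6
  distant$end[late] <- distant$end[late] + 8e6
  expect_equal(run_call(distant), "same_chr_distant")
  # order swapped without strand flips -> reordered
  swapped <- base_focal[match(c("g001", "g002", "g006", "g007", "g008",
                                "g003", "g009", "g010"), base_focal$gene_id), ]
  swapped$start <- gene_layout(8, gene_len = 20000, gap = 5000)$start
  swapped$end <- swapped$start + 19999
  expect_equal(run_call(swapped), "same_chr_reordered")
  # order swapped with both flank strands flipped -> reversed (inversion)
  reversed <- swapped
  reversed$strand[reversed$gene_id %in% c("g003", "g006")] <- "-"
  expect_equal(run_call(reversed), "same_chr_reversed")
  # flank unplaced in focal genome -> unresolved
  unp <- base_focal
  unp$placed[unp$gene_id == "g006"] <- FALSE
  expect_equal(run_call(unp), "unresolved")
})

test_that("BED export is 0-based half-open", {
  lay <- gene_layout(6, gene_len = 20000, gap = 5000)
  tbl <- make_flagged(lay, c("g002", "g003", "g004"))
  b <- detect_missing_blocks(tbl)
  path <- withr::local_tempfile(fileext = ".bed")
  export_blocks_bed(b, tbl, "lizard", path)
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                             "score", "strand"),
                         col_types = "ciicic")
  expect_equal(bed$start, as.integer(b$start - 1))
  expect_equal(bed$end, as.integer(b$end))
  expect_equal(bed$end - bed$start, as.integer(b$span + 1))
})
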