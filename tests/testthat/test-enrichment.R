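toy_genome <- function(n = 500, n_chr = 5) {
  gene_layout(n, chr = as.character(rep(seq_len(n_chr), each = n / n_chr)),
              gene_len = 20000, gap = 5000,
              ids = sprintf("g%04d", seq_len(n)))
}

test_that("control sets honour every matching constraint", {
  tbl <- make_tbl(toy_genome())
  req <- tibble::tibble(chromosome = c("1", "3"), n_genes = c(4L, 3L),
                        span = NA_real_)
  excluded <- c("g0010", "g0011", "g0012", "g0013")
  sets <- generate_control_sets(tbl, req, n_sets = 20, seed = 21,
                                exclude = excluded)
  v <- tibble::as_tibble(tbl)
  for (s in sets) {
    expect_length(s, 7L)
    expect_equal(anyDuplicated(s), 0L)
    expect_length(intersect(s, excluded), 0L)
    # independent verification: chromosome, contiguity and two-species
    # colinearity of each emitted block
    blk1 <- s[1:4]; blk2 <- s[5:7]
    for (blk in list(blk1, blk2)) {
      idx <- match(blk, v$gene_id)
      expect_equal(length(unique(v$lizard_chr[idx])), 1L)
      pos <- sort(match(blk, v$gene_id[v$lizard_chr == v$lizard_chr[idx[1]]]))
      expect_equal(pos, seq(min(pos), length.out = length(blk)))
      bo <- order(v$human_start[idx])
      ao <- order(v$lizard_start[idx])
      expect_true(identical(bo, ao) || identical(bo, rev(ao)))
    }
    expect_equal(unique(v$lizard_chr[match(blk1, v$gene_id)]), "1")
    expect_equal(unique(v$lizard_chr[match(blk2, v$gene_id)]), "3")
  }
})

test_that("control sets are seed-reproducible and span matching works", {
  tbl <- make_tbl(toy_genome())
  req <- tibble::tibble(chromosome = "2", n_genes = 3L, span = 70000)
  s1 <- generate_control_sets(tbl, req, n_sets = 5, seed = 77)
  s2 <- generate_control_sets(tbl, req, n_sets = 5, seed = 77)
  expect_identical(unclass(s1)[], unclass(s2)[])
  s3 <- generate_control_sets(tbl, req, n_sets = 5, seed = 78)
  expect_false(identical(unclass(s1)[], unclass(s3)[]))
  # span of every emitted block within the +/-20% tolerance
  v <- tibble::as_tibble(tbl)
  for (s in s1) {
    idx <- match(s, v$gene_id)
    span <- max(v$lizard_end[idx]) - min(v$lizard_start[idx])
    expect_lte(abs(span - 70000), 0.2 * 70000)
  }
  # an unsatisfiable requirement names itself
  bad <- tibble::tibble(chromosome = "2", n_genes = 3L, span = 5e6)
  expect_error(generate_control_sets(tbl, bad, n_sets = 1, seed = 1,
                                     max_attempts = 50),
               "requirement 1")
  # empty spec -> empty sets
  empty <- generate_control_sets(tbl, tibble::tibble(chromosome = character(),
                                                     n_genes = integer()),
                                 n_sets = 3, seed = 1)
  expect_length(empty, 3L)
  expect_length(empty[[1]], 0L)
})

make_ann <- function(pairs, source = "go") {
  annotation_table(tibble::tibble(gene_id = pairs[[1]], term_id = pairs[[2]]),
                   source = source)
}

test_that("permutation p-values behave at the degenerate extremes", {
  universe <- sprintf("u%02d", 1:10)
  ann <- make_ann(list(universe, rep("T1", 10)))  # every gene annotated
  res <- permutation_test(universe[1:4], ann, universe, n_permutations = 50,
                          seed = 1)
  expect_equal(res$p_value, 1)  # statistic identical in all permutations
  expect_error(permutation_test(character(), ann, universe), "non-empty")
  # p bounded below by 1/(n+1) with the add-one correction
  ann2 <- make_ann(list(universe[1:4], rep("T1", 4)))
  res2 <- permutation_test(universe[1:4], ann2, universe,
                           n_permutations = 200, seed = 2)
  expect_gte(res2$p_value, 1 / 201)
  expect_lte(res2$p_value, 1)
})

test_that("permutation p equals exact enumeration on a 5-gene universe", {
  universe <- c("a", "b", "c", "d", "e")
  ann <- make_ann(list(c("a", "b", "c"), c("T1", "T1", "T2")))
  all_pairs <- utils::combn(universe, 2, simplify = FALSE)  # all 10 controls
  obs_set <- c("a", "b")
  res <- permutation_test(obs_set, ann, universe, controls = all_pairs,
                          exhaustive = TRUE)
  # oracle: statistic = genes with >= 1 term; enumerate all C(5,2) subsets
  stat <- function(s) sum(s %in% c("a", "b", "c"))
  null <- vapply(all_pairs, stat, numeric(1))
  obs <- stat(obs_set)
  p_exact <- min(1, 2 * min(sum(null >= obs), sum(null <= obs)) / 10)
  expect_equal(res$p_value, p_exact)
})

test_that("phenotype runs exclude the no-abnormal-phenotype catch-all", {
  universe <- sprintf("u%02d", 1:10)
  ann <- annotation_table(
    tibble::tibble(gene_id = c(universe, "u01"),
                   term_id = c(rep("MP:none", 10), "MP:0001")),
    catalog = tibble::tibble(
      term_id = c("MP:none", "MP:0001"),
      label = c("No abnormal phenotype detected", "real phenotype")),
    source = "phenotype")
  res <- permutation_test(universe[1:3], ann, universe, n_permutations = 50,
                          seed = 4)
  expect_false("MP:none" %in% res$terms$term_id)
  # the total statistic counts only genes with a real term
  expect_equal(res$observed, sum(c("u01") %in% universe[1:3]))
})

test_that("per-term q-values are BH-consistent", {
  withr::with_seed(8, {
    universe <- sprintf("u%03d", 1:120)
    pairs <- tibble::tibble(
      gene_id = sample(universe, 300, replace = TRUE),
      term_id = sample(paste0("T", 1:12), 300, replace = TRUE))
    ann <- annotation_table(dplyr::distinct(pairs), source = "go")
    res <- permutation_test(sample(universe, 25), ann, universe,
                            n_permutations = 99, seed = 5)
  })
  tt <- res$terms
  expect_equal(tt$q_value, oracle_bh(tt$p_value))
  o <- order(tt$p_value)
  expect_true(all(diff(tt$q_value[o]) >= -1e-12))
  expect_gte(min(tt$q_value), min(tt$p_value))
  expect_true(all(tt$q_value >= tt$p_value - 1e-12))
})

test_that("Fisher term enrichment matches hypergeometric enumeration", {
  # equal term frequency, balanced counts: observed table is the mode
  set <- sprintf("s%d", 1:4)
  bg_only <- sprintf("b%d", 1:4)
  ann <- make_ann(list(c("s1", "s2", "b1", "b2"), rep("T1", 4)))
  bal <- fisher_term_enrichment(set, c(set, bg_only), ann)
  expect_equal(bal$p_value, 1)
  # table (3, 10; 7, 80) against the enumeration oracle
  set2 <- sprintf("s%02d", 1:10)
  bg2 <- c(set2, sprintf("b%02d", 1:90))
  carriers <- c(set2[1:3], sprintf("b%02d", 1:10))
  ann2 <- make_ann(list(carriers, rep("T1", length(carriers))))
  res2 <- fisher_term_enrichment(set2, bg2, ann2)
  expect_equal(res2$set_with, 3)
  expect_equal(res2$bg_with, 10)
  expect_equal(res2$set_without, 7)
  expect_equal(res2$bg_without, 80)
  expect_equal(res2$p_value, oracle_fisher_p(3, 10, 7, 80))
  # the enriched flag is a strict alpha threshold
  expect_identical(res2$enriched, res2$p_value < 0.05)
  just_below <- fisher_term_enrichment(set2, bg2, ann2,
                                       alpha = res2$p_value * 1.001)
  just_above <- fisher_term_enrichment(set2, bg2, ann2,
                                       alpha = res2$p_value * 0.999)
  expect_true(just_below$enriched)
  expect_false(just_above$enriched)
  expect_error(fisher_term_enrichment(c("zz"), bg2, ann2), "subset")
})

test_that("Venn classification follows the 7-region truth table", {
  tt <- expand.grid(chicken = c(FALSE, TRUE), human = c(FALSE, TRUE),
                    lizard = c(FALSE, TRUE))
  expected <- c("none",  # - - -
                "B1",    # C - -
                "A",     # - H -
                "B2",    # C H -
                "C",     # - - L
                "C",     # C - L
                "A",     # - H L
                "B2")    # C H L
  for (i in seq_len(nrow(tt))) {
    term <- "T1"
    vg <- venn_group_classify(
      chicken = if (tt$chicken[i]) term else character(),
      human = if (tt$human[i]) term else character(),
      lizard = if (tt$lizard[i]) term else character())
    got <- if (nrow(vg$terms) == 0) "none" else vg$terms$group
    expect_equal(got, expected[i],
                 label = sprintf("region C=%d H=%d L=%d", tt$chicken[i],
                                 tt$human[i], tt$lizard[i]))
  }
})

test_that("per-gene Venn conflicts follow the similarity rule", {
  # gene gX carries a Group A term and a Group B2 term
  vg <- venn_group_classify(
    chicken = "kinase activity",
    human = c("protein kinase activity", "kinase activity"),
    lizard = character(),
    gene_terms = tibble::tibble(
      gene_id = c("gX", "gX", "gY"),
      term_id = c("protein kinase activity", "kinase activity",
                  "protein kinase activity")),
    similar = function(a, b) grepl("kinase", a) && grepl("kinase", b))
  gX <- vg$genes[vg$genes$gene_id == "gX", ]
  expect_equal(gX$groups[[1]], "B2")  # most species-inclusive group
  expect_equal(gX$resolution, "similar_terms_most_inclusive")
  gY <- vg$genes[vg$genes$gene_id == "gY", ]
  expect_equal(gY$groups[[1]], "A")
  # dissimilar terms: the gene is listed in both groups
  vg2 <- venn_group_classify(
    chicken = "feather development",
    human = "lipid transport",
    lizard = character(),
    gene_terms = tibble::tibble(
      gene_id = c("gZ", "gZ"),
      term_id = c("feather development", "lipid transport")))
  gZ <- vg2$genes[vg2$genes$gene_id == "gZ", ]
  expect_setequal(gZ$groups[[1]], c("A", "B1"))
  expect_equal(gZ$resolution, "dissimilar_terms_listed_in_each")
})
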