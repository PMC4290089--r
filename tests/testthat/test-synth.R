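test_that("simulated tables are deterministic given the seed", {
  spec <- genome_sim_spec(seed = 13, dropout_rate = 0.05,
                          inversion_rate = 0.3, translocation_rate = 0.2,
                          unplaced_fraction = 0.02)
  s1 <- simulate_ortholog_tables(spec)
  s2 <- simulate_ortholog_tables(spec)
  expect_identical(tibble::as_tibble(s1$table), tibble::as_tibble(s2$table))
  expect_identical(s1$truth$dropout_genes, s2$truth$dropout_genes)
  s3 <- simulate_ortholog_tables(genome_sim_spec(seed = 14,
                                                 dropout_rate = 0.05))
  expect_false(identical(tibble::as_tibble(s1$table),
                         tibble::as_tibble(s3$table)))
})

test_that("a zero-deletion genome yields no candidates", {
  spec <- genome_sim_spec(planted_blocks = tibble::tibble(n_genes = integer()),
                          seed = 2)
  sim <- simulate_ortholog_tables(spec)
  cand <- identify_candidates(sim$table, c("lizard", "human"), "chicken")
  expect_equal(glance(cand)$n_candidates, 0L)
})

test_that("planted blocks are recovered exactly with zero noise", {
  spec <- genome_sim_spec(seed = 31)
  sim <- simulate_ortholog_tables(spec)
  cand <- identify_candidates(sim$table, c("lizard", "human"), "chicken")
  tbl <- flag_missing(sim$table, cand)
  blocks <- detect_missing_blocks(tbl)
  truth_keys <- vapply(sim$truth$planted_blocks$members, function(m) {
    paste(sort(m), collapse = ",")
  }, character(1))
  got_keys <- vapply(blocks$members, function(m) paste(sort(m), collapse = ","),
                     character(1))
  expect_setequal(got_keys, truth_keys)
})

test_that("emitted tables satisfy the container invariants", {
  sim <- simulate_ortholog_tables(genome_sim_spec(seed = 4,
                                                  unplaced_fraction = 0.05,
                                                  dropout_rate = 0.02))
  tbl <- sim$table
  # re-validating the raw data must succeed
  expect_silent(revalidated <- ortholog_table(tibble::as_tibble(tbl),
                                              ortholog_species(tbl)))
  v <- tibble::as_tibble(tbl)
  for (s in ortholog_species(tbl)) {
    st <- v[[paste0(s, "_start")]]; en <- v[[paste0(s, "_end")]]
    ok <- !is.na(st)
    expect_true(all(st[ok] >= 1))
    expect_true(all(en[ok] >= st[ok]))
  }
  # absent focal orthologs are exactly class "none"
  expect_identical(is.na(v$chicken_id), v$chicken_class == "none")
})

test_that("gene-level degradation grows with the dropout rate", {
  rates <- c(0, 0.05, 0.15, 0.3)
  n_cand <- integer(length(rates))
  for (i in seq_along(rates)) {
    spec <- genome_sim_spec(seed = 50, dropout_rate = rates[i])
    sim <- simulate_ortholog_tables(spec)
    cand <- identify_candidates(sim$table, c("lizard", "human"), "chicken")
    n_cand[i] <- glance(cand)$n_candidates
    # planted blocks stay recoverable: dropout is kept off block margins
    tbl <- flag_missing(sim$table, cand)
    blocks <- detect_missing_blocks(tbl)
    truth_keys <- vapply(sim$truth$planted_blocks$members, function(m) {
      paste(sort(m), collapse = ",")
    }, character(1))
    got_keys <- vapply(blocks$members, function(m) {
      paste(sort(m), collapse = ",")
    }, character(1))
    expect_true(all(truth_keys %in% got_keys))
  }
  # same seed, higher rate: the dropout set grows monotonically
  expect_true(all(diff(n_cand) >= 0))
})

test_that("planted annotation enrichments hit their target rates", {
  genes <- sprintf("g%04d", 1:5000)
  target <- withr::with_seed(99, sample(genes, 50))
  # relative risk 0: no carriers inside the target set
  zero <- simulate_annotations(genes, "T1",
                               planted = tibble::tibble(
                                 term_id = "T1", relative_risk = 0,
                                 set = list(target)),
                               base_rate = 0.1, seed = 6)
  expect_length(intersect(zero$annotation$gene_id[
    zero$annotation$term_id == "T1"], target), 0L)
  # relative risk 5 on base 0.1: in-set carrier frequency ~0.5
  freqs <- vapply(1:5, function(s) {
    sim <- simulate_annotations(genes, "T1",
                                planted = tibble::tibble(
                                  term_id = "T1", relative_risk = 5,
                                  set = list(target)),
                                base_rate = 0.1, seed = s)
    length(intersect(sim$annotation$gene_id, target)) / length(target)
  }, numeric(1))
  sd3 <- 3 * sqrt(0.5 * 0.5 / 50)
  expect_true(all(abs(freqs - 0.5) <= sd3))
  # relative risk 1 everywhere: in-set and background frequencies agree
  null <- simulate_annotations(genes, "T1", base_rate = 0.1, seed = 7)
  f_in <- length(intersect(null$annotation$gene_id, target)) / 50
  f_out <- length(setdiff(null$annotation$gene_id, target)) / 4950
  expect_lt(abs(f_in - f_out), 3 * sqrt(0.1 * 0.9 / 50))
  # capping warns
  expect_warning(simulate_annotations(genes[1:10], "T1",
                                      planted = tibble::tibble(
                                        term_id = "T1", relative_risk = 20,
                                        set = list(genes[1:5])),
                                      base_rate = 0.1, seed = 1),
                 "capped")
})
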