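toy_table <- function(seed = 1, n = 4, len = 200, k = 3) {
  set.seed(seed)
  recs <- lapply(LETTERS[seq_len(n)], random_dna_record, len = len)
  vector_table(lapply(recs, dl_composition, k = k))
}

test_that("resampled multiplicities sum to the full component count N", {
  tab <- toy_table()
  expect_equal(sum(tab$weights) + tab$zero_weight, tab$n_total)
  for (s in 1:5) {
    rt <- resample_columns(tab, seed = s)
    expect_true(all(rt$weights == floor(rt$weights)))
    expect_true(all(rt$weights >= 0))
    expect_equal(sum(rt$weights) + rt$zero_weight, tab$n_total)
  }
  # protein table spans a much larger implicit component space
  set.seed(2)
  precs <- lapply(c("p1", "p2", "p3"), function(id) {
    genome_record(id, random_seq(300, "protein"), "protein")
  })
  ptab <- vector_table(lapply(precs, dl_composition, k = 3))
  prt <- resample_columns(ptab, seed = 3)
  expect_equal(sum(prt$weights) + prt$zero_weight, 20^3)
})

test_that("resampling is reproducible from the seed", {
  tab <- toy_table()
  a <- resample_columns(tab, seed = 99)
  b <- resample_columns(tab, seed = 99)
  expect_identical(a$weights, b$weights)
  expect_identical(a$zero_weight, b$zero_weight)
})

test_that("each column's expected multiplicity is one", {
  tab <- toy_table(seed = 3, n = 3, len = 120, k = 2)
  set.seed(123)
  reps <- 1000
  acc <- numeric(ncol(tab$values))
  for (i in seq_len(reps)) acc <- acc + resample_columns(tab)$weights
  means <- acc / reps
  # multiplicity of a fixed column is Binomial(N, 1/N): mean 1, var ~ 1
  se <- sqrt(1 / reps)
  expect_true(all(abs(means - 1) < 3.5 * se + 0.02))
  expect_lt(abs(mean(means) - 1), 3 * se)
})

test_that("unit weights reproduce the sparse pairwise distances exactly", {
  set.seed(4)
  recs <- lapply(c("A", "B", "C", "D"), random_dna_record, len = 250)
  vecs <- lapply(recs, dl_composition, k = 3)
  tab <- vector_table(vecs)
  for (m in c("correlation", "chord")) {
    expect_equal(dlphylo:::table_distance_matrix(tab, m),
                 distance_matrix(vecs, method = m), tolerance = 1e-12)
  }
})

test_that("bootstrap supports are seed-reproducible and bounded", {
  set.seed(5)
  sim <- simulate_genomes(5, n_genes = 3, gene_length = 300,
                          alphabet = "protein", branch_mean = 0.1, seed = 21)
  r1 <- bootstrap_supports(sim$records, 3, "correlation", B = 15, seed = 7)
  r2 <- bootstrap_supports(sim$records, 3, "correlation", B = 15, seed = 7)
  expect_identical(r1, r2)
  expect_true(all(r1$supports$support >= 0 & r1$supports$support <= 100))
  expect_identical(nrow(r1$supports), as.integer(sim$true_tree$Nnode - 1))
  # single replicate can only produce all-or-nothing supports
  r3 <- bootstrap_supports(sim$records, 3, "chord", B = 1, seed = 8)
  expect_true(all(r3$supports$support %in% c(0, 100)))
})

test_that("supports are invariant to taxon input order", {
  set.seed(6)
  sim <- simulate_genomes(5, n_genes = 2, gene_length = 400,
                          alphabet = "dna", branch_mean = 0.15, seed = 31)
  r1 <- bootstrap_supports(sim$records, 4, "chord", B = 10, seed = 9)
  r2 <- bootstrap_supports(rev(sim$records), 4, "chord", B = 10, seed = 9)
  s1 <- r1$supports[order(r1$supports$bipartition), ]
  s2 <- r2$supports[order(r2$supports$bipartition), ]
  expect_identical(s1$bipartition, s2$bipartition)
  expect_equal(s1$support, s2$support)
})

test_that("degenerate zero-variance vectors raise the documented error", {
  recs <- list(
    genome_record("h1", "AAAAAAAAAA", "dna"),
    genome_record("h2", "CCCCCCCCCC", "dna"),
    genome_record("ok", "ACGTACGTACG", "dna")
  )
  expect_error(bootstrap_supports(recs, 2, B = 5, seed = 1),
               class = "dl_undefined_correlation")
})

test_that("the distinct-columns variant keeps each drawn column once", {
  tab <- toy_table()
  rt <- resample_columns(tab, seed = 11, variant = "distinct")
  expect_true(all(rt$weights %in% c(0, 1)))
  expect_lte(sum(rt$weights) + rt$zero_weight, tab$n_total)
})

test_that("median support for the true clade does not decrease with sequence length", {
  tree <- parse_newick("(a:0.04,b:0.04,(c:0.04,d:0.04):0.03);")
  sup_by_len <- lapply(c(100, 400, 1600), function(len) {
    vapply(1:10, function(s) {
      sim <- evolve_sequences(tree, n_genes = 1, gene_length = len,
                              alphabet = "protein", seed = 5000 + s)
      bs <- bootstrap_supports(sim$records, 3, "correlation", B = 40,
                               seed = 6000 + s)
      v <- bs$supports$support[bs$supports$bipartition == "c|d"]
      # a reference tree resolving the wrong quartet gives the true clade
      # zero support
      if (length(v) == 0) 0 else v
    }, numeric(1))
  })
  med <- vapply(sup_by_len, median, numeric(1))
  expect_true(all(diff(med) >= 0))
  expect_gt(mean(sup_by_len[[3]]), mean(sup_by_len[[1]]))
})

test_that("majority-rule consensus keeps edges by their replicate frequency", {
  t_ab <- parse_newick("((A,B),(C,D));")
  cons_same <- majority_rule_consensus(list(t_ab, t_ab, t_ab))
  expect_identical(robinson_foulds(cons_same, t_ab), 0L)
  expect_true(all(cons_same$node.label[nzchar(cons_same$node.label)] == "100"))

  t_ac <- parse_newick("((A,C),(B,D));")
  cons <- majority_rule_consensus(list(t_ab, t_ab, t_ac))
  expect_identical(robinson_foulds(cons, t_ab), 0L)
  expect_true("66.7" %in% cons$node.label)

  star <- parse_newick("(A,B,C,D);")
  cons_star <- majority_rule_consensus(list(star, star))
  expect_identical(cons_star$Nnode, 1L)

  bad <- parse_newick("((A,B),(C,E));")
  expect_error(majority_rule_consensus(list(t_ab, bad)),
               class = "dl_leafset_mismatch")
})
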