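make_cv <- function(id, len = 250, k = 3, alphabet = "dna") {
  dl_composition(genome_record(id, random_seq(len, alphabet), alphabet), k)
}

test_that("self- and mirror-correlations hit the exact endpoints", {
  set.seed(1)
  x <- make_cv("a")
  expect_equal(cv_correlation(x, x), 1)
  expect_equal(correlation_distance(x, x), 0)
  expect_equal(chord_distance(x, x), 0)
  neg <- x
  neg$x <- -neg$x
  neg$taxon_id <- "neg"
  expect_equal(cv_correlation(x, neg), -1)
  expect_equal(correlation_distance(x, neg), 1)
  expect_equal(chord_distance(x, neg), 2)
})

test_that("sparse full-N algebra matches the dense oracle at DNA K = 3", {
  set.seed(2)
  for (i in 1:20) {
    sa <- random_seq(200, "dna"); sb <- random_seq(200, "dna")
    xa <- dl_composition(genome_record("a", sa, "dna"), 3)
    xb <- dl_composition(genome_record("b", sb, "dna"), 3)
    da <- dense_dl_vector(sa, 3, "dna")$x
    db <- dense_dl_vector(sb, 3, "dna")$x
    expect_equal(correlation_distance(xa, xb),
                 dense_correlation_distance(da, db), tolerance = 1e-12)
    expect_equal(chord_distance(xa, xb),
                 dense_chord_distance(da, db), tolerance = 1e-12)
  }
})

test_that("the MAMA/AMAM pair matches the dense oracle exactly", {
  xa <- dl_composition(genome_record("a", "MAMA", "protein"), 2)
  xb <- dl_composition(genome_record("b", "AMAM", "protein"), 2)
  da <- dense_dl_vector("MAMA", 2, "protein")$x
  db <- dense_dl_vector("AMAM", 2, "protein")$x
  expect_equal(correlation_distance(xa, xb),
               dense_correlation_distance(da, db), tolerance = 1e-14)
})

test_that("distance bounds, symmetry and zero self-distance hold", {
  set.seed(3)
  for (i in 1:15) {
    x <- make_cv("a"); y <- make_cv("b")
    dc <- correlation_distance(x, y)
    ch <- chord_distance(x, y)
    expect_gte(dc, 0); expect_lte(dc, 1)
    expect_gte(ch, 0); expect_lte(ch, 2)
    expect_equal(dc, correlation_distance(y, x), tolerance = 1e-12)
    expect_equal(ch, chord_distance(y, x), tolerance = 1e-12)
  }
})

test_that("chord distance satisfies the triangle inequality on random triples", {
  set.seed(4)
  for (i in 1:100) {
    v <- lapply(c("a", "b", "c"), make_cv, len = 120)
    ab <- chord_distance(v[[1]], v[[2]])
    bc <- chord_distance(v[[2]], v[[3]])
    ac <- chord_distance(v[[1]], v[[3]])
    expect_lte(ac, ab + bc + 1e-9)
    expect_lte(ab, ac + bc + 1e-9)
    expect_lte(bc, ab + ac + 1e-9)
  }
})

test_that("degenerate vectors raise the documented correlation error", {
  # a homopolymer has p == q == 1 on its single K-mer, so X is identically 0
  z <- dl_composition(genome_record("z", "AAAAAAAA", "dna"), 2)
  x <- dl_composition(genome_record("x", "ACGTACGTAC", "dna"), 2)
  expect_error(cv_correlation(z, x), class = "dl_undefined_correlation")
  expect_error(chord_distance(z, z), class = "dl_undefined_distance")
})

test_that("distance_matrix obeys its contracts", {
  set.seed(5)
  recs <- lapply(c("A", "B", "C", "D"), random_dna_record, len = 200)
  dm <- distance_matrix(recs, 3, "correlation")
  expect_identical(rownames(dm), c("A", "B", "C", "D"))
  expect_true(all(diag(dm) == 0))
  expect_lt(max(abs(dm - t(dm))), 1e-12)
  # equals pair-by-pair recomputation
  va <- dl_composition(recs[[1]], 3); vb <- dl_composition(recs[[2]], 3)
  expect_equal(dm["A", "B"], correlation_distance(va, vb))
  # identical records are at distance zero
  same <- lapply(c("X", "Y", "Z"), function(id) {
    genome_record(id, recs[[1]]$sequences, "dna")
  })
  dm0 <- distance_matrix(same, 3, "chord")
  expect_true(all(dm0 == 0))
  # permuting the input permutes rows/columns consistently
  dm_perm <- distance_matrix(recs[c(3, 1, 4, 2)], 3, "correlation")
  expect_equal(dm_perm[rownames(dm), colnames(dm)], dm)
  # duplicate ids and undefined pairs are named errors
  expect_error(distance_matrix(recs[c(1, 1, 2)], 3), class = "dl_duplicate_taxa")
  degenerate <- c(recs[1:2], list(genome_record("hom", "AAAAAAAA", "dna")))
  expect_error(distance_matrix(degenerate, 2), class = "dl_undefined_pair")
})

test_that("PHYLIP matrices roundtrip within print precision", {
  set.seed(6)
  recs <- lapply(c("A", "B", "C"), random_dna_record, len = 150)
  dm <- distance_matrix(recs, 3, "chord")
  text <- write_phylip(dm)
  expect_match(text, "^    3\n")
  back <- read_phylip(text)
  expect_identical(rownames(back), rownames(dm))
  expect_equal(back, dm, tolerance = 1e-6)
  # file roundtrip
  path <- withr::local_tempfile(fileext = ".phy")
  write_phylip(dm, path)
  expect_equal(read_phylip(path), dm, tolerance = 1e-6)
})

test_that("malformed PHYLIP input is rejected with named errors", {
  expect_error(read_phylip("3\nA 0 1 2\nB 1 0 3"), class = "dl_malformed_file")
  expect_error(read_phylip("3\nA 0 1 2\nB 1 0 3\nC 2 3 0\nD 0 0 0"),
               class = "dl_malformed_file")
  expect_error(read_phylip("nope\nA 0"), class = "dl_malformed_file")
  expect_error(read_phylip("2\nA 0 1\nB 1 zero"), class = "dl_malformed_file")
})

test_that("the cosine flavour is exposed and differs from centered Pearson", {
  set.seed(8)
  x <- make_cv("a"); y <- make_cv("b")
  r_cos <- cv_correlation(x, y, type = "cosine")
  s <- sum(x$x[intersect(names(x$x), names(y$x))] *
             y$x[intersect(names(x$x), names(y$x))])
  expect_equal(r_cos, s / sqrt(sum(x$x^2) * sum(y$x^2)), tolerance = 1e-12)
})
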