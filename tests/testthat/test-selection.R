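test_that("fractional site counts match hand-derived and oracle values", {
  # Phe TTT: only TTC among the 9 neighbors is synonymous
  expect_equal(count_sites("TTT"), c(S = 1 / 3, N = 8 / 3))
  # Gly GGG: third position fully synonymous (4-fold family)
  s <- count_sites("GGG")
  expect_gte(s[["S"]], 1)
  expect_error(count_sites("TAA"), "stop")

  gc <- oracle_codon_table()
  for (codon in names(gc)[gc != "*"]) {
    expect_equal(count_sites(codon), oracle_sites(codon), tolerance = 1e-12)
    # S + N <= 3, equality iff no neighbor is a stop
    expect_lte(sum(count_sites(codon)), 3 + 1e-12)
  }
})

test_that("pairwise NG86 equals the exhaustive-pathway oracle on random codon pairs", {
  set.seed(20)
  gc <- oracle_codon_table()
  n_checked <- 0
  for (i in 1:500) {
    pair <- random_sense_codons(2)
    want <- oracle_path_diffs(pair[1], pair[2])
    if (is.null(want)) next  # all pathways stop-blocked (not reached in practice)
    r <- pairwise_kaks(pair[1], pair[2])
    expect_equal(c(Sd = r$Sd, Nd = r$Nd), want, tolerance = 1e-12)
    # pathway-average conservation: Sd + Nd = number of differing positions
    ndiff <- sum(strsplit(pair[1], "")[[1]] != strsplit(pair[2], "")[[1]])
    expect_equal(r$Sd + r$Nd, ndiff, tolerance = 1e-12)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 490)
})

test_that("pairwise Ka/Ks: symmetry, identity, and single-change cases", {
  set.seed(21)
  a <- paste(random_sense_codons(60), collapse = "")
  b <- paste(random_sense_codons(60), collapse = "")
  ra <- pairwise_kaks(a, b)
  rb <- pairwise_kaks(b, a)
  expect_identical(ra[c("S", "N", "Sd", "Nd", "Ka", "Ks")],
                   rb[c("S", "N", "Sd", "Nd", "Ka", "Ks")])

  r0 <- pairwise_kaks(a, a)
  expect_equal(r0$Ka, 0)
  expect_equal(r0$Ks, 0)
  expect_true(is.na(r0$ratio))  # 0/0 reported as undefined

  # one synonymous third-position change in a 4-fold codon among identical codons
  x <- paste(rep("GGA", 100), collapse = "")
  y <- paste(c(rep("GGA", 99), "GGC"), collapse = "")
  r1 <- pairwise_kaks(x, y)
  expect_equal(r1$Sd, 1)
  expect_equal(r1$Nd, 0)
  expect_equal(r1$Ka, 0)
  expect_gt(r1$Ks, 0)

  # gap/N codon columns are skipped
  r2 <- pairwise_kaks("ATG---GGA", "ATGCTAGGC")
  expect_equal(r2$codons_used, 2L)
  expect_equal(r2$codons_skipped, 1L)

  expect_error(pairwise_kaks("ATG", "ATGCTA"), "equal length")
  expect_error(pairwise_kaks("ATGC", "ATGA"), "multiple of 3")
})

test_that("Jukes-Cantor correction expands p and flags saturation", {
  set.seed(22)
  a <- paste(random_sense_codons(200), collapse = "")
  b <- paste(random_sense_codons(200), collapse = "")
  r <- pairwise_kaks(a, b)
  if (!is.na(r$Ks)) expect_gte(r$Ks, r$pS)
  if (!is.na(r$Ka)) expect_gte(r$Ka, r$pN)
  # two unrelated random sequences usually saturate pS (>= 0.75)
  expect_true(is.na(jc_distance_matrix(c(a = strrep("A", 8),
                                         b = strrep("C", 8)))["a", "b"]))
})

test_that("gene-wise means: identical sets give 0, aggregations reported", {
  seqs <- c(a = "ATGCTAGGAACC", b = "ATGCTAGGAACC", c = "ATGCTAGGAACC")
  res <- gene_mean_kaks(list(g1 = seqs))
  expect_equal(res$mean_Ka, 0)
  expect_equal(res$mean_Ks, 0)
  expect_equal(res$n_pairs, 3L)
  expect_warning(gene_mean_kaks(list(g1 = seqs, solo = seqs[1])), "skipped")
})

test_that("purifying and neutral regimes are recovered from simulated families", {
  # omega = 0.1 at interspecific divergence: estimate well below 1
  set.seed(23)
  anc <- paste(random_sense_codons(250), collapse = "")
  tree <- "(a:0.22,b:0.22,c:0.22,d:0.22);"
  fam01 <- evolve_family(anc, tree, omega = 0.1, kappa = 2, seed = 31)
  r01 <- gene_mean_kaks(list(g = fam01))
  expect_lt(r01$ratio_of_means, 0.3)
  expect_gt(r01$ratio_of_means, 0.02)

  # two genes at omega 0.05 and 0.5 keep their ordering
  f_lo <- evolve_family(anc, tree, omega = 0.05, kappa = 2, seed = 32)
  f_hi <- evolve_family(anc, tree, omega = 0.5, kappa = 2, seed = 33)
  r2 <- gene_mean_kaks(list(lo = f_lo, hi = f_hi))
  expect_lt(r2$ratio_of_means[r2$gene == "lo"], r2$ratio_of_means[r2$gene == "hi"])
})
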