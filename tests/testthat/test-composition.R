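test_that("base composition and skews come from exact counts", {
  p <- base_composition("ACGT")
  expect_equal(unlist(p[c("T_pct", "C_pct", "A_pct", "G_pct")]),
               c(25, 25, 25, 25), ignore_attr = TRUE)
  expect_equal(p$AT_skew, 0)
  expect_equal(p$GC_skew, 0)

  p <- base_composition("AAAA")
  expect_equal(p$A_pct, 100)
  expect_equal(p$AT_skew, 1)
  expect_true(is.na(p$GC_skew))  # zero G+C denominator flagged as NA

  # N excluded from all denominators
  p <- base_composition("AANN")
  expect_equal(p$A_pct, 100)
  expect_equal(p$size, 4L)

  expect_error(base_composition(""), "empty")
  expect_warning(base_composition("NNNN"), "all N")
})

test_that("skew matches the published 3-decimal values from printed percentages", {
  expect_equal(round(skew(31.4, 25.1), 3), 0.112)  # full-genome AT-skew
  expect_equal(round(skew(34.7, 20.1), 3), 0.266)  # rRNAs AT-skew
  expect_equal(skew(10, 10), 0)
})

test_that("skew invariants: bounds, sign, negation under revcomp", {
  set.seed(7)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
    p <- base_composition(s)
    expect_lte(abs(p$AT_skew), 1)
    expect_lte(abs(p$GC_skew), 1)
    expect_equal(sign(p$AT_skew), sign(p$n_A - p$n_T))
    q <- base_composition(revcomp(s))
    expect_equal(q$AT_skew, -p$AT_skew)
    expect_equal(q$GC_skew, -p$GC_skew)
  }
})

test_that("concatenation additivity of counts", {
  s1 <- "ACGTACGGGT"
  s2 <- "TTTACGN"
  p12 <- base_composition(paste0(s1, s2))
  p1 <- base_composition(s1)
  p2 <- base_composition(s2)
  for (b in c("n_A", "n_C", "n_G", "n_T", "n_N")) {
    expect_equal(p12[[b]], p1[[b]] + p2[[b]])
  }
})

test_that("region table matches direct counting and published-strand orientation", {
  rec <- simulate_mitogenome(seed = 4)
  comp <- region_compositions(rec)
  # full genome row equals direct counting of the sequence
  expect_equal(comp[comp$region == "Full genome", ],
               base_composition(rec$sequence, "Full genome"),
               ignore_attr = TRUE)
  # per-gene rows count heavy-strand slices: ND6 (light-strand gene) shows
  # skews inverted relative to its coding strand
  f <- rec$features
  nd6 <- f[f$name == "ND6", ]
  nd6_heavy <- base_composition(substr(rec$sequence, nd6$start, nd6$end))
  expect_equal(comp$AT_skew[comp$region == "ND6"], nd6_heavy$AT_skew)
  nd6_coding <- base_composition(revcomp(substr(rec$sequence, nd6$start, nd6$end)))
  expect_equal(nd6_coding$AT_skew, -nd6_heavy$AT_skew)
  # the concatenated PCG row is codon-trimmed: 3 x pooled codon count
  cds <- extract_cds(rec, trim = TRUE)
  expect_equal(comp$size[comp$region == "PCGs"], sum(nchar(cds)))
  expect_error(region_compositions(fish_mito_template()), "no sequence")
})

test_that("codon-position pooling across CDS sets", {
  p <- codon_position_composition(c("ATGATGATG"))
  expect_equal(p$A_pct, c(100, 0, 0))
  expect_equal(p$T_pct, c(0, 100, 0))
  expect_equal(p$G_pct, c(0, 0, 100))

  p2 <- codon_position_composition(c("ATGTAA", "ATGTAA"))
  expect_equal(p2$A_pct[1], 50)  # first positions: A,T,A,T
  expect_equal(p2$T_pct[1], 50)
  expect_equal(p2$size, rep(4L, 3))

  expect_error(codon_position_composition(character(0)), "empty")
  expect_error(codon_position_composition("AT"), "shorter")
})

test_that("generator composition targeting: regions hit their configured bands", {
  cfg <- sim_config()
  rec <- simulate_mitogenome(cfg, seed = 8)
  comp <- region_compositions(rec)
  row_of <- function(lbl) comp[comp$region == lbl, ]
  # i.i.d.-sampled regions vs their own configured probabilities:
  # goodness-of-fit at the region's actual sample size
  for (pair in list(c("D-loop", "control"), c("rRNAs", "rRNA"), c("tRNAs", "tRNA"))) {
    got <- row_of(pair[1])
    want <- cfg$region_probs[[pair[2]]][c("T", "C", "A", "G")]
    obs <- unlist(got[c("n_T", "n_C", "n_A", "n_G")])
    gof <- suppressWarnings(stats::chisq.test(obs, p = want))
    expect_gt(gof$p.value, 1e-4)
  }
  # genome-wide vs the mixture implied by the configuration: PCG bases follow
  # the sense-codon-restricted product measure, other regions their own probs
  gc <- mito_genetic_code()
  sense <- names(gc)[gc != "*"]
  w <- apply(do.call(rbind, strsplit(sense, "")), 1,
             function(b) prod(cfg$base_probs[b]))
  w <- w / sum(w)
  pcg_marginal <- sapply(c("A", "C", "G", "T"), function(b) {
    sum(w * rowSums(do.call(rbind, strsplit(sense, "")) == b)) / 3
  })
  f <- rec$features
  sizes <- c(
    PCG_H = sum(f$size[f$ftype == "PCG" & f$strand == "H"]),
    PCG_L = sum(f$size[f$ftype == "PCG" & f$strand == "L"]),
    control = sum(f$size[f$ftype == "control"]),
    rRNA = sum(f$size[f$ftype == "rRNA"]),
    tRNA = sum(f$size[f$ftype == "tRNA"]))
  spacer <- rec$length - sum(sizes) + 23  # overlapping bases counted once
  # light-strand PCGs appear complemented on the heavy strand
  pcg_marginal_L <- pcg_marginal[c(A = "T", C = "G", G = "C", T = "A")]
  names(pcg_marginal_L) <- c("A", "C", "G", "T")
  mix <- (sizes[["PCG_H"]] * pcg_marginal[c("A", "C", "G", "T")] +
          sizes[["PCG_L"]] * pcg_marginal_L[c("A", "C", "G", "T")] +
          sizes[["control"]] * cfg$region_probs$control[c("A", "C", "G", "T")] +
          sizes[["rRNA"]] * cfg$region_probs$rRNA[c("A", "C", "G", "T")] +
          sizes[["tRNA"]] * cfg$region_probs$tRNA[c("A", "C", "G", "T")] +
          spacer * cfg$base_probs[c("A", "C", "G", "T")]) / rec$length
  got <- row_of("Full genome")
  for (b in c("A", "C", "G", "T")) {
    expect_lt(abs(got[[paste0(b, "_pct")]] - 100 * mix[[b]]), 1)
  }
})
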