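tpl <- fish_mito_template()

test_that("adjacency spacers follow the signed gap/overlap convention", {
  adj <- compute_adjacencies(tpl)
  expect_equal(nrow(adj), nrow(tpl$features))
  get <- function(up) adj$spacer[adj$upstream == up]
  expect_equal(get("ND1"), 6L)          # gap before tRNA-Ile
  expect_equal(get("ATP8"), -7L)        # overlap with ATP6
  expect_equal(get("D-loop"), 0L)       # wrap pair abuts position 1
  expect_true(adj$circular[adj$upstream == "D-loop"])
})

test_that("circular closure holds exactly: sizes + signed spacers = length", {
  adj <- compute_adjacencies(tpl)
  expect_identical(sum(tpl$features$size) + sum(adj$spacer), tpl$length)
  # and on simulated genomes, whatever the seed
  for (s in 1:3) {
    rec <- simulate_mitogenome(seed = s)
    expect_identical(sum(rec$features$size) + sum(compute_adjacencies(rec)$spacer),
                     rec$length)
  }
})

test_that("structure summary reproduces the published template quantities", {
  sr <- summarize_structure(tpl)
  expect_equal(sr$n_spacers, 11L)
  expect_equal(sr$n_overlaps, 7L)
  expect_equal(sr$longest_spacer$spacer, 33L)
  expect_equal(c(sr$longest_spacer$upstream, sr$longest_spacer$downstream),
               c("tRNA-Asn", "tRNA-Cys"))
  expect_equal(sr$longest_overlap$spacer, -7L)
  expect_equal(sr$trna_size_range, c(67L, 76L))
  census <- sr$strand_census
  expect_equal(census["PCG", "L"], c(PCG = 1L), ignore_attr = TRUE)
  expect_equal(census["tRNA", "L"], c(tRNA = 8L), ignore_attr = TRUE)
  # census totals match feature counts per type
  expect_equal(rowSums(census)[names(table(tpl$features$ftype))],
               table(tpl$features$ftype), ignore_attr = TRUE)
})

test_that("start/stop codons are classified from sequence on coding strands", {
  # synthetic two-gene genome: one H-strand ATG..TAA, one L-strand ATG..TAA
  feats <- gene_features(c("fwd", "rev"), c(1, 13), c(12, 24), c("H", "L"))
  seqn <- paste0("ATGAAACCCTAA", revcomp("ATGGGGTTTTAA"))
  rec <- mitogenome(feats, sequence = seqn)
  sr <- summarize_structure(rec)
  expect_equal(unname(sr$start_codons), c("ATG", "ATG"))
  expect_equal(unname(sr$stop_codons), c("TAA", "TAA"))

  # incomplete stops: remainder 1 -> T--, remainder 2 -> TA-
  feats2 <- gene_features(c("p1", "p2"), c(1, 14), c(13, 27), "H")
  seqn2 <- paste0("ATGAAACCCAAAT", "ATGCCCAAACCCTA")
  rec2 <- mitogenome(feats2, sequence = seqn2)
  sr2 <- summarize_structure(rec2)
  expect_equal(unname(sr2$stop_codons), c("T--", "TA-"))

  expect_error(
    summarize_structure(mitogenome(gene_features(c("tiny", "t2"), c(1, 6), c(4, 9),
                                                 "H", ftype = c("PCG", "tRNA")),
                                   sequence = "ATGAAACGT")),
    "shorter than 6")
})

test_that("hairpin search agrees with exhaustive enumeration", {
  # enumeration over all (arm length, position) candidates: the maximal
  # hairpin has a 5 bp stem (GGGGA / TCCCC) around the loop AATT
  hit <- find_stem_loop("GGGGAAATTTCCCC", min_stem = 4)
  expect_equal(hit$stem, 5L)
  expect_equal(hit$arm5, "GGGGA")
  expect_equal(hit$arm3, "TCCCC")
  expect_equal(hit$loop_seq, "AATT")
  expect_identical(hit$arm3, revcomp(hit$arm5))

  expect_null(find_stem_loop("ACGTACGT", min_stem = 4))
  expect_null(find_stem_loop(strrep("A", 30), min_stem = 4))

  # random windows <= 50 bp against the brute-force oracle
  set.seed(42)
  for (i in 1:40) {
    w <- paste(sample(c("A", "C", "G", "T"), sample(12:50, 1), replace = TRUE),
               collapse = "")
    got <- find_stem_loop(w, min_stem = 3, max_loop = nchar(w))
    want <- oracle_stem_loop(w, min_stem = 3)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(c(stem = got$stem, loop = got$loop, start = got$start),
                   want, ignore_attr = TRUE)
    }
  }
})

test_that("stem arms of a reported hairpin are reverse-complementary", {
  rec <- simulate_mitogenome(seed = 3)
  adj <- compute_adjacencies(rec)
  gap <- adj[adj$upstream == "tRNA-Asn", ]
  up_end <- rec$features$end[rec$features$name == "tRNA-Asn"]
  window <- substr(rec$sequence, up_end + 1, up_end + gap$spacer)
  hit <- find_stem_loop(window, min_stem = 3)
  if (!is.null(hit)) {
    expect_identical(hit$arm3, revcomp(hit$arm5))
    expect_gte(hit$loop, 3L)
  } else {
    succeed("no hairpin in this random 33 bp window")
  }
})
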