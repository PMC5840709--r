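test_that("smith_waterman handles the identity and floor cases", {
  ns <- test_scheme_nt()
  r <- smith_waterman("ACGT", "ACGT", ns)
  expect_equal(r$score, 4)
  expect_equal(r$identity, 1)
  expect_equal(r$a_interval, c(0L, 4L))

  r0 <- smith_waterman("A", "T", ns)
  expect_equal(r0$score, 0)
  expect_equal(r0$n_cols, 0L)
})

test_that("smith_waterman matches the independent DP oracle", {
  ns <- test_scheme_nt()
  ps <- scoring_scheme("protein")
  with_seed(101, {
    for (rep in 1:30) {
      a <- random_nt(sample(3:40, 1))
      b <- random_nt(sample(3:40, 1))
      expect_equal(smith_waterman(a, b, ns)$score,
                   oracle_sw(a, b, ns$matrix, ns$gap_open, ns$gap_extend))
    }
    for (rep in 1:20) {
      a <- random_aa(sample(3:40, 1))
      b <- random_aa(sample(3:40, 1))
      expect_equal(smith_waterman(a, b, ps)$score,
                   oracle_sw(a, b, ps$matrix, ps$gap_open, ps$gap_extend))
    }
    # exhaustive enumeration on tiny inputs backs up the DP oracle
    for (rep in 1:5) {
      a <- random_nt(sample(2:4, 1))
      b <- random_nt(sample(2:4, 1))
      expect_equal(smith_waterman(a, b, ns)$score,
                   oracle_sw_tiny(a, b, ns$matrix, ns$gap_open, ns$gap_extend))
    }
  })
})

test_that("alignment score agrees with Biostrings as a second oracle", {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                baseOnly = TRUE)
  ns <- test_scheme_nt()
  with_seed(55, {
    for (rep in 1:10) {
      a <- random_nt(sample(10:50, 1))
      b <- random_nt(sample(10:50, 1))
      ref <- Biostrings::score(Biostrings::pairwiseAlignment(
        a, b, type = "local", substitutionMatrix = m,
        gapOpening = 2, gapExtension = 1))
      expect_equal(smith_waterman(a, b, ns)$score, ref)
    }
  })
})

test_that("smith_waterman score is symmetric in its arguments", {
  ns <- test_scheme_nt()
  with_seed(17, {
    for (rep in 1:20) {
      a <- random_nt(sample(5:30, 1))
      b <- random_nt(sample(5:30, 1))
      expect_equal(smith_waterman(a, b, ns)$score,
                   smith_waterman(b, a, ns)$score)
    }
  })
})

test_that("stop sentinel scores as mismatch against everything", {
  m <- blosum62()
  expect_true(all(m["*", ] < 0))
  expect_true(all(m[, "*"] < 0))
  expect_lt(m["*", "*"], 0)
})

test_that("E-value follows the closed form with its scaling laws", {
  expect_equal(evalue(20, 1000, 1000), 1e6 * 2^-20)
  expect_equal(round(evalue(20, 1000, 1000), 4), 0.9537)
  # exact linearity in database length
  expect_equal(evalue(20, 1000, 2000), 2 * evalue(20, 1000, 1000))
  # monotone decrease in bit score
  bits <- seq(10, 200, by = 5)
  ev <- vapply(bits, evalue, numeric(1), query_len = 500, db_len = 1e6)
  expect_true(all(diff(ev) < 0))
})

test_that("seed index counts positions and skips degenerate k-mers", {
  with_seed(5, {
    sc <- c(one = random_nt(1000))
    idx <- build_seed_index(sc, 12, "nucleotide")
    expect_equal(length(idx$pos_v), 1000 - 12 + 1)

    homo <- c(h = strrep("A", 50))
    idx2 <- build_seed_index(homo, 4, "nucleotide")
    expect_equal(length(ls(idx2$env)), 1L)

    expect_warning(idx3 <- build_seed_index(c(n = strrep("N", 100)), 4,
                                            "nucleotide"),
                   "empty seed index")
    expect_equal(length(idx3$pos_v), 0L)
  })
})

test_that("search finds planted queries on both strands", {
  with_seed(23, {
    flank1 <- random_nt(600)
    insert <- random_nt(120)
    flank2 <- random_nt(600)
    sc <- c(chr = paste0(flank1, insert, flank2))
    ns <- scoring_scheme("nucleotide")

    hits <- search_homology(c(q = insert), sc, ns)
    expect_gt(nrow(hits), 0)
    expect_equal(hits$identity[1], 1)
    expect_equal(hits$coverage[1], 1)
    expect_equal(hits$strand[1], "+")
    expect_equal(c(hits$start[1], hits$end[1]), c(600L, 720L))

    rhits <- search_homology(c(q = revcomp(insert)), sc, ns)
    expect_equal(rhits$strand[1], "-")
    expect_equal(c(rhits$start[1], rhits$end[1]), c(600L, 720L))
  })
})

test_that("translated search recovers a protein behind synonymous codons", {
  with_seed(31, {
    prot <- random_aa(90)
    cds <- synteloss:::backtranslate(prot)  # fresh random codon choices
    sc <- c(chr = paste0(random_nt(500), cds, random_nt(500)))
    hits <- search_homology(c(p = prot), sc, scoring_scheme("protein"))
    expect_gt(nrow(hits), 0)
    expect_equal(hits$identity[1], 1)
    expect_gte(hits$coverage[1], 0.95)
  })
})

test_that("planted loci rank first across divergence up to 0.2", {
  with_seed(67, {
    ps <- scoring_scheme("protein")
    for (rep in 1:50) {
      d <- runif(1, 0, 0.2)
      prot <- random_aa(sample(80:150, 1))
      mut <- synteloss:::mutate_protein(prot, d)
      sc <- c(chr = paste0(random_nt(400), synteloss:::backtranslate(mut),
                           random_nt(400)))
      hits <- search_homology(c(p = prot), sc, ps,
                              params = list(e_max = Inf, min_coverage = 0))
      expect_gt(nrow(hits), 0)
      planted_start <- 400L
      expect_lt(abs(hits$start[1] - planted_start), 50L)
    }
  })
})

test_that("raising min_coverage never adds hits", {
  with_seed(41, {
    prot <- random_aa(100)
    sc <- c(chr = paste0(random_nt(300), synteloss:::backtranslate(prot),
                         random_nt(300)))
    ps <- scoring_scheme("protein")
    covs <- c(0, 0.25, 0.5, 0.75, 0.95)
    ns <- vapply(covs, function(mc)
      nrow(search_homology(c(p = prot), sc, ps,
                           params = list(min_coverage = mc, e_max = Inf))),
      integer(1))
    expect_true(all(diff(ns) <= 0))
  })
})

test_that("empty substrate yields an empty hit list, not an error", {
  expect_message(
    h <- search_homology(c(q = "ACGTACGTACGTACGT"), character(0),
                         scoring_scheme("nucleotide")),
    "empty substrate")
  expect_equal(nrow(h), 0L)
})
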