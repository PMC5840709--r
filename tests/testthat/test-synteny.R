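test_that("neighborhood extraction respects window and scaffold ends", {
  g <- symbol_row_genome(paste0("s", 1:7))
  nb <- extract_neighborhood(g, "s4", window = 3)
  expect_equal(nb$upstream, c("S1", "S2", "S3"))
  expect_equal(nb$downstream, c("S5", "S6", "S7"))
  expect_equal(nb$focal, "S4")

  first <- extract_neighborhood(g, "s1", window = 3)
  expect_length(first$upstream, 0)
  expect_equal(first$downstream, c("S2", "S3", "S4"))

  expect_error(extract_neighborhood(g, "missing"), "no gene")

  # virtual neighborhood around a position between genes
  sg <- scaffold_genes(g, "scA")
  pos <- sg$end[3] + 5L
  virt <- extract_neighborhood(g, list(scaffold = "scA", pos = pos),
                               window = 2)
  expect_true(is.na(virt$focal))
  expect_equal(virt$upstream, c("S2", "S3"))
  expect_equal(virt$downstream, c("S4", "S5"))
})

test_that("synteny score matches brute-force common-subsequence enumeration", {
  nb_of <- function(syms) {
    g <- symbol_row_genome(c("focal", syms))
    extract_neighborhood(g, "focal", window = length(syms))
  }
  a <- nb_of(c("g1", "g2", "g3", "g4"))
  b <- nb_of(c("g1", "g3", "g2", "g4"))
  sc <- synteny_score(a, b)
  expect_equal(sc$n_lcs, 3L)
  expect_equal(sc$score, 0.75)
  expect_equal(oracle_lcs(c("G1", "G2", "G3", "G4"),
                          c("G1", "G3", "G2", "G4")), 3L)

  expect_equal(synteny_score(a, a)$score, 1)
  expect_equal(synteny_score(a, nb_of(c("x1", "x2", "x3")))$score, 0)


  # randomized agreement with the enumeration oracle (orientation fixed by
  # taking the better of forward and reversed, as the scorer does)
  with_seed(73, {
    for (rep in 1:15) {
      pa <- sample(paste0("g", 1:6))
      pb <- sample(paste0("g", 1:6), sample(3:6, 1))
      na <- nb_of(pa)
      nbb <- nb_of(pb)
      got <- synteny_score(na, nbb)
      A <- toupper(pa[pa %in% pb])
      B <- toupper(pb[pb %in% pa])
      want <- max(oracle_lcs(A, B), oracle_lcs(A, rev(B))) /
        min(length(pa), length(pb))
      expect_equal(got$score, want)
    }
  })
})

test_that("synteny score is symmetric and reversal-invariant", {
  nb_of <- function(syms) {
    g <- symbol_row_genome(c("focal", syms))
    extract_neighborhood(g, "focal", window = length(syms))
  }
  with_seed(29, {
    for (rep in 1:10) {
      pa <- sample(paste0("g", 1:7), 5)
      pb <- sample(paste0("g", 1:7), 5)
      a <- nb_of(pa)
      b <- nb_of(pb)
      expect_equal(synteny_score(a, b)$score, synteny_score(b, a)$score)
      ar <- nb_of(rev(pa))
      br <- nb_of(rev(pb))
      expect_equal(synteny_score(ar, br)$score, synteny_score(a, b)$score)
    }
  })
})

test_that("windows with no named genes score zero with a status flag", {
  g <- symbol_row_genome(paste0("u", 1:5))
  g$genes$symbol <- ""
  g2 <- annotated_genome(g$scaffolds, g$genes)
  nb1 <- extract_neighborhood(g2, "id_u3", window = 2)
  nb2 <- extract_neighborhood(g2, "id_u3", window = 2)
  sc <- synteny_score(nb1, nb2)
  expect_equal(sc$score, 0)
  expect_equal(sc$status, "no_named_genes")
})

test_that("anchoring an identical target yields both flanks for interior genes", {
  cfg <- sim_config(seed = 3, n_scaffolds = 2, genes_per_scaffold = 6,
                    divergence = 0, indel_rate = 0, n_losses = 0,
                    n_paralog_duplications = 0, n_inversions = 0)
  sp <- generate_pair(cfg)
  interior <- sp$reference$genes$id[
    !sp$reference$genes$id %in%
      unlist(lapply(split(sp$reference$genes, sp$reference$genes$scaffold),
                    function(d) d$id[c(1, nrow(d))]))]
  for (id in interior) {
    nb <- extract_neighborhood(sp$reference, id, window = 3)
    anc <- anchor_flanks(sp$target, nb, sp$panel)
    expect_equal(anc$status, "both_flanks")
  }
})

test_that("at zero divergence the anchored interval equals the truth gap", {
  cfg <- sim_config(seed = 8, n_scaffolds = 3, genes_per_scaffold = 8,
                    divergence = 0, indel_rate = 0, n_losses = 4,
                    n_paralog_duplications = 0, n_inversions = 0)
  sp <- generate_pair(cfg)
  lost <- sp$truth[sp$truth$fate == "lost", ]
  for (i in seq_len(nrow(lost))) {
    nb <- extract_neighborhood(sp$reference, lost$id[i], window = 5)
    anc <- anchor_flanks(sp$target, nb, sp$panel)
    expect_equal(anc$status, "both_flanks")
    expect_equal(anc$interval$scaffold, lost$interval_scaffold[i])
    expect_equal(anc$interval$start, lost$interval_start[i])
    expect_equal(anc$interval$end, lost$interval_end[i])
  }
})

test_that("flanks split across scaffolds never produce an interval", {
  ga <- symbol_row_genome(c("u1", "focal", "d1"), scaffold = "ref_sc")
  # target carries u1 and d1 on different scaffolds
  up <- symbol_row_genome("u1", scaffold = "tA")
  down <- symbol_row_genome("d1", scaffold = "tB")
  target <- annotated_genome(c(up$scaffolds, down$scaffolds),
                             rbind(up$genes, down$genes))
  nb <- extract_neighborhood(ga, "focal", window = 2)
  anc <- anchor_flanks(target, nb)
  expect_true(anc$status %in% c("one_flank", "none"))
  expect_null(anc$interval)
})

test_that("symbol-stripped targets still anchor through homology", {
  cfg <- sim_config(seed = 12, n_scaffolds = 2, genes_per_scaffold = 6,
                    divergence = 0.1, indel_rate = 0, n_losses = 1,
                    n_paralog_duplications = 0, n_inversions = 0)
  sp <- generate_pair(cfg)
  lost_id <- sp$truth$id[sp$truth$fate == "lost"]
  stripped <- sp$target
  new_ids <- sprintf("anon%03d", seq_len(nrow(stripped$genes)))
  stripped$cds$gene_id <- new_ids[match(stripped$cds$gene_id,
                                        stripped$genes$id)]
  stripped$genes$id <- new_ids
  stripped$genes$symbol <- ""
  stripped <- annotated_genome(stripped$scaffolds, stripped$genes,
                               stripped$cds)
  nb <- extract_neighborhood(sp$reference, lost_id, window = 3)
  anc <- anchor_flanks(stripped, nb, sp$panel)
  expect_equal(anc$status, "both_flanks")
  expect_true(all(anc$anchors$method == "homology"))
})

test_that("interval scans find planted queries and stay quiet elsewhere", {
  with_seed(91, {
    prot <- random_aa(120)
    cds <- synteloss:::backtranslate(prot)
    left <- random_nt(3000)
    right <- random_nt(3000)
    sc <- c(chrI = paste0(left, cds, right))
    genome <- annotated_genome(sc, data.frame(
      id = "flank", symbol = "flank", scaffold = "chrI", start = 0L,
      end = 100L, strand = "+", stringsAsFactors = FALSE))

    hit_iv <- list(scaffold = "chrI", start = 2900L,
                   end = 3100L + nchar(cds))
    hits <- scan_interval(genome, hit_iv, c(q = prot))
    expect_gt(nrow(hits), 0)
    expect_equal(attr(hits, "scan_status"), "scanned")

    zero <- scan_interval(genome, list(scaffold = "chrI", start = 500L,
                                       end = 500L), c(q = prot))
    expect_equal(nrow(zero), 0L)
    expect_equal(attr(zero, "scan_status"), "empty_interval")

    # false-positive rate over pure intergenic intervals
    fp <- 0L
    for (rep in 1:100) {
      iv_genome <- annotated_genome(c(chr = random_nt(4000)),
                                    data.frame(id = "g", symbol = "g",
                                               scaffold = "chr", start = 0L,
                                               end = 10L, strand = "+",
                                               stringsAsFactors = FALSE))
      q <- random_aa(150)
      s <- scan_interval(iv_genome, list(scaffold = "chr", start = 0L,
                                         end = 4000L), c(q = q),
                         params = list(pad = 0L))
      if (nrow(s) > 0) fp <- fp + 1L
    }
    expect_lte(fp / 100, 0.01)
  })
})

test_that("interval scan hits are a subset of whole-genome hits at equal thresholds", {
  with_seed(47, {
    prot <- random_aa(100)
    sc <- c(chr = paste0(random_nt(1000), synteloss:::backtranslate(prot),
                         random_nt(1000)))
    genome <- annotated_genome(sc, data.frame(
      id = "g", symbol = "g", scaffold = "chr", start = 0L, end = 10L,
      strand = "+", stringsAsFactors = FALSE))
    whole <- search_homology(c(q = prot), genome, scoring_scheme("protein"),
                             params = list(e_max = 1e-3, min_coverage = 0.3))
    iv <- list(scaffold = "chr", start = 900L, end = 1500L)
    inside <- scan_interval(genome, iv, c(q = prot),
                            params = list(pad = 0L))
    for (i in seq_len(nrow(inside))) {
      match_row <- whole$scaffold == inside$scaffold[i] &
        abs(whole$start - inside$start[i]) <= 3
      expect_true(any(match_row))
    }
  })
})
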