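make_tiny_panel <- function() {
  with_seed(61, {
    a <- random_aa(120)
    b <- synteloss:::mutate_protein(a, 0.3)   # recognizable paralog of a
    c_ <- random_aa(140)
    ortholog_panel(
      id = c("pyy_sp1", "pyy_sp2", "npy_sp1", "npy_sp2", "oth_sp1", "oth_sp2"),
      symbol = c("pyy", "pyy", "npy", "npy", "oth", "oth"),
      species = rep(c("sp1", "sp2"), 3),
      seq = c(a, synteloss:::mutate_protein(a, 0.1),
              b, synteloss:::mutate_protein(b, 0.1),
              c_, synteloss:::mutate_protein(c_, 0.1)))
  })
}

test_that("reciprocal check passes self and flags paralogs", {
  panel <- make_tiny_panel()
  self <- reciprocal_best_check(panel$seq[panel$id == "pyy_sp1"], panel, "pyy")
  expect_true(self$pass)
  expect_equal(self$ranked$symbol[1], "pyy")

  # with a tight distinct-symbol budget the paralog outranks the query gene
  par <- reciprocal_best_check(panel$seq[panel$id == "npy_sp1"], panel, "pyy",
                               top_n = 1)
  expect_false(par$pass)
  expect_equal(par$paralog_note, "npy")

  none <- reciprocal_best_check("", panel, "pyy")
  expect_false(none$pass)
  expect_equal(none$reason, "no_panel_hit")
})

test_that("a target identical to the reference is called present throughout", {
  cfg <- sim_config(seed = 21, n_scaffolds = 2, genes_per_scaffold = 6,
                    divergence = 0, indel_rate = 0, n_losses = 0,
                    n_paralog_duplications = 0, n_inversions = 0)
  sp <- generate_pair(cfg)
  calls <- classify_panel(sp$truth$id, sp$queries, sp$reference, sp$target,
                          sp$panel)
  expect_true(all(calls$status == "present"))
})

test_that("simulated losses are called absent and never present", {
  cfg <- sim_config(seed = 42, n_scaffolds = 4, genes_per_scaffold = 10,
                    divergence = 0.15, n_losses = 10,
                    n_paralog_duplications = 3, n_inversions = 1)
  sp <- generate_pair(cfg)
  calls <- classify_panel(sp$truth$id, sp$queries, sp$reference, sp$target,
                          sp$panel)
  m <- merge(calls, sp$truth[, c("id", "fate")], by.x = "symbol", by.y = "id")
  lost <- m[m$fate == "lost", ]
  expect_equal(nrow(lost), 10L)
  expect_true(all(lost$status == "absent"))
  expect_false(any(lost$status == "present"))
  kept <- m[m$fate != "lost", ]
  expect_gte(mean(kept$status == "present"), 0.9)
})

test_that("evidence chains justify every call", {
  cfg <- sim_config(seed = 42, n_scaffolds = 3, genes_per_scaffold = 8,
                    divergence = 0.15, n_losses = 4,
                    n_paralog_duplications = 2, n_inversions = 1)
  sp <- generate_pair(cfg)
  calls <- classify_panel(sp$truth$id, sp$queries, sp$reference, sp$target,
                          sp$panel)
  for (call in attr(calls, "calls")) {
    steps <- vapply(call$evidence, `[[`, "", "step")
    outcomes <- vapply(call$evidence, `[[`, "", "outcome")
    if (call$status == "present") {
      expect_true(any(grepl("^reciprocal_", steps) & outcomes == "pass"),
                  info = call$symbol)
    }
    if (call$status == "absent") {
      via_scan <- any(steps == "anchor_flanks" & outcomes == "both_flanks") &&
        any(steps == "interval_scan" & outcomes == "empty")
      via_paralog <- !is.na(call$paralog_note)
      expect_true(via_scan || via_paralog, info = call$symbol)
    }
  }
})

test_that("tightening e_max never flips a call toward present", {
  cfg <- sim_config(seed = 13, n_scaffolds = 3, genes_per_scaffold = 8,
                    divergence = 0.15, n_losses = 3,
                    n_paralog_duplications = 1, n_inversions = 1)
  sp <- generate_pair(cfg)
  loose <- classify_panel(sp$truth$id, sp$queries, sp$reference, sp$target,
                          sp$panel, params = list(e_max = 1e-10))
  tight <- classify_panel(sp$truth$id, sp$queries, sp$reference, sp$target,
                          sp$panel, params = list(e_max = 1e-60))
  for (i in seq_len(nrow(loose))) {
    if (loose$status[i] == "absent") {
      expect_false(tight$status[i] == "present", info = loose$symbol[i])
    }
  }
})

test_that("classify_panel handles empty input and per-gene errors", {
  cfg <- sim_config(seed = 21, n_scaffolds = 2, genes_per_scaffold = 6,
                    divergence = 0, n_losses = 0,
                    n_paralog_duplications = 0, n_inversions = 0)
  sp <- generate_pair(cfg)
  empty <- classify_panel(character(0), NULL, sp$reference, sp$target,
                          sp$panel)
  expect_equal(nrow(empty), 0L)

  mixed <- classify_panel(c("g0001", "no_such_gene"), sp$queries,
                          sp$reference, sp$target, sp$panel)
  expect_equal(mixed$status[mixed$symbol == "g0001"], "present")
  expect_equal(mixed$status[mixed$symbol == "no_such_gene"], "error")
})

test_that("transcript evidence rescues present but never proves absence", {
  cfg <- sim_config(seed = 33, n_scaffolds = 2, genes_per_scaffold = 6,
                    divergence = 0.1, indel_rate = 0, n_losses = 1,
                    n_paralog_duplications = 0, n_inversions = 0)
  sp <- generate_pair(cfg)
  lost_id <- sp$truth$id[sp$truth$fate == "lost"]
  kept_id <- sp$truth$id[sp$truth$fate == "kept"][1]

  # target genome stripped of the kept gene's scaffold would lose the hit;
  # instead, present a transcriptome carrying the kept gene and a target
  # where that gene's body is masked
  masked <- drop_gene(sp$target, kept_id)
  tx <- setNames(extract_cds(sp$target, kept_id), "t1")
  call <- classify_gene(kept_id, sp$queries[[kept_id]], sp$reference, masked,
                        sp$panel, transcriptome = tx)
  expect_equal(call$status, "present")
  expect_equal(call$locus$source, "transcriptome")

  # the lost gene has no transcript; absence must come from the genome side
  call2 <- classify_gene(lost_id, sp$queries[[lost_id]], sp$reference,
                         sp$target, sp$panel, transcriptome = tx)
  expect_equal(call2$status, "absent")
})
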