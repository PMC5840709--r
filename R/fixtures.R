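random_protein <- function(n) {
  paste(c("M", sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n - 1L,
                      replace = TRUE)), collapse = "")
}

#' Deterministic gene-neighborhood fixture bundle
#'
#' Builds the miniature reference/target genome pair that encodes, at the
#' gene-symbol level, the neighborhoods the agastric-fish gene-loss
#' comparison rests on: a reference species carrying `ghrl` between
#' `ccdc174` and `tatdn2` with a wrasse-like target retaining both flanks
#' but no `ghrl`; target loci for `ghsrb`, `mln`, `mlnr` (next to
#' `fndc3a`), `pyya`, `pyyb`, `ccka`, `cckb`, `npy`, `pomc`, `lep`,
#' `muc5ac` (next to `muc2`), `tcn2` and `tcnl` (next to `abcg4`); and
#' deleted target loci for `mboat4`, `gif`, `tcn1` and the stomach genes
#' (`pga`, `atp4a`, `atp4b`, `gast`, `lipf`, `tff1`, `pgc`). The panel
#' carries related paralog families (`npy` vs `pyya`/`pyyb`; `ccka`/`cckb`;
#' `tcn1`/`tcn2`/`tcnl`) to exercise paralog disambiguation, and a
#' separate one-locus target carrying only `npy` for the pyy-query
#' discrimination case.
#'
#' All sequences are synthetic placeholders generated under a fixed internal
#' seed - the symbol-level structure, not the sequence content, is what the
#' fixtures encode - so the bundle is byte-stable across runs and
#' independent of the caller's RNG state. `ghsrb` is the canonical symbol
#' for the ghrelin-receptor family (alias `ghsr`); `mln` for motilin
#' (alias `mnl`).
#'
#' @return list of class `fig1_fixtures`: `ref` and `target`
#'   (`annotated_genome`s), `panel` (`ortholog_panel`), `queries` (named
#'   protein vector, one canonical symbol per family), `expected`
#'   (data.frame of symbol and expected status), `npy_only_target`
#'   (one-locus `annotated_genome`), `aliases`.
#' @export
build_fig1_fixtures <- function() {
  with_seed(20160104L, {
    ct <- .codon_table()

    prot <- list()
    # NPY/PYY peptide family: paralogs recognizably related
    base_pyy <- random_protein(96)
    prot$pyya <- mutate_protein(base_pyy, 0.08)
    prot$pyyb <- mutate_protein(base_pyy, 0.16)
    prot$npy <- mutate_protein(base_pyy, 0.30)
    # cholecystokinin paralogs
    base_cck <- random_protein(120)
    prot$ccka <- mutate_protein(base_cck, 0.08)
    prot$cckb <- mutate_protein(base_cck, 0.18)
    # transcobalamin family: tcn1 absent but related to tcn2/tcnl
    base_tcn <- random_protein(190)
    prot$tcn1 <- mutate_protein(base_tcn, 0.12)
    prot$tcn2 <- mutate_protein(base_tcn, 0.22)
    prot$tcnl <- mutate_protein(base_tcn, 0.30)
    # unrelated families
    singles <- c(ghrl = 105, mboat4 = 200, ghsrb = 180, mln = 110,
                 mlnr = 190, pomc = 160, lep = 140, muc5ac = 240,
                 gif = 170, pga = 185, atp4a = 210, atp4b = 150,
                 gast = 100, lipf = 190, tff1 = 80, pgc = 185)
    for (s in names(singles)) prot[[s]] <- random_protein(singles[[s]])

    # region layouts: focal gene with its flanking symbols; named neighbors
    # from the published comparisons, otherwise generic fillers
    nb <- function(sym, i) paste0(sym, "nb", i)
    region <- function(sym, upstream = c(nb(sym, 1), nb(sym, 2)),
                       downstream = c(nb(sym, 3), nb(sym, 4)),
                       lost = FALSE) {
      list(sym = sym, order = c(upstream, sym, downstream), lost = lost)
    }
    regions <- list(
      region("ghrl", upstream = "ccdc174",
             downstream = c("tatdn2", nb("ghrl", 1), nb("ghrl", 2)),
             lost = TRUE),
      region("mboat4", lost = TRUE),
      region("gif", lost = TRUE),
      region("tcn1", lost = TRUE),
      region("pga", lost = TRUE),
      region("atp4a", lost = TRUE),
      region("atp4b", lost = TRUE),
      region("gast", lost = TRUE),
      region("lipf", lost = TRUE),
      region("tff1", lost = TRUE),
      region("pgc", lost = TRUE),
      region("muc5ac", upstream = c(nb("muc5ac", 1), "muc2")),
      region("ghsrb"),
      region("mln"),
      region("mlnr", upstream = c(nb("mlnr", 1), "fndc3a")),
      region("pyya"),
      region("pyyb"),
      region("npy"),
      region("ccka"),
      region("cckb"),
      region("tcn2"),
      region("tcnl", upstream = c(nb("tcnl", 1), "abcg4")),
      region("pomc"),
      region("lep"))

    # proteins for every neighbor symbol
    all_syms <- c(unique(unlist(lapply(regions, `[[`, "order"))),
                  "npyonlynb1", "npyonlynb2")
    for (s in setdiff(all_syms, names(prot))) {
      prot[[s]] <- random_protein(sample(100:220, 1L))
    }

    build_scaffold <- function(order, prefix) {
      genes <- lapply(order, function(s) {
        list(id = paste0(prefix, "_", s), symbol = s,
             cds = backtranslate(prot[[s]], ct),
             strand = sample(c("+", "-"), 1L))
      })
      gaps <- vapply(seq_len(length(order) + 1L),
                     function(i) random_dna(sample(300:800, 1L)), character(1))
      list(gaps = gaps, genes = genes)
    }

    ref_plan <- list()
    tgt_plan <- list()
    for (r in regions) {
      ref_plan[[paste0("ref_", r$sym)]] <- build_scaffold(r$order, "ref")
      tord <- if (r$lost) setdiff(r$order, r$sym) else r$order
      tgt_plan[[paste0("wra_", r$sym)]] <- build_scaffold(tord, "wra")
    }
    ref <- .plan_to_genome(ref_plan)
    target <- .plan_to_genome(tgt_plan)

    # one-locus target for the pyy-query paralog case: only an npy locus
    npy_only <- .plan_to_genome(list(
      npyonly_sc = build_scaffold(c("npyonlynb1", "npy", "npyonlynb2"),
                                  "npyonly")))

    syms <- names(prot)
    panel <- ortholog_panel(
      id = c(paste0(syms, "_ref"), paste0(syms, "_out")),
      symbol = c(syms, syms),
      species = c(rep("refspecies", length(syms)),
                  rep("outgroup", length(syms))),
      seq = c(unlist(prot), vapply(prot, mutate_protein, character(1),
                                   rate = 0.2)))

    families <- vapply(regions, `[[`, "", "sym")
    queries <- setNames(vapply(families, function(s) prot[[s]], character(1)),
                        families)
    expected <- data.frame(
      symbol = families,
      status = ifelse(vapply(regions, `[[`, logical(1), "lost"),
                      "absent", "present"),
      stringsAsFactors = FALSE)

    structure(list(ref = ref, target = target, panel = panel,
                   queries = queries, expected = expected,
                   npy_only_target = npy_only,
                   aliases = c(ghsrb = "ghsr", mln = "mnl")),
              class = "fig1_fixtures")
  })
}
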