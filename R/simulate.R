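#' Evaluate code under a fixed RNG seed, restoring the RNG state after
#'
#' @param seed integer seed.
#' @param code expression.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n, gc = 0.45) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# ATG + (n_codons - 2) random non-stop codons + stop
random_cds <- function(n_codons, gc = 0.45) {
  stopifnot(n_codons >= 3L)
  body <- character(n_codons - 2L)
  for (i in seq_along(body)) {
    repeat {
      cod <- random_dna(3L, gc)
      if (!cod %in% STOP_CODONS) break
    }
    body[i] <- cod
  }
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1L))
}

# codon-aware divergence: two-thirds of substitutions at third codon
# positions (mostly synonymous), start/stop codons untouched, substitutions
# that would create an in-frame stop are redirected
diverge_cds <- function(cds, d) {
  L <- nchar(cds)
  if (d <= 0 || L < 9L) return(cds)
  n_sub <- rbinom(1L, L, d)
  if (n_sub == 0L) return(cds)
  chars <- strsplit(cds, "")[[1]]
  internal <- 4:(L - 3L)
  thirds <- internal[internal %% 3L == 0L]
  others <- setdiff(internal, thirds)
  n3 <- min(round(2 / 3 * n_sub), length(thirds))
  n12 <- min(n_sub - n3, length(others))
  pos <- c(if (n3 > 0) sample(thirds, n3),
           if (n12 > 0) sample(others, n12))
  for (p in pos) {
    ci <- ((p - 1L) %/% 3L) * 3L + 1L
    alts <- setdiff(c("A", "C", "G", "T"), chars[p])
    alts <- sample(alts)
    for (b in alts) {
      codon <- chars[ci:(ci + 2L)]
      codon[p - ci + 1L] <- b
      if (!paste(codon, collapse = "") %in% STOP_CODONS) {
        chars[p] <- b
        break
      }
    }
  }
  paste(chars, collapse = "")
}

# neutral divergence with small indels, for intergenic sequence
diverge_dna <- function(seq, d, indel_rate = 0) {
  L <- nchar(seq)
  if (L == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  if (d > 0) {
    hit <- which(stats::runif(L) < d)
    for (p in hit) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  if (indel_rate > 0) {
    n_ind <- rbinom(1L, L, indel_rate)
    for (i in seq_len(n_ind)) {
      if (length(chars) < 12L) break
      len <- sample(1:6, 1L)
      pos <- sample(length(chars) - len, 1L)
      if (stats::runif(1) < 0.5) {
        chars <- chars[-(pos:(pos + len - 1L))]
      } else {
        ins <- strsplit(random_dna(len), "")[[1]]
        chars <- append(chars, ins, after = pos)
      }
    }
  }
  paste(chars, collapse = "")
}

protein_from_cds <- function(cds) sub("\\*$", "", translate_nt(cds))

mutate_protein <- function(aa, rate) {
  if (rate <= 0) return(aa)
  chars <- strsplit(aa, "")[[1]]
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (p in hit) chars[p] <- sample(setdiff(aas, chars[p]), 1L)
  paste(chars, collapse = "")
}

.codon_table <- function() {
  code <- Biostrings::GENETIC_CODE
  split(names(code), unname(code))
}

backtranslate <- function(aa, codon_table = .codon_table()) {
  chars <- strsplit(aa, "")[[1]]
  codons <- vapply(chars, function(a) {
    cands <- codon_table[[a]]
    if (is.null(cands)) stop("cannot back-translate residue ", a)
    cands <- setdiff(cands, STOP_CODONS)
    cands[sample.int(length(cands), 1L)]
  }, character(1))
  paste0("ATG", paste(codons, collapse = ""), sample(STOP_CODONS, 1L))
}

#' Simulation configuration for a reference/target genome pair
#'
#' Defines the study conditions the generator emulates: ortholog families in
#' conserved gene orders shared by a reference and a target genome, with a
#' known subset of genes deleted in the target (flanks always retained),
#' paralogous duplicates at unlinked loci, per-gene codon-aware sequence
#' divergence, and local gene-order inversions.
#'
#' @param seed RNG seed; identical configs and seeds give byte-identical
#'   written outputs.
#' @param n_scaffolds,genes_per_scaffold genome shape.
#' @param cds_codons_range CDS length range in codons (incl. start/stop).
#' @param intergenic_range intergenic gap length range in bp.
#' @param gc GC content of generated sequence.
#' @param divergence per-site substitution probability between reference and
#'   target (codon-aware in CDS: two-thirds of substitutions at third codon
#'   positions).
#' @param indel_rate per-site indel initiation probability, applied to
#'   intergenic sequence only so reading frames stay intact.
#' @param n_losses genes deleted in the target (never at scaffold ends,
#'   never adjacent to each other).
#' @param n_paralog_duplications diverged gene copies inserted on another
#'   scaffold.
#' @param n_inversions inverted blocks of 2-4 contiguous genes.
#' @param duplicate_extra_divergence extra substitution probability applied
#'   to duplicate copies.
#' @param outgroup_divergence divergence of the third, outgroup panel copy
#'   per family.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_scaffolds = 5L, genes_per_scaffold = 20L,
                       cds_codons_range = c(100L, 300L),
                       intergenic_range = c(200L, 800L), gc = 0.45,
                       divergence = 0.15, indel_rate = 0.02,
                       n_losses = 10L, n_paralog_duplications = 5L,
                       n_inversions = 3L,
                       duplicate_extra_divergence = 0.1,
                       outgroup_divergence = 0.15) {
  stopifnot(divergence >= 0, divergence <= 0.5, n_losses >= 0,
            n_paralog_duplications >= 0, n_inversions >= 0,
            n_scaffolds >= 1, genes_per_scaffold >= 3,
            cds_codons_range[1] >= 10, intergenic_range[1] >= 50)
  total <- n_scaffolds * genes_per_scaffold
  if (n_losses > total - 2L * n_scaffolds) {
    stop("infeasible config: n_losses exceeds eligible interior genes")
  }
  structure(list(seed = seed, n_scaffolds = n_scaffolds,
                 genes_per_scaffold = genes_per_scaffold,
                 cds_codons_range = cds_codons_range,
                 intergenic_range = intergenic_range, gc = gc,
                 divergence = divergence, indel_rate = indel_rate,
                 n_losses = n_losses,
                 n_paralog_duplications = n_paralog_duplications,
                 n_inversions = n_inversions,
                 duplicate_extra_divergence = duplicate_extra_divergence,
                 outgroup_divergence = outgroup_divergence),
            class = "sim_config")
}

# assemble an annotated_genome from a per-scaffold plan of alternating
# gaps and genes: plan[[sc]] = list(gaps = chr[n+1], genes = list of
# list(id, symbol, cds, strand))
.plan_to_genome <- function(plan) {
  scaffolds <- character(0)
  grows <- list()
  crows <- list()
  for (sc in names(plan)) {
    pl <- plan[[sc]]
    pos <- 0L
    parts <- character(0)
    push <- function(s) {
      parts[[length(parts) + 1L]] <<- s
      pos <<- pos + nchar(s)
    }
    push(pl$gaps[1L])
    for (j in seq_along(pl$genes)) {
      g <- pl$genes[[j]]
      body <- if (g$strand == "+") g$cds else revcomp(g$cds)
      start <- pos
      push(body)
      grows[[length(grows) + 1L]] <- data.frame(
        id = g$id, symbol = g$symbol, scaffold = sc, start = start,
        end = pos, strand = g$strand, stringsAsFactors = FALSE)
      crows[[length(crows) + 1L]] <- data.frame(
        gene_id = g$id, start = start, end = pos, stringsAsFactors = FALSE)
      push(pl$gaps[j + 1L])
    }
    scaffolds[sc] <- paste(parts, collapse = "")
  }
  annotated_genome(scaffolds, do.call(rbind, grows), do.call(rbind, crows))
}

#' Generate a reference/target annotated-genome pair with ground truth
#'
#' Builds a reference genome gene-by-gene (symbols `g0001`, `g0002`, ...),
#' derives the target by codon-aware divergence, then gene losses (gene body
#' removed, intergenic gap retained), paralog duplications (extra-diverged
#' copy appended to another scaffold), and inversions of 2-4 gene blocks.
#' Event gene sets are disjoint and never touch a lost gene's flanks, so
#' every lost gene's expected candidate interval (the gap between its
#' surviving neighbors, recorded in the ground truth) is well defined.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_pair`: `reference` and `target`
#'   (`annotated_genome`s), `panel` (reference + outgroup proteins per
#'   family), `queries` (named reference proteins), `truth` (per-gene fate
#'   table with expected intervals for losses), `config`.
#' @export
generate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ct <- .codon_table()
  nsc <- config$n_scaffolds
  npg <- config$genes_per_scaffold
  scnames <- sprintf("ref_scaffold_%02d", seq_len(nsc))

  ref_plan <- list()
  gid <- 0L
  for (sc in scnames) {
    gaps <- vapply(seq_len(npg + 1L), function(i)
      random_dna(sample(config$intergenic_range[1]:config$intergenic_range[2], 1L),
                 config$gc), character(1))
    genes <- lapply(seq_len(npg), function(j) {
      gid <<- gid + 1L
      nc <- sample(config$cds_codons_range[1]:config$cds_codons_range[2], 1L)
      list(id = sprintf("g%04d", gid), symbol = sprintf("g%04d", gid),
           cds = random_cds(nc, config$gc),
           strand = sample(c("+", "-"), 1L))
    })
    ref_plan[[sc]] <- list(gaps = gaps, genes = genes)
  }
  reference <- .plan_to_genome(ref_plan)

  # target plan: divergence first
  tgt_plan <- ref_plan
  names(tgt_plan) <- sub("^ref_", "tgt_", names(tgt_plan))
  for (sc in names(tgt_plan)) {
    tgt_plan[[sc]]$gaps <- vapply(tgt_plan[[sc]]$gaps, diverge_dna,
                                  character(1), d = config$divergence,
                                  indel_rate = config$indel_rate,
                                  USE.NAMES = FALSE)
    tgt_plan[[sc]]$genes <- lapply(tgt_plan[[sc]]$genes, function(g) {
      g$cds <- diverge_cds(g$cds, config$divergence)
      g
    })
  }

  # event gene selection on (scaffold index, gene index) coordinates
  all_pos <- do.call(rbind, lapply(seq_len(nsc), function(s)
    data.frame(s = s, j = seq_len(npg))))
  all_pos$id <- vapply(seq_len(nrow(all_pos)), function(i)
    ref_plan[[scnames[all_pos$s[i]]]]$genes[[all_pos$j[i]]]$id, character(1))
  interior <- all_pos[all_pos$j > 1L & all_pos$j < npg, ]

  pick_losses <- function() {
    if (config$n_losses == 0L) return(interior[0, ])
    cand <- interior[sample.int(nrow(interior)), ]
    taken <- cand[0, ]
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, ]
      adj <- taken$s == r$s & abs(taken$j - r$j) <= 1L
      if (!any(adj)) taken <- rbind(taken, r)
      if (nrow(taken) == config$n_losses) break
    }
    taken
  }
  losses <- pick_losses()
  if (nrow(losses) < config$n_losses) {
    stop("infeasible config: could not place non-adjacent losses")
  }
  lost_ids <- losses$id
  near_lost <- function(s, j) any(losses$s == s & abs(losses$j - j) <= 1L)

  free <- all_pos[!all_pos$id %in% lost_ids, ]
  dup_pool <- free[!vapply(seq_len(nrow(free)), function(i)
    near_lost(free$s[i], free$j[i]), logical(1)), ]
  if (nrow(dup_pool) < config$n_paralog_duplications) {
    stop("infeasible config: not enough genes for duplications")
  }
  dups <- dup_pool[sample.int(nrow(dup_pool), config$n_paralog_duplications), ]

  # inversion blocks: contiguous interior runs of kept, non-dup genes not
  # adjacent to any lost gene
  inv_blocks <- list()
  used <- c(lost_ids, dups$id)
  for (b in seq_len(config$n_inversions)) {
    placed <- FALSE
    for (try in seq_len(200L)) {
      len <- sample(2:4, 1L)
      s <- sample.int(nsc, 1L)
      if (npg - len < 2L) next
      j1 <- sample(2:(npg - len), 1L)
      js <- j1:(j1 + len - 1L)
      ids <- vapply(js, function(j) ref_plan[[scnames[s]]]$genes[[j]]$id,
                    character(1))
      if (any(ids %in% used)) next
      if (any(vapply(js, function(j) near_lost(s, j), logical(1)))) next
      inv_blocks[[b]] <- list(s = s, js = js, ids = ids)
      used <- c(used, ids)
      placed <- TRUE
      break
    }
    if (!placed) stop("infeasible config: could not place inversion blocks")
  }
  inverted_ids <- unlist(lapply(inv_blocks, `[[`, "ids"))

  # apply inversions: reverse gene order, flip strands, reverse-complement
  # and reverse the inner gaps
  for (bl in inv_blocks) {
    sc <- names(tgt_plan)[bl$s]
    pl <- tgt_plan[[sc]]
    js <- bl$js
    genes <- pl$genes[js]
    genes <- rev(lapply(genes, function(g) {
      g$strand <- if (g$strand == "+") "-" else "+"
      g
    }))
    pl$genes[js] <- genes
    inner <- (js[1] + 1L):js[length(js)]
    pl$gaps[inner] <- rev(vapply(pl$gaps[inner], revcomp, character(1),
                                 USE.NAMES = FALSE))
    tgt_plan[[sc]] <- pl
  }

  # apply losses: drop gene, merge its flanking gaps (gap content retained)
  loss_neighbors <- list()
  for (i in seq_len(nrow(losses))) {
    s <- losses$s[i]; j <- losses$j[i]
    sc <- names(tgt_plan)[s]
    ids <- vapply(ref_plan[[scnames[s]]]$genes, `[[`, "", "id")
    loss_neighbors[[losses$id[i]]] <- list(prev = ids[j - 1L], nxt = ids[j + 1L])
  }
  for (s in seq_len(nsc)) {
    sc <- names(tgt_plan)[s]
    pl <- tgt_plan[[sc]]
    drop_j <- sort(losses$j[losses$s == s], decreasing = TRUE)
    for (j in drop_j) {
      pl$genes[[j]] <- NULL
      pl$gaps[j] <- paste0(pl$gaps[j], pl$gaps[j + 1L])
      pl$gaps <- pl$gaps[-(j + 1L)]
    }
    tgt_plan[[sc]] <- pl
  }

  # duplications: extra-diverged copy appended to a different scaffold
  dup_ids <- character(0)
  for (i in seq_len(nrow(dups))) {
    src_sc <- scnames[dups$s[i]]
    src <- ref_plan[[src_sc]]$genes[[dups$j[i]]]
    tgt_sc_i <- if (nsc > 1L) sample(setdiff(seq_len(nsc), dups$s[i]), 1L) else 1L
    sc <- names(tgt_plan)[tgt_sc_i]
    copy <- src
    copy$id <- paste0(src$id, "_dup")
    copy$cds <- diverge_cds(diverge_cds(src$cds, config$divergence),
                            config$duplicate_extra_divergence)
    copy$strand <- sample(c("+", "-"), 1L)
    pl <- tgt_plan[[sc]]
    pl$genes[[length(pl$genes) + 1L]] <- copy
    pl$gaps <- c(pl$gaps, random_dna(
      sample(config$intergenic_range[1]:config$intergenic_range[2], 1L),
      config$gc))
    tgt_plan[[sc]] <- pl
    dup_ids <- c(dup_ids, src$id)
  }

  target <- .plan_to_genome(tgt_plan)

  # ground truth with expected candidate intervals for losses
  fate <- setNames(rep("kept", nrow(all_pos)), all_pos$id)
  fate[inverted_ids] <- "inverted"
  fate[dup_ids] <- "duplicated"
  fate[lost_ids] <- "lost"
  tg <- target$genes
  truth <- data.frame(id = all_pos$id, symbol = all_pos$id,
                      fate = unname(fate[all_pos$id]),
                      dup_id = ifelse(all_pos$id %in% dup_ids,
                                      paste0(all_pos$id, "_dup"), NA_character_),
                      interval_scaffold = NA_character_,
                      interval_start = NA_integer_,
                      interval_end = NA_integer_, stringsAsFactors = FALSE)
  for (lid in lost_ids) {
    nb <- loss_neighbors[[lid]]
    pi <- match(nb$prev, tg$id)
    ni <- match(nb$nxt, tg$id)
    k <- match(lid, truth$id)
    truth$interval_scaffold[k] <- tg$scaffold[pi]
    truth$interval_start[k] <- tg$end[pi]
    truth$interval_end[k] <- tg$start[ni]
  }
  truth <- truth[order(truth$id), ]
  rownames(truth) <- NULL

  # ortholog panel: reference proteins plus a diverged outgroup copy
  ref_genes <- unlist(lapply(ref_plan, `[[`, "genes"), recursive = FALSE)
  prots <- vapply(ref_genes, function(g) protein_from_cds(g$cds), character(1))
  syms <- vapply(ref_genes, `[[`, "", "symbol")
  out_prots <- vapply(ref_genes, function(g)
    protein_from_cds(diverge_cds(g$cds, config$outgroup_divergence)),
    character(1))
  panel <- ortholog_panel(
    id = c(paste0(syms, "_ref"), paste0(syms, "_out")),
    symbol = c(syms, syms),
    species = c(rep("refspecies", length(syms)),
                rep("outgroup", length(syms))),
    seq = c(prots, out_prots))
  queries <- setNames(prots, syms)

  structure(list(reference = reference, target = target, panel = panel,
                 queries = queries, truth = truth, config = config),
            class = "sim_pair")
}

#' @export
print.sim_pair <- function(x, ...) {
  cat(sprintf(paste0("sim_pair (seed %s): %d reference genes; target: %d ",
                     "lost, %d duplicated, %d inverted\n"),
              x$config$seed, nrow(x$reference$genes),
              sum(x$truth$fate == "lost"), sum(x$truth$fate == "duplicated"),
              sum(x$truth$fate == "inverted")))
  invisible(x)
}

#' Write a simulated pair to disk
#'
#' Writes `ref.fa`, `ref.gff3`, `target.fa`, `target.gff3`, `panel.faa`,
#' `truth.tsv` and a `manifest.json` carrying the configuration, seed and
#' MD5 of every file. Identical configs and seeds produce byte-identical
#' files.
#'
#' @param pair a `sim_pair`.
#' @param dir output directory (created if needed).
#' @return named character vector of file MD5 sums, invisibly.
#' @export
write_sim_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "sim_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(dir, x)
  write_fasta(pair$reference$scaffolds, f("ref.fa"))
  write_gff3(pair$reference, f("ref.gff3"))
  write_fasta(pair$target$scaffolds, f("target.fa"))
  write_gff3(pair$target, f("target.gff3"))
  write_panel_fasta(pair$panel, f("panel.faa"))
  utils::write.table(pair$truth, f("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c("ref.fa", "ref.gff3", "target.fa", "target.gff3", "panel.faa",
             "truth.tsv")
  sums <- tools::md5sum(vapply(files, f, character(1)))
  names(sums) <- files
  manifest <- list(config = unclass(pair$config), md5 = as.list(sums))
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(sums)
}

#' Negative-binomial segment-count simulation configuration
#'
#' Emulates the transcriptional profiling design: four sequential gut
#' segments with six biological replicates each, per-gene log-normal
#' baseline expression, and a configurable fraction of genes carrying a
#' multiplicative anterior-to-posterior gradient.
#'
#' @param seed RNG seed.
#' @param n_genes number of genes.
#' @param n_segments ordered segments (default 4).
#' @param samples_per_segment replicates per segment (default 6).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   0 gives Poisson counts.
#' @param frac_declining,frac_increasing fraction of genes with a declining
#'   (anterior-high) or increasing gradient.
#' @param fold_range total first-to-last segment fold of gradient genes.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline FPKM.
#' @param libsize_range per-sample library size range.
#' @param length_range gene length range in bp.
#' @return object of class `counts_config`.
#' @export
counts_config <- function(seed = 1L, n_genes = 2000L, n_segments = 4L,
                          samples_per_segment = 6L, dispersion = 0.1,
                          frac_declining = 0.3, frac_increasing = 0.05,
                          fold_range = c(4, 16),
                          baseline_meanlog = log(50), baseline_sdlog = 1.2,
                          libsize_range = c(8e5, 1.2e6),
                          length_range = c(500L, 5000L)) {
  stopifnot(frac_declining >= 0, frac_increasing >= 0,
            frac_declining + frac_increasing <= 1, dispersion >= 0,
            n_segments >= 3, samples_per_segment >= 1)
  structure(list(seed = seed, n_genes = n_genes, n_segments = n_segments,
                 samples_per_segment = samples_per_segment,
                 dispersion = dispersion, frac_declining = frac_declining,
                 frac_increasing = frac_increasing, fold_range = fold_range,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 libsize_range = libsize_range, length_range = length_range),
            class = "counts_config")
}

#' Simulate segment-ordered RNA-seq counts with ground truth
#'
#' Gradient genes receive per-segment multiplicative factors
#' `fold^(-(t-1)/(S-1))` (declining) or its mirror; counts are drawn
#' negative-binomially around `FPKM * length * library_size / 1e9`.
#'
#' @param config a [counts_config()].
#' @return list of class `sim_counts`: `em` (an [expr_matrix()]), `truth`
#'   (data.frame gene/class/fold), `config`.
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "counts_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  S <- config$n_segments
  nps <- config$samples_per_segment
  genes <- sprintf("gene%05d", seq_len(ng))
  segs <- paste0("S", seq_len(S))
  segments <- rep(segs, each = nps)
  samples <- paste0(rep(segs, each = nps), "_r", rep(seq_len(nps), S))

  n_dec <- round(config$frac_declining * ng)
  n_inc <- round(config$frac_increasing * ng)
  cls <- rep("none", ng)
  if (n_dec > 0) cls[seq_len(n_dec)] <- "declining"
  if (n_inc > 0) cls[n_dec + seq_len(n_inc)] <- "increasing"

  base_fpkm <- rlnorm(ng, config$baseline_meanlog, config$baseline_sdlog)
  fold <- ifelse(cls == "none", 1,
                 runif(ng, config$fold_range[1], config$fold_range[2]))
  lens <- sample(config$length_range[1]:config$length_range[2], ng,
                 replace = TRUE)
  libs <- round(runif(S * nps, config$libsize_range[1], config$libsize_range[2]))

  # per-gene, per-segment expected FPKM
  tfrac <- (seq_len(S) - 1) / (S - 1)
  factors <- matrix(1, ng, S)
  dec <- cls == "declining"
  inc <- cls == "increasing"
  if (any(dec)) factors[dec, ] <- outer(fold[dec], tfrac, function(f, t) f^(-t))
  if (any(inc)) factors[inc, ] <- outer(fold[inc], tfrac, function(f, t) f^(t - 1))
  mu_fpkm <- base_fpkm * factors

  counts <- matrix(0L, ng, S * nps, dimnames = list(genes, samples))
  for (k in seq_len(S * nps)) {
    seg_i <- match(segments[k], segs)
    mu <- mu_fpkm[, seg_i] * lens * libs[k] / 1e9
    counts[, k] <- if (config$dispersion > 0) {
      rnbinom(ng, mu = mu, size = 1 / config$dispersion)
    } else {
      stats::rpois(ng, mu)
    }
  }
  em <- expr_matrix(counts, segments, setNames(lens, genes), seg_levels = segs)
  truth <- data.frame(gene = genes, class = cls, fold = fold,
                      stringsAsFactors = FALSE)
  structure(list(em = em, truth = truth, config = config),
            class = "sim_counts")
}
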