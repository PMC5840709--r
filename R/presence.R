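#' Construct an ortholog protein panel
#'
#' A multi-species, symbol-tagged protein set standing in for the
#' non-redundant protein database of the reciprocal search step. Symbols
#' form families: the same symbol appearing for multiple species.
#'
#' @param id,symbol,species,seq equal-length character vectors.
#' @return object of class `ortholog_panel` (a data.frame).
#' @export
ortholog_panel <- function(id, symbol, species, seq) {
  stopifnot(length(id) == length(symbol), length(id) == length(species),
            length(id) == length(seq), all(nzchar(symbol)),
            all(nzchar(species)))
  if (anyDuplicated(id)) stop("duplicated panel record id(s)")
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", toupper(seq))
  if (any(bad)) stop("panel sequence(s) outside amino-acid alphabet: ",
                     paste(id[bad], collapse = ", "))
  structure(data.frame(id = id, symbol = symbol, species = species,
                       seq = toupper(seq), stringsAsFactors = FALSE),
            class = c("ortholog_panel", "data.frame"))
}

#' Write / read an ortholog panel as protein FASTA
#'
#' Headers carry the id, symbol and species as whitespace-separated fields:
#' `>id symbol species`.
#'
#' @param panel an `ortholog_panel`.
#' @param path FASTA path.
#' @return `write_panel_fasta`: `path` invisibly; `read_panel_fasta`: an
#'   `ortholog_panel`.
#' @export
write_panel_fasta <- function(panel, path) {
  seqs <- panel$seq
  names(seqs) <- paste(panel$id, panel$symbol, panel$species)
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' @rdname write_panel_fasta
#' @export
read_panel_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  parts <- strsplit(names(set), "\\s+")
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("panel FASTA header without 'id symbol species' fields")
  ortholog_panel(id = vapply(parts, `[`, "", 1L),
                 symbol = vapply(parts, `[`, "", 2L),
                 species = vapply(parts, `[`, "", 3L),
                 seq = as.character(set))
}

#' Reciprocal top-hit verification
#'
#' Searches a candidate sequence back against the ortholog panel and passes
#' only if the intended gene symbol is among the `top_n` distinct-symbol
#' hits - the step at which a strong but paralogous locus is unmasked. On
#' failure the best-ranked foreign symbol is reported as `paralog_note`.
#'
#' @param candidate_seq candidate amino-acid sequence (typically the
#'   translated aligned target region of a genome hit).
#' @param panel an `ortholog_panel`.
#' @param target_symbol the symbol the candidate is supposed to be.
#' @param scheme protein [scoring_scheme()].
#' @param top_n distinct symbols inspected.
#' @param e_max maximum panel-hit E-value considered at all.
#' @return list with `pass`, `ranked` (data.frame of panel hits in rank
#'   order), `paralog_note` (best foreign symbol on fail, else `NA`), and
#'   `reason` (`"rank"`, `"not_in_top"`, or `"no_panel_hit"`).
#' @export
reciprocal_best_check <- function(candidate_seq, panel, target_symbol,
                                  scheme = scoring_scheme("protein"),
                                  top_n = 5L, e_max = 1e-3) {
  stopifnot(inherits(panel, "ortholog_panel"), nrow(panel) > 0)
  candidate_seq <- toupper(candidate_seq)
  if (!nzchar(candidate_seq)) {
    return(list(pass = FALSE, ranked = NULL, paralog_note = NA_character_,
                reason = "no_panel_hit"))
  }
  raw <- sw_score_many_cpp(candidate_seq, panel$seq, scheme$matrix,
                           scheme$alphabet, scheme$gap_open, scheme$gap_extend)
  bits <- bit_score(raw, scheme)
  db_len <- sum(nchar(panel$seq))
  ev <- evalue(bits, nchar(candidate_seq), db_len)
  ord <- order(-bits, panel$symbol, panel$id)
  ranked <- data.frame(id = panel$id[ord], symbol = panel$symbol[ord],
                       species = panel$species[ord], raw_score = raw[ord],
                       bit_score = bits[ord], e_value = ev[ord],
                       stringsAsFactors = FALSE)
  ranked <- ranked[ranked$raw_score > 0 & ranked$e_value <= e_max, ,
                   drop = FALSE]
  if (!nrow(ranked)) {
    return(list(pass = FALSE, ranked = ranked, paralog_note = NA_character_,
                reason = "no_panel_hit"))
  }
  top_syms <- unique(toupper(ranked$symbol))[seq_len(min(top_n, length(unique(ranked$symbol))))]
  pass <- toupper(target_symbol) %in% top_syms
  note <- if (pass) NA_character_ else {
    foreign <- setdiff(top_syms, toupper(target_symbol))
    tolower(foreign[1])
  }
  list(pass = pass, ranked = ranked, paralog_note = note,
       reason = if (pass) "rank" else "not_in_top")
}

.presence_params <- function(params) {
  utils::modifyList(list(
    k = 4L, e_max = 1e-10, min_coverage = 0.5, max_candidates = 3L,
    top_n = 5L, reciprocal_e_max = 1e-3,
    theta = 0.3, min_shared = 2L, window = 5L,
    e_max_interval = 1e-3, scan_min_coverage = 0.3, pad = 2000L,
    anchor_e_max = 1e-10, anchor_min_coverage = 0.5), params)
}

#' Classify one query gene as present, absent or ambiguous
#'
#' The full decision tree: (1) seed-and-extend search of the query protein
#' against the target genome (and transcriptome, if given); (2) reciprocal
#' top-hit verification of each qualifying candidate against the ortholog
#' panel; (3) microsynteny validation of the best reciprocal-passing genome
#' hit against the reference neighborhood(s); (4) when no candidate
#' qualifies, flank anchoring and an interval scan - a gene is called absent
#' only when both flanks anchor and the intervening interval is empty, or
#' when every hit fails the reciprocal check as a recognizable paralog.
#' Anything else is ambiguous: an unanchorable interval never proves loss.
#'
#' A reciprocal pass on a transcript can rescue a present call even when the
#' genome hit is weak, but transcript absence alone never contributes to an
#' absent call (a gene can be present yet unexpressed).
#'
#' @param symbol the query gene symbol.
#' @param query_seq the query protein sequence (single string).
#' @param refs a single `annotated_genome` or list of them (reference
#'   species annotations used for neighborhoods).
#' @param target the target `annotated_genome`.
#' @param panel an `ortholog_panel`.
#' @param transcriptome optional named character vector of transcripts.
#' @param scheme protein [scoring_scheme()].
#' @param params overrides of the classifier defaults (see
#'   `.presence_params`): search `k`/`e_max`/`min_coverage`, reciprocal
#'   `top_n`, synteny acceptance `theta` (0.3) with `min_shared` (2) shared
#'   named genes, neighborhood `window` (5), interval-scan thresholds.
#' @param target_index,tx_index optional prebuilt translated seed indexes.
#' @return object of class `presence_call`: `symbol`, `status`
#'   (`"present"`, `"absent"`, `"ambiguous"`), `locus`, `paralog_note`,
#'   `max_synteny`, `evidence` (ordered step records), `params`.
#' @export
classify_gene <- function(symbol, query_seq, refs, target, panel,
                          transcriptome = NULL,
                          scheme = scoring_scheme("protein"),
                          params = list(), target_index = NULL,
                          tx_index = NULL) {
  if (is.null(query_seq) || !nzchar(query_seq)) {
    stop("missing query protein for ", symbol)
  }
  if (inherits(refs, "annotated_genome")) refs <- list(refs)
  p <- .presence_params(params)
  ev <- list()
  note <- function(step, outcome, ...) {
    ev[[length(ev) + 1L]] <<- list(step = step, outcome = outcome,
                                   metrics = list(...))
  }
  q <- list(id = symbol, seq = toupper(query_seq))
  sp <- list(k = p$k, e_max = p$e_max, min_coverage = p$min_coverage)

  ghits <- search_homology(q, target, scheme, params = sp, index = target_index)
  note("genome_search", if (nrow(ghits)) "hits" else "no_hit",
       n_hits = nrow(ghits),
       best_e = if (nrow(ghits)) ghits$e_value[1] else NA_real_)
  thits <- NULL
  if (!is.null(transcriptome) && length(transcriptome)) {
    thits <- search_homology(q, transcriptome, scheme, params = sp,
                             index = tx_index)
    note("transcriptome_search", if (nrow(thits)) "hits" else "no_hit",
         n_hits = nrow(thits))
  }

  finish <- function(status, locus = NULL, paralog_note = NA_character_,
                     max_synteny = NA_real_) {
    structure(list(symbol = symbol, status = status, locus = locus,
                   paralog_note = paralog_note, max_synteny = max_synteny,
                   evidence = ev, params = p),
              class = "presence_call")
  }

  run_reciprocal <- function(hits, source) {
    n <- min(nrow(hits), p$max_candidates)
    notes <- character(0)
    for (i in seq_len(n)) {
      rb <- reciprocal_best_check(hits$target_aln[i], panel, symbol, scheme,
                                  top_n = p$top_n, e_max = p$reciprocal_e_max)
      note(paste0("reciprocal_", source), if (rb$pass) "pass" else "fail",
           candidate = i, reason = rb$reason,
           paralog_note = rb$paralog_note,
           top_symbol = if (!is.null(rb$ranked) && nrow(rb$ranked))
             rb$ranked$symbol[1] else NA_character_)
      if (rb$pass) return(list(hit = hits[i, , drop = FALSE], notes = notes))
      if (!is.na(rb$paralog_note)) notes <- c(notes, rb$paralog_note)
      else notes <- c(notes, NA_character_)
    }
    list(hit = NULL, notes = notes)
  }

  g_rb <- if (nrow(ghits)) run_reciprocal(ghits, "genome") else
    list(hit = NULL, notes = character(0))

  ref_nbs <- list()
  for (r in seq_along(refs)) {
    nb <- tryCatch(extract_neighborhood(refs[[r]], symbol, p$window),
                   error = function(e) NULL)
    if (!is.null(nb)) ref_nbs[[length(ref_nbs) + 1L]] <- nb
  }
  if (!length(ref_nbs)) stop("no reference neighborhood derivable for ", symbol)

  if (!is.null(g_rb$hit)) {
    h <- g_rb$hit
    locus <- list(scaffold = h$scaffold, start = h$start, end = h$end,
                  source = "genome")
    mid <- floor((h$start + h$end) / 2)
    tnb <- extract_neighborhood(target, list(scaffold = h$scaffold, pos = mid),
                                p$window)
    informative <- vapply(ref_nbs, function(nb)
      length(.nb_symbols(nb)) >= p$min_shared, logical(1))
    if (!any(informative)) {
      note("synteny", "uninformative_reference", max_score = NA_real_)
      return(finish("present", locus))
    }
    scores <- vapply(ref_nbs[informative], function(nb) {
      sc <- synteny_score(tnb, nb)
      if (sc$n_lcs < p$min_shared) 0 else sc$score
    }, numeric(1))
    best <- max(scores)
    note("synteny", if (best >= p$theta) "pass" else "fail",
         max_score = best, theta = p$theta)
    if (best >= p$theta) return(finish("present", locus, max_synteny = best))
    # synteny failed: if the hit sits on an annotated target gene of a
    # different symbol, the neighborhood comparison has identified the locus
    # as that paralog, not the query - the gene itself is absent
    tg <- target$genes
    ov <- which(tg$scaffold == h$scaffold & tg$start < h$end & tg$end > h$start)
    if (length(ov)) {
      ovlen <- pmin(tg$end[ov], h$end) - pmax(tg$start[ov], h$start)
      sym_ov <- tg$symbol[ov[which.max(ovlen)]]
      if (!nzchar(sym_ov)) sym_ov <- tg$id[ov[which.max(ovlen)]]
      if (toupper(sym_ov) != toupper(symbol)) {
        note("paralog_identified", "synteny", locus_symbol = sym_ov)
        return(finish("absent", paralog_note = tolower(sym_ov),
                      max_synteny = best))
      }
    }
    return(finish("ambiguous", locus, max_synteny = best))
  }

  if (!is.null(thits) && nrow(thits)) {
    t_rb <- run_reciprocal(thits, "transcriptome")
    if (!is.null(t_rb$hit)) {
      h <- t_rb$hit
      locus <- list(scaffold = h$scaffold, start = h$start, end = h$end,
                    source = "transcriptome")
      note("transcript_rescue", "present")
      return(finish("present", locus))
    }
  }

  if (length(g_rb$notes)) {
    # genome hits existed but none verified; a recognizable paralog at every
    # hit is itself evidence of absence (the query's family member is
    # elsewhere), anything less stays ambiguous
    if (all(!is.na(g_rb$notes))) {
      note("decision", "all_hits_paralogous", paralogs = unique(g_rb$notes))
      return(finish("absent", paralog_note = g_rb$notes[1]))
    }
    note("decision", "unverifiable_hits")
    return(finish("ambiguous"))
  }

  # no qualifying genome hit: flank anchoring + interval scan
  for (nb in ref_nbs) {
    anc <- anchor_flanks(target, nb, panel, scheme,
                         params = list(anchor_e_max = p$anchor_e_max,
                                       anchor_min_coverage = p$anchor_min_coverage,
                                       k = p$k),
                         index = target_index)
    note("anchor_flanks", anc$status,
         ref_scaffold = nb$scaffold,
         interval = if (!is.null(anc$interval))
           sprintf("%s:%d-%d", anc$interval$scaffold, anc$interval$start,
                   anc$interval$end) else NA_character_)
    if (anc$status == "both_flanks") {
      scan <- scan_interval(target, anc$interval, q, scheme,
                            params = list(e_max_interval = p$e_max_interval,
                                          scan_min_coverage = p$scan_min_coverage,
                                          pad = p$pad))
      note("interval_scan", if (nrow(scan)) "hits" else "empty",
           n_hits = nrow(scan), status = attr(scan, "scan_status"))
      if (!nrow(scan)) return(finish("absent"))
      return(finish("ambiguous"))
    }
  }
  note("decision", "flanks_unanchored")
  finish("ambiguous")
}

#' @export
print.presence_call <- function(x, ...) {
  loc <- if (!is.null(x$locus)) {
    sprintf(" @ %s:%s-%s (%s)", x$locus$scaffold, x$locus$start, x$locus$end,
            x$locus$source)
  } else ""
  pn <- if (!is.na(x$paralog_note)) sprintf(" [paralog: %s]", x$paralog_note) else ""
  cat(sprintf("%s: %s%s%s\n", x$symbol, x$status, loc, pn))
  invisible(x)
}

#' Classify a set of query genes
#'
#' Runs [classify_gene()] per symbol over a shared seed index, recording
#' per-gene errors as `"error"` rows so one bad query never aborts the run.
#' Row order is deterministic (input symbol order).
#'
#' @param symbols character vector of query symbols.
#' @param queries named character vector of query proteins (names are
#'   symbols); symbols missing from `queries` are taken from the panel
#'   (first record of that symbol).
#' @param refs reference `annotated_genome`(s).
#' @param target target `annotated_genome`.
#' @param panel an `ortholog_panel`.
#' @param transcriptome optional named character vector of transcripts.
#' @param scheme protein [scoring_scheme()].
#' @param params classifier parameter overrides (see [classify_gene()]).
#' @return a `presence_calls` data.frame (symbol, status, locus columns,
#'   paralog_note, max_synteny); the full `presence_call` objects are in
#'   `attr(x, "calls")`.
#' @export
classify_panel <- function(symbols, queries = NULL, refs, target, panel,
                           transcriptome = NULL,
                           scheme = scoring_scheme("protein"),
                           params = list()) {
  p <- .presence_params(params)
  if (!length(symbols)) {
    out <- data.frame(symbol = character(), status = character(),
                      scaffold = character(), start = integer(),
                      end = integer(), source = character(),
                      paralog_note = character(), max_synteny = numeric(),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("presence_calls", "data.frame"),
                     calls = list()))
  }
  target_index <- build_seed_index(target, p$k, "translated")
  tx_index <- if (!is.null(transcriptome) && length(transcriptome)) {
    build_seed_index(transcriptome, p$k, "translated")
  } else NULL
  calls <- vector("list", length(symbols))
  rows <- vector("list", length(symbols))
  for (i in seq_along(symbols)) {
    sym <- symbols[i]
    qs <- if (!is.null(queries) && sym %in% names(queries)) queries[[sym]] else {
      pi <- which(toupper(panel$symbol) == toupper(sym))
      if (length(pi)) panel$seq[pi[1]] else NULL
    }
    call <- tryCatch(
      classify_gene(sym, qs, refs, target, panel, transcriptome, scheme,
                    params, target_index = target_index, tx_index = tx_index),
      error = function(e) {
        structure(list(symbol = sym, status = "error", locus = NULL,
                       paralog_note = NA_character_, max_synteny = NA_real_,
                       evidence = list(list(step = "error",
                                            outcome = conditionMessage(e),
                                            metrics = list())),
                       params = p),
                  class = "presence_call")
      })
    calls[[i]] <- call
    rows[[i]] <- data.frame(
      symbol = sym, status = call$status,
      scaffold = if (!is.null(call$locus)) call$locus$scaffold else NA_character_,
      start = if (!is.null(call$locus)) call$locus$start else NA_integer_,
      end = if (!is.null(call$locus)) call$locus$end else NA_integer_,
      source = if (!is.null(call$locus)) call$locus$source else NA_character_,
      paralog_note = call$paralog_note, max_synteny = call$max_synteny,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("presence_calls", "data.frame"), calls = calls)
}

#' @export
print.presence_calls <- function(x, ...) {
  cat("presence_calls:", nrow(x), "query gene(s)\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
summary.presence_calls <- function(object, ...) {
  tab <- table(factor(object$status,
                      levels = c("present", "absent", "ambiguous", "error")))
  cat("presence/absence calls by status:\n")
  print(tab)
  invisible(tab)
}
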