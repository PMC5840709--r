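#' Scoring scheme for local alignment
#'
#' Bundles the substitution matrix, affine gap penalties (costs; a gap of
#' length L costs `gap_open + L * gap_extend`) and the Karlin-Altschul
#' parameters used to convert raw scores to bit scores and E-values.
#'
#' Protein defaults use BLOSUM62 with gapped-BLAST penalties 11/1 and the
#' standard gapped estimates lambda = 0.267, K = 0.041. Nucleotide defaults
#' use match +1 / mismatch -2 with gaps 5/2 and lambda = 1.28, K = 0.46.
#' The stop-codon sentinel `*` scores as a mismatch against everything,
#' including itself, so reading-frame breaks never score positively.
#'
#' @param type `"protein"` or `"nucleotide"`.
#' @param match,mismatch nucleotide match/mismatch scores (ignored for
#'   protein).
#' @param gap_open,gap_extend gap penalties, as positive costs.
#' @param K,lambda Karlin-Altschul parameters.
#' @param matrix optional substitution matrix overriding the default; square
#'   numeric with identical dimnames.
#' @return object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(type = c("protein", "nucleotide"),
                           match = 1, mismatch = -2,
                           gap_open = NULL, gap_extend = NULL,
                           K = NULL, lambda = NULL, matrix = NULL) {
  type <- match.arg(type)
  if (type == "protein") {
    if (is.null(matrix)) matrix <- blosum62()
    gap_open <- gap_open %||% 11
    gap_extend <- gap_extend %||% 1
    lambda <- lambda %||% 0.267
    K <- K %||% 0.041
  } else {
    if (is.null(matrix)) {
      ab <- DNA_ALPHABET
      matrix <- base::matrix(mismatch, length(ab), length(ab),
                             dimnames = list(ab, ab))
      diag(matrix) <- match
      matrix["N", ] <- mismatch
      matrix[, "N"] <- mismatch
    }
    gap_open <- gap_open %||% 5
    gap_extend <- gap_extend %||% 2
    lambda <- lambda %||% 1.28
    K <- K %||% 0.46
  }
  stopifnot(gap_open > 0 || gap_extend > 0, lambda > 0, K > 0,
            identical(rownames(matrix), colnames(matrix)))
  structure(list(type = type, matrix = matrix,
                 alphabet = paste(rownames(matrix), collapse = ""),
                 gap_open = gap_open, gap_extend = gap_extend,
                 K = K, lambda = lambda),
            class = "scoring_scheme")
}

#' BLOSUM62 with mismatch-only stop sentinel
#'
#' The Biostrings BLOSUM62 matrix, with the `*` row/column forced to -4
#' everywhere (including `*` vs `*`) so stop codons behave as universal
#' mismatches.
#'
#' @return numeric substitution matrix.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  m["*", ] <- -4
  m[, "*"] <- -4
  m
}

#' Smith-Waterman local alignment
#'
#' Optimal local alignment under affine gaps (Gotoh), with deterministic
#' traceback (ties broken diagonal > up > left). Optionally banded around a
#' seed diagonal.
#'
#' @param a,b sequences over the scheme's alphabet.
#' @param scheme a [scoring_scheme()].
#' @param band half-band width around `diag`, or `NULL` for a full DP.
#' @param diag seed diagonal (`b` position minus `a` position) for banded
#'   alignment.
#' @return list with `score`, 0-based half-open `a_interval`/`b_interval`,
#'   `identity` (identities over alignment columns), `n_cols`, and the gapped
#'   alignment strings `a_aln`, `b_aln`.
#' @export
smith_waterman <- function(a, b, scheme, band = NULL, diag = 0L) {
  stopifnot(inherits(scheme, "scoring_scheme"), nzchar(a), nzchar(b))
  r <- sw_align_cpp(toupper(a), toupper(b), scheme$matrix, scheme$alphabet,
                    scheme$gap_open, scheme$gap_extend,
                    if (is.null(band)) -1L else as.integer(band),
                    as.integer(diag), TRUE)
  if (r$score <= 0 || is.na(r$a_start)) {
    return(list(score = r$score, a_interval = c(0L, 0L),
                b_interval = c(0L, 0L), identity = 0, n_cols = 0L,
                a_aln = "", b_aln = ""))
  }
  list(score = r$score,
       a_interval = c(r$a_start - 1L, r$a_end),
       b_interval = c(r$b_start - 1L, r$b_end),
       identity = if (r$n_cols > 0) r$n_ident / r$n_cols else 0,
       n_cols = r$n_cols, a_aln = r$a_aln, b_aln = r$b_aln)
}

#' Bit score from a raw alignment score
#'
#' `S' = (lambda * S - ln K) / ln 2`.
#'
#' @param raw raw alignment score.
#' @param scheme a [scoring_scheme()].
#' @return bit score.
#' @export
bit_score <- function(raw, scheme) {
  (scheme$lambda * raw - log(scheme$K)) / log(2)
}

#' Karlin-Altschul E-value
#'
#' Expected number of chance alignments at or above a bit score in a search
#' space of `query_len * db_len`: `E = m * n * 2^(-S')`.
#'
#' @param bit_score bit score.
#' @param query_len,db_len query and database lengths (> 0).
#' @return E-value.
#' @export
evalue <- function(bit_score, query_len, db_len) {
  stopifnot(is.finite(bit_score), query_len > 0, db_len > 0)
  query_len * db_len * 2^(-bit_score)
}

valid_kmer <- function(km) !grepl("[NX*]", km)

.substrate_scaffolds <- function(substrate) {
  if (inherits(substrate, "annotated_genome")) substrate$scaffolds
  else {
    stopifnot(is.character(substrate))
    toupper(substrate)
  }
}

#' Build a k-mer seed index of a substrate
#'
#' Maps every k-mer of the substrate to its locations; in translated mode all
#' six reading frames of every scaffold are indexed. K-mers containing `N`,
#' `X` or `*` are skipped.
#'
#' @param substrate an `annotated_genome` or named character vector of
#'   sequences (e.g. transcripts).
#' @param k word size (>= 2).
#' @param mode `"nucleotide"` or `"translated"`.
#' @return object of class `seed_index`.
#' @export
build_seed_index <- function(substrate, k, mode = c("nucleotide", "translated")) {
  mode <- match.arg(mode)
  stopifnot(k >= 2)
  scaffolds <- .substrate_scaffolds(substrate)
  if (mode == "translated") {
    frames <- do.call(rbind, lapply(names(scaffolds), function(sc) {
      tr <- six_frame_translate(scaffolds[[sc]])
      data.frame(scaffold = sc, frame = names(tr), seq = unname(tr),
                 nt_len = nchar(scaffolds[[sc]]), stringsAsFactors = FALSE)
    }))
  } else {
    frames <- data.frame(scaffold = names(scaffolds), frame = "+",
                         seq = unname(scaffolds), nt_len = nchar(scaffolds),
                         stringsAsFactors = FALSE)
  }
  frame_v <- integer(0); pos_v <- integer(0); km_all <- character(0)
  for (i in seq_len(nrow(frames))) {
    s <- frames$seq[i]
    n <- nchar(s)
    if (n < k) next
    pos <- seq_len(n - k + 1L)
    km <- substring(s, pos, pos + k - 1L)
    ok <- valid_kmer(km)
    if (!any(ok)) next
    frame_v <- c(frame_v, rep.int(i, sum(ok)))
    pos_v <- c(pos_v, pos[ok])
    km_all <- c(km_all, km[ok])
  }
  if (!length(km_all)) {
    warning("no indexable ", k, "-mers in substrate; empty seed index")
    env <- new.env(hash = TRUE, parent = emptyenv())
  } else {
    env <- list2env(split(seq_along(km_all), km_all),
                    hash = TRUE, parent = emptyenv())
  }
  structure(list(k = as.integer(k), mode = mode, frames = frames,
                 frame_v = frame_v, pos_v = pos_v, env = env,
                 db_len = sum(nchar(scaffolds))),
            class = "seed_index")
}

.seed_lookup <- function(index, qseq) {
  k <- index$k
  n <- nchar(qseq)
  if (n < k) return(NULL)
  qpos <- seq_len(n - k + 1L)
  km <- substring(qseq, qpos, qpos + k - 1L)
  ok <- valid_kmer(km)
  hits <- lapply(which(ok), function(i) {
    e <- index$env[[km[i]]]
    if (is.null(e)) return(NULL)
    cbind(qpos = i, idx = e)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || !nrow(hits)) return(NULL)
  data.frame(qpos = hits[, "qpos"],
             frame_row = index$frame_v[hits[, "idx"]],
             tpos = index$pos_v[hits[, "idx"]])
}

# cluster seeds of one frame by diagonal; returns list of (tpos, qpos) groups
.cluster_diagonals <- function(seeds, band) {
  seeds$diag <- seeds$tpos - seeds$qpos
  seeds <- seeds[order(seeds$diag, seeds$tpos), , drop = FALSE]
  brk <- c(TRUE, diff(seeds$diag) > band)
  split(seeds, cumsum(brk))
}

.empty_hits <- function() {
  structure(data.frame(query_id = character(), scaffold = character(),
                       start = integer(), end = integer(), strand = character(),
                       frame = character(), raw_score = numeric(),
                       bit_score = numeric(), e_value = numeric(),
                       coverage = numeric(), identity = numeric(),
                       q_start = integer(), q_end = integer(),
                       target_aln = character(), stringsAsFactors = FALSE),
            class = c("homology_hits", "data.frame"))
}

# map an aligned interval on a frame sequence back to forward-strand
# 0-based half-open genome coordinates
.frame_to_genome <- function(frame, nt_len, aa_start1, aa_end1, translated) {
  if (!translated) {
    return(c(aa_start1 - 1L, aa_end1, strand = NA))
  }
  f <- as.integer(substring(frame, 2L))
  s0 <- 3L * (aa_start1 - 1L) + (f - 1L)
  e0 <- 3L * aa_end1 + (f - 1L)
  if (startsWith(frame, "+")) c(s0, e0) else c(nt_len - e0, nt_len - s0)
}

#' Seed-and-extend homology search
#'
#' Replaces the BLASTn/BLASTx/tBLASTn steps at desk scale: exact k-mer seeds
#' are clustered by diagonal, each cluster is extended by Smith-Waterman over
#' a local window, scored, converted to bit scores and E-values, and filtered
#' by `e_max` and `min_coverage`. In translated mode (protein query against a
#' nucleotide substrate) all six frames are searched and aligned frame
#' coordinates are mapped back to forward-strand genome coordinates.
#' Hit ordering is deterministic: bit score descending, then E-value
#' ascending, then (scaffold, start).
#'
#' @param query a single named character (id -> sequence) or
#'   `list(id =, seq =)`.
#' @param substrate an `annotated_genome` or named character vector
#'   (transcripts/scaffolds).
#' @param scheme a [scoring_scheme()]; a protein scheme against a nucleotide
#'   substrate triggers translated search.
#' @param params list overriding defaults `k` (4 protein / 12 nucleotide),
#'   `e_max` (1e-10), `min_coverage` (0.5), `max_hits` (20), `band` (32),
#'   `pad` (extension window padding, 24), `min_seeds` (2; diagonal clusters
#'   with fewer seed matches are not extended).
#' @param index a prebuilt [build_seed_index()] for the substrate (rebuilt
#'   when `NULL`); reuse it when searching many queries.
#' @return a `homology_hits` data.frame.
#' @export
search_homology <- function(query, substrate, scheme = scoring_scheme("protein"),
                            params = list(), index = NULL) {
  if (is.character(query)) {
    stopifnot(length(query) == 1L, !is.null(names(query)))
    query <- list(id = names(query), seq = unname(query))
  }
  qseq <- toupper(query$seq)
  Lq <- nchar(qseq)
  translated <- scheme$type == "protein"
  p <- utils::modifyList(list(k = if (translated) 4L else 12L, e_max = 1e-10,
                              min_coverage = 0.5, max_hits = 20L, band = 32L,
                              pad = 24L, min_seeds = 2L), params)
  scaffolds <- .substrate_scaffolds(substrate)
  if (!length(scaffolds) || all(!nzchar(scaffolds))) {
    message("empty substrate; no hits")
    return(.empty_hits())
  }
  if (is.null(index)) {
    index <- build_seed_index(substrate, p$k,
                              if (translated) "translated" else "nucleotide")
  }
  stopifnot(index$k == p$k)
  db_len <- index$db_len

  queries <- list(list(seq = qseq, orient = "+"))
  if (!translated) queries <- c(queries, list(list(seq = revcomp(qseq), orient = "-")))

  rows <- list()
  for (qv in queries) {
    seeds <- .seed_lookup(index, qv$seq)
    if (is.null(seeds)) next
    for (fr in unique(seeds$frame_row)) {
      fs <- seeds[seeds$frame_row == fr, , drop = FALSE]
      finfo <- index$frames[fr, ]
      flen <- nchar(finfo$seq)
      clusters <- .cluster_diagonals(fs, p$band)
      # bound work on repetitive substrates: strongest clusters first
      if (length(clusters) > 3L * p$max_hits) {
        sizes <- vapply(clusters, nrow, integer(1))
        clusters <- clusters[order(-sizes)[seq_len(3L * p$max_hits)]]
      }
      for (cl in clusters) {
        if (nrow(cl) < p$min_seeds) next
        wstart <- max(1L, min(cl$tpos - cl$qpos + 1L) - p$pad)
        wend <- min(flen, max(cl$tpos + (Lq - cl$qpos)) + p$pad)
        if (wend < wstart) next
        win <- substring(finfo$seq, wstart, wend)
        aln <- smith_waterman(qv$seq, win, scheme)
        if (aln$score <= 0) next
        bs <- bit_score(aln$score, scheme)
        ev <- evalue(bs, Lq, db_len)
        b1 <- aln$b_interval[1] + wstart       # 1-based start on frame seq
        b2 <- aln$b_interval[2] + wstart - 1L  # 1-based end on frame seq
        g <- .frame_to_genome(finfo$frame, finfo$nt_len, b1, b2, translated)
        qint <- aln$a_interval
        if (qv$orient == "-") qint <- c(Lq - qint[2], Lq - qint[1])
        strand <- if (translated) {
          if (startsWith(finfo$frame, "+")) "+" else "-"
        } else qv$orient
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = query$id, scaffold = finfo$scaffold,
          start = as.integer(g[1]), end = as.integer(g[2]), strand = strand,
          frame = if (translated) finfo$frame else qv$orient,
          raw_score = aln$score, bit_score = bs, e_value = ev,
          coverage = (qint[2] - qint[1]) / Lq, identity = aln$identity,
          q_start = as.integer(qint[1]), q_end = as.integer(qint[2]),
          target_aln = gsub("-", "", aln$b_aln, fixed = TRUE),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(.empty_hits())
  hits <- do.call(rbind, rows)
  hits <- hits[hits$e_value <= p$e_max & hits$coverage >= p$min_coverage, ,
               drop = FALSE]
  if (!nrow(hits)) return(.empty_hits())
  hits <- hits[order(-hits$bit_score, hits$e_value, hits$scaffold, hits$start), ,
               drop = FALSE]
  # non-maximum suppression: drop hits mostly covered by a better kept hit
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    if (any(keep)) {
      ks <- which(keep)
      same <- hits$scaffold[ks] == hits$scaffold[i]
      if (any(same)) {
        ov <- pmin(hits$end[ks[same]], hits$end[i]) -
          pmax(hits$start[ks[same]], hits$start[i])
        shorter <- pmin(hits$end[ks[same]] - hits$start[ks[same]],
                        hits$end[i] - hits$start[i])
        if (any(ov > 0.5 * shorter)) ok <- FALSE
      }
    }
    keep[i] <- ok
  }
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) > p$max_hits) hits <- hits[seq_len(p$max_hits), , drop = FALSE]
  rownames(hits) <- NULL
  structure(hits, class = c("homology_hits", "data.frame"), params = p)
}
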