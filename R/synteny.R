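#' Extract the gene neighborhood of a focal locus
#'
#' Returns up to `window` genes on each side of a focal gene (or of an
#' explicit locus, giving a "virtual" neighborhood), in coordinate order and
#' truncated at scaffold ends. "Upstream" always means lower coordinate.
#' Genes without a symbol are represented by their ids. Symbols are
#' uppercase-normalized for comparison.
#'
#' @param genome an `annotated_genome`.
#' @param focal a gene symbol or id, or `list(scaffold =, pos =)` for a
#'   virtual neighborhood around a position.
#' @param window maximum genes per side (>= 1).
#' @param species optional species tag carried in the result.
#' @return object of class `gene_neighborhood` with elements `species`,
#'   `focal`, `upstream`/`downstream` (symbol vectors in coordinate order),
#'   `upstream_named`/`downstream_named` (logical: had a real symbol),
#'   `scaffold`, `start`, `end`.
#' @export
extract_neighborhood <- function(genome, focal, window = 5L, species = "") {
  stopifnot(window >= 1L)
  g <- genome$genes
  sym_of <- function(rows) {
    s <- ifelse(nzchar(rows$symbol), rows$symbol, rows$id)
    toupper(s)
  }
  if (is.list(focal)) {
    scaf <- focal$scaffold
    pos <- focal$pos
    sg <- scaffold_genes(genome, scaf)
    hitrow <- which(sg$start <= pos & sg$end > pos)
    if (length(hitrow)) {
      fi <- hitrow[1]
      focal_sym <- sym_of(sg[fi, , drop = FALSE])
      up <- sg[seq_len(fi - 1L), , drop = FALSE]
      down <- sg[setdiff(seq_len(nrow(sg)), seq_len(fi)), , drop = FALSE]
    } else {
      focal_sym <- NA_character_
      up <- sg[sg$end <= pos, , drop = FALSE]
      down <- sg[sg$start >= pos, , drop = FALSE]
    }
  } else {
    i <- which(toupper(g$symbol) == toupper(focal) | g$id == focal)
    if (!length(i)) stop("no gene with symbol or id '", focal, "' and no locus given")
    i <- i[1]
    scaf <- g$scaffold[i]
    sg <- scaffold_genes(genome, scaf)
    fi <- which(sg$id == g$id[i])
    focal_sym <- sym_of(sg[fi, , drop = FALSE])
    up <- sg[seq_len(fi - 1L), , drop = FALSE]
    down <- sg[setdiff(seq_len(nrow(sg)), seq_len(fi)), , drop = FALSE]
  }
  up <- utils::tail(up, window)
  down <- utils::head(down, window)
  win_rows <- rbind(up, down)
  structure(list(species = species, focal = focal_sym,
                 upstream = sym_of(up), downstream = sym_of(down),
                 upstream_named = nzchar(up$symbol),
                 downstream_named = nzchar(down$symbol),
                 scaffold = scaf,
                 start = if (nrow(win_rows)) min(win_rows$start) else NA_integer_,
                 end = if (nrow(win_rows)) max(win_rows$end) else NA_integer_),
            class = "gene_neighborhood")
}

#' @export
print.gene_neighborhood <- function(x, ...) {
  cat(sprintf("gene_neighborhood [%s] %s | (%s) | %s\n",
              x$scaffold, paste(x$upstream, collapse = " "),
              ifelse(is.na(x$focal), "-", x$focal),
              paste(x$downstream, collapse = " ")))
  invisible(x)
}

.nb_symbols <- function(nb, named_only = TRUE) {
  s <- c(nb$upstream, nb$downstream)
  if (named_only) s[c(nb$upstream_named, nb$downstream_named)] else s
}

lcs_length <- function(a, b) {
  n <- length(a); m <- length(b)
  if (!n || !m) return(0L)
  prev <- integer(m + 1L)
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    for (j in seq_len(m)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Order-conservation score between two gene neighborhoods
#'
#' Restricts each neighborhood to the named genes shared with the other,
#' computes the longest common subsequence of the two shared-symbol orders,
#' and normalizes by the smaller named-gene count. Both orientations of `b`
#' are tried (assembly/strand orientation differs across species) and the
#' better score is kept, making the score symmetric and between 0 and 1.
#'
#' @param a,b `gene_neighborhood` objects.
#' @return list with `score`, `shared` (shared named symbols), `n_lcs`,
#'   `orientation` (`"forward"` or `"reversed"`), and `status` (`"ok"` or
#'   `"no_named_genes"` when either window has no named genes, in which case
#'   the score is 0).
#' @export
synteny_score <- function(a, b) {
  stopifnot(inherits(a, "gene_neighborhood"), inherits(b, "gene_neighborhood"))
  A <- .nb_symbols(a)
  B <- .nb_symbols(b)
  if (!length(A) || !length(B)) {
    return(list(score = 0, shared = character(0), n_lcs = 0L,
                orientation = "forward", status = "no_named_genes"))
  }
  shared <- intersect(A, B)
  As <- A[A %in% shared]
  Bs <- B[B %in% shared]
  fwd <- lcs_length(As, Bs)
  rev_ <- lcs_length(As, rev(Bs))
  n_lcs <- max(fwd, rev_)
  list(score = n_lcs / min(length(A), length(B)), shared = shared,
       n_lcs = as.integer(n_lcs),
       orientation = if (rev_ > fwd) "reversed" else "forward",
       status = "ok")
}

.anchor_one <- function(target, symbol, panel, scheme, params, index) {
  # annotation-symbol equality first
  g <- target$genes
  hit <- which(toupper(ifelse(nzchar(g$symbol), g$symbol, g$id)) == toupper(symbol))
  if (length(hit)) {
    return(data.frame(symbol = symbol, scaffold = g$scaffold[hit],
                      start = g$start[hit], end = g$end[hit],
                      method = "symbol", stringsAsFactors = FALSE))
  }
  # homology fallback against the panel protein of that symbol
  if (is.null(panel)) return(NULL)
  pi <- which(toupper(panel$symbol) == toupper(symbol))
  if (!length(pi)) return(NULL)
  q <- list(id = symbol, seq = panel$seq[pi[1]])
  hits <- search_homology(q, target, scheme,
                          params = list(e_max = params$anchor_e_max,
                                        min_coverage = params$anchor_min_coverage,
                                        k = params$k),
                          index = index)
  if (!nrow(hits)) return(NULL)
  data.frame(symbol = symbol, scaffold = hits$scaffold[1],
             start = hits$start[1], end = hits$end[1],
             method = "homology", stringsAsFactors = FALSE)
}

#' Anchor a reference neighborhood's flanks in a target genome
#'
#' Locates the flanking genes of a reference neighborhood in the target,
#' trying annotation-symbol equality first and falling back to homology of
#' the flank's panel protein (coverage >= 0.5 and E <= 1e-10 by default).
#' When an upstream and a downstream flank anchor on one scaffold without
#' overlapping, the candidate interval spanning the gap between the
#' innermost such pair is returned - the region where the focal gene
#' "should" be.
#'
#' @param target the target `annotated_genome`.
#' @param reference_nb a `gene_neighborhood` from the reference species.
#' @param panel optional `ortholog_panel` used for homology anchoring.
#' @param scheme protein [scoring_scheme()] for homology anchoring.
#' @param params list overriding `anchor_e_max` (1e-10),
#'   `anchor_min_coverage` (0.5), `k` (4).
#' @param index optional translated [build_seed_index()] of `target`.
#' @return object of class `synteny_anchor`: `anchors` (data.frame of
#'   anchored flank loci), `status` (`"both_flanks"`, `"one_flank"` or
#'   `"none"`), and `interval` (`list(scaffold, start, end)` or `NULL`).
#' @export
anchor_flanks <- function(target, reference_nb, panel = NULL,
                          scheme = scoring_scheme("protein"),
                          params = list(), index = NULL) {
  stopifnot(inherits(reference_nb, "gene_neighborhood"))
  p <- utils::modifyList(list(anchor_e_max = 1e-10, anchor_min_coverage = 0.5,
                              k = 4L), params)
  up_syms <- reference_nb$upstream[reference_nb$upstream_named]
  down_syms <- reference_nb$downstream[reference_nb$downstream_named]
  # innermost-first: upstream symbols are coordinate-ascending
  up_syms <- rev(up_syms)
  anchor_side <- function(syms) {
    out <- list()
    for (s in syms) {
      a <- .anchor_one(target, s, panel, scheme, p, index)
      if (!is.null(a)) out[[length(out) + 1L]] <- a
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  ua <- anchor_side(up_syms)
  da <- anchor_side(down_syms)
  anchors <- rbind(
    if (!is.null(ua)) cbind(ua, side = "upstream", stringsAsFactors = FALSE),
    if (!is.null(da)) cbind(da, side = "downstream", stringsAsFactors = FALSE))
  status <- "none"
  interval <- NULL
  if (!is.null(ua) && !is.null(da)) {
    # innermost compatible pair: candidates are already innermost-first
    for (i in seq_len(nrow(ua))) {
      for (j in seq_len(nrow(da))) {
        if (ua$scaffold[i] != da$scaffold[j]) next
        gap_start <- min(ua$end[i], da$end[j])
        gap_end <- max(ua$start[i], da$start[j])
        overlap <- min(ua$end[i], da$end[j]) > max(ua$start[i], da$start[j])
        if (overlap) next
        interval <- list(scaffold = ua$scaffold[i],
                         start = gap_start, end = gap_end)
        break
      }
      if (!is.null(interval)) break
    }
    status <- if (!is.null(interval)) "both_flanks" else "one_flank"
  } else if (!is.null(ua) || !is.null(da)) {
    status <- "one_flank"
  }
  structure(list(anchors = anchors, status = status, interval = interval),
            class = "synteny_anchor")
}

#' Homology scan restricted to a genomic interval
#'
#' Translated search of a query protein against one interval of the target
#' (padded on both sides for annotation-boundary tolerance), with thresholds
#' relaxed relative to the genome-wide search so that absence is declared
#' only after a maximally sensitive look. Hits are mapped back to genome
#' coordinates.
#'
#' @param target the target `annotated_genome`.
#' @param interval `list(scaffold, start, end)` in 0-based half-open
#'   coordinates.
#' @param query protein query (named character or `list(id =, seq =)`).
#' @param scheme protein [scoring_scheme()].
#' @param params list overriding `e_max_interval` (1e-3),
#'   `scan_min_coverage` (0.3), `pad` (2000), `k` (4).
#' @return a `homology_hits` data.frame; attribute `scan_status` is
#'   `"empty_interval"` for a zero-length (post-clamp) interval, else
#'   `"scanned"`.
#' @export
scan_interval <- function(target, interval, query,
                          scheme = scoring_scheme("protein"),
                          params = list()) {
  p <- utils::modifyList(list(e_max_interval = 1e-3, scan_min_coverage = 0.3,
                              pad = 2000L, k = 4L), params)
  scaf <- interval$scaffold
  if (!scaf %in% names(target$scaffolds)) stop("unknown scaffold: ", scaf)
  slen <- nchar(target$scaffolds[[scaf]])
  if (interval$start < 0L || interval$end > slen) {
    stop("interval beyond scaffold bounds")
  }
  s0 <- max(0L, interval$start - p$pad)
  e0 <- min(slen, interval$end + p$pad)
  if (e0 <= s0 || interval$end <= interval$start) {
    out <- .empty_hits()
    attr(out, "scan_status") <- "empty_interval"
    return(out)
  }
  sub <- substring(target$scaffolds[[scaf]], s0 + 1L, e0)
  names(sub) <- scaf
  hits <- search_homology(query, sub, scheme,
                          params = list(e_max = p$e_max_interval,
                                        min_coverage = p$scan_min_coverage,
                                        k = p$k))
  if (nrow(hits)) {
    hits$start <- hits$start + s0
    hits$end <- hits$end + s0
  }
  attr(hits, "scan_status") <- "scanned"
  hits
}
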