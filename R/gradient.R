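#' Construct a segment-ordered expression matrix
#'
#' Raw RNA-seq counts over samples assigned to ordered gut segments
#' (anterior to posterior), with per-gene transcript lengths for FPKM
#' normalization.
#'
#' @param counts integer matrix, genes x samples, row/colnames set.
#' @param segments character/factor of length `ncol(counts)` assigning each
#'   sample to a segment; `seg_levels` fixes the anterior-to-posterior order
#'   (defaults to order of first appearance).
#' @param lengths named numeric vector of gene lengths in bp (> 0).
#' @param seg_levels ordered segment labels.
#' @return object of class `expr_matrix`.
#' @export
expr_matrix <- function(counts, segments, lengths, seg_levels = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have row (gene) and column (sample) names")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (length(segments) != ncol(counts)) {
    stop("one segment assignment per sample required")
  }
  if (is.null(seg_levels)) seg_levels <- unique(as.character(segments))
  segments <- factor(as.character(segments), levels = seg_levels)
  if (anyNA(segments)) stop("sample(s) with segment outside seg_levels")
  if (!all(rownames(counts) %in% names(lengths))) {
    stop("missing gene length(s)")
  }
  lengths <- lengths[rownames(counts)]
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("gene lengths must be positive")
  }
  structure(list(counts = counts, segments = segments, lengths = lengths),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples over segments %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(levels(x$segments), collapse = " > ")))
  invisible(x)
}

#' FPKM normalization
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `FPKM = 1e9 * count / (length_bp * library_size)`. Library sizes default
#' to per-sample total counts.
#'
#' @param x an `expr_matrix`, or a counts matrix.
#' @param lengths gene lengths in bp (ignored for `expr_matrix` input).
#' @param library_sizes per-sample totals; defaults to `colSums(counts)`.
#' @return numeric matrix of FPKM values, same shape as the counts.
#' @export
fpkm <- function(x, lengths = NULL, library_sizes = NULL) {
  if (inherits(x, "expr_matrix")) {
    counts <- x$counts
    lengths <- x$lengths
  } else {
    counts <- as.matrix(x)
    stopifnot(!is.null(lengths))
    if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
      lengths <- lengths[rownames(counts)]
    }
  }
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (length(library_sizes) != ncol(counts)) {
    stop("one library size per sample required")
  }
  if (any(library_sizes <= 0)) stop("zero or negative library size")
  1e9 * sweep(counts / lengths, 2, library_sizes, "/")
}

#' Per-segment mean FPKM
#'
#' @param em an `expr_matrix`.
#' @param library_sizes optional per-sample totals passed to [fpkm()].
#' @return matrix genes x segments of arithmetic mean FPKM.
#' @export
segment_means <- function(em, library_sizes = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  f <- fpkm(em, library_sizes = library_sizes)
  segs <- levels(em$segments)
  out <- matrix(0, nrow(f), length(segs),
                dimnames = list(rownames(f), segs))
  for (s in segs) out[, s] <- rowMeans(f[, em$segments == s, drop = FALSE])
  out
}

#' Fold change between two segments' mean FPKM
#'
#' `(mean_i + eps) / (mean_j + eps)` with a pseudocount `eps` so genes
#' expressed in only one segment give a finite ratio.
#'
#' @param em an `expr_matrix`.
#' @param gene gene id.
#' @param seg_i,seg_j segment labels.
#' @param eps pseudocount in FPKM units.
#' @param library_sizes optional per-sample totals passed to [fpkm()].
#' @return numeric ratio.
#' @export
segment_fold_change <- function(em, gene, seg_i, seg_j, eps = 0.01,
                                library_sizes = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  if (!gene %in% rownames(em$counts)) stop("unknown gene: ", gene)
  if (!all(c(seg_i, seg_j) %in% levels(em$segments))) {
    stop("unknown segment label")
  }
  m <- segment_means(em, library_sizes = library_sizes)[gene, ]
  (m[[seg_i]] + eps) / (m[[seg_j]] + eps)
}

.classify_profile <- function(m, min_fold, tol, eps) {
  if (all(m == 0)) return(c(class = "flat", flag = "all_zero"))
  S <- length(m)
  fold_down <- (m[1] + eps) / (m[S] + eps)
  noninc <- all(m[-1] <= m[-S] * (1 + tol))
  nondec <- all(m[-S] <= m[-1] * (1 + tol))
  if (noninc && fold_down >= min_fold) return(c(class = "declining", flag = ""))
  if (nondec && 1 / fold_down >= min_fold) return(c(class = "increasing", flag = ""))
  if (max(fold_down, 1 / fold_down) < min_fold) return(c(class = "flat", flag = ""))
  c(class = "other", flag = "")
}

#' Anterior-to-posterior gradient classification
#'
#' Classifies each gene's segment profile as `declining` (segment means
#' non-increasing within a multiplicative tolerance, and first/last fold at
#' least `min_fold`), `increasing` (symmetric), `flat` (first/last fold
#' below `min_fold` in both directions), or `other`. All-zero genes are
#' `flat` with flag `"all_zero"`. The classification is descriptive - the
#' shape the per-segment FPKM display shows - not a differential-expression
#' test.
#'
#' @param em an `expr_matrix` with >= 3 ordered segments.
#' @param genes genes to classify (default all).
#' @param min_fold minimum first/last fold change (default 2).
#' @param tol multiplicative monotonicity tolerance (default 0.1).
#' @param eps FPKM pseudocount for fold changes.
#' @param library_sizes optional per-sample totals passed to [fpkm()].
#' @return data.frame with `gene`, `class`, `fold_first_last`, `flag`.
#' @export
gradient_class <- function(em, genes = NULL, min_fold = 2, tol = 0.1,
                           eps = 0.01, library_sizes = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  if (nlevels(em$segments) < 3L) stop("need >= 3 ordered segments")
  means <- segment_means(em, library_sizes = library_sizes)
  if (is.null(genes)) genes <- rownames(em$counts)
  if (!all(genes %in% rownames(em$counts))) stop("unknown gene(s)")
  res <- t(vapply(genes, function(g)
    .classify_profile(means[g, ], min_fold, tol, eps), character(2)))
  S <- ncol(means)
  data.frame(gene = genes,
             class = unname(res[, "class"]),
             fold_first_last = (means[genes, 1] + eps) / (means[genes, S] + eps),
             flag = unname(res[, "flag"]),
             row.names = NULL, stringsAsFactors = FALSE)
}
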