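#' @useDynLib synteloss, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rnbinom rlnorm runif setNames
#' @importFrom utils head tail write.table read.table
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement over the `A,C,G,T,N` alphabet used
#' throughout the package.
#'
#' @param x a single DNA string.
#' @return the reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bad <- gsub("[ACGTN]", "", toupper(x))
  if (nzchar(bad)) {
    stop("non-IUPAC character(s) in sequence: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(x)), "")[[1]]),
        collapse = "")
}

#' Read a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file into a named
#' character vector. Sequences are uppercased; duplicate record ids are an
#' error.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (file.size(path) == 0L) stop("parse error at line 1: empty FASTA file ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!startsWith(trimws(first), ">")) {
    stop("parse error at line 1: expected FASTA header ('>') in ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("parse error at line 1: no records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicated FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  out <- toupper(as.character(set))
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  # fixed ordering as given; writer output is deterministic
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct an annotated genome
#'
#' The container every search and synteny operation runs over: scaffold
#' sequences plus ordered, stranded gene models. All internal coordinates are
#' 0-based half-open; GFF3's 1-based inclusive convention is converted exactly
#' once on read and once on write.
#'
#' @param scaffolds named character vector of scaffold sequences.
#' @param genes data.frame with columns `id`, `symbol`, `scaffold`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`); 0-based half-open coordinates.
#' @param cds data.frame with columns `gene_id`, `start`, `end` giving ordered
#'   CDS segments in genome coordinates; may be empty.
#' @return an object of class `annotated_genome`.
#' @export
annotated_genome <- function(scaffolds, genes, cds = NULL) {
  stopifnot(is.character(scaffolds), !is.null(names(scaffolds)))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("id", "symbol", "scaffold", "start", "end", "strand")
  if (!all(need %in% names(genes))) {
    stop("genes table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(cds)) {
    cds <- data.frame(gene_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  }
  cds <- as.data.frame(cds, stringsAsFactors = FALSE)
  if (nrow(genes)) {
    if (anyDuplicated(genes$id)) {
      stop("duplicated gene id(s): ",
           paste(unique(genes$id[duplicated(genes$id)]), collapse = ", "))
    }
    if (!all(genes$scaffold %in% names(scaffolds))) {
      stop("gene(s) on unknown scaffold")
    }
    if (any(genes$start >= genes$end)) stop("gene with start >= end")
    slen <- nchar(scaffolds)[genes$scaffold]
    beyond <- genes$end > slen | genes$start < 0L
    if (any(beyond)) {
      stop("gene(s) beyond scaffold bounds: ",
           paste(genes$id[beyond], collapse = ", "))
    }
    genes <- genes[order(genes$scaffold, genes$start, genes$id), , drop = FALSE]
    rownames(genes) <- NULL
  }
  if (nrow(cds)) {
    if (!all(cds$gene_id %in% genes$id)) stop("CDS for unknown gene id")
    g <- genes[match(cds$gene_id, genes$id), ]
    if (any(cds$start < g$start | cds$end > g$end)) {
      stop("CDS segment outside its gene interval")
    }
    cds <- cds[order(match(cds$gene_id, genes$id), cds$start), , drop = FALSE]
    rownames(cds) <- NULL
  }
  structure(list(scaffolds = toupper(scaffolds), genes = genes, cds = cds),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("annotated_genome: %d scaffold(s), %s bp, %d gene model(s)\n",
              length(x$scaffolds),
              format(sum(nchar(x$scaffolds)), big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

#' Genes of one scaffold, sorted by start
#'
#' @param genome an `annotated_genome`.
#' @param scaffold scaffold id.
#' @return data.frame of gene models sorted by start coordinate.
#' @export
scaffold_genes <- function(genome, scaffold) {
  g <- genome$genes[genome$genes$scaffold == scaffold, , drop = FALSE]
  g[order(g$start), , drop = FALSE]
}

#' Read an annotated genome from GFF3 + FASTA
#'
#' Parses gene/mRNA/CDS features, converts GFF3's 1-based inclusive
#' coordinates to the package's 0-based half-open convention, and sorts genes
#' per scaffold by start. The gene symbol is taken from the first attribute
#' key in `symbol_attrs` that is present and non-empty (Ensembl and MAKER
#' GFF dialects differ in where they carry it).
#'
#' @param path path to a GFF3 file.
#' @param fasta path to the matching FASTA file, or a named character vector
#'   of scaffold sequences.
#' @param symbol_attrs attribute keys tried in order for the gene symbol.
#' @return an `annotated_genome`.
#' @export
read_gff3 <- function(path, fasta, symbol_attrs = c("gene_name", "Name", "ID")) {
  scaffolds <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    read_fasta(fasta)
  } else {
    stopifnot(is.character(fasta), !is.null(names(fasta)))
    toupper(fasta)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  seqn <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  strands <- as.character(GenomicRanges::strand(gr))

  bad <- !(seqn %in% names(scaffolds)) | ends > nchar(scaffolds)[seqn] | starts < 1L
  if (any(bad)) {
    stop("GFF3 feature(s) beyond scaffold bounds: ",
         paste(utils::head(paste0(seqn[bad], ":", starts[bad], "-", ends[bad]), 3),
               collapse = ", "))
  }

  attr_or_na <- function(key, i) {
    if (!key %in% names(md)) return(NA_character_)
    v <- md[[key]]
    if (methods::is(v, "List")) {
      v <- vapply(v, function(e) if (length(e)) as.character(e[[1]]) else NA_character_,
                  character(1))
    }
    as.character(v)[i]
  }

  gi <- which(type == "gene")
  if (!length(gi)) stop("no gene features in ", path)
  ids <- attr_or_na("ID", gi)
  if (anyNA(ids)) stop("gene feature without ID attribute in ", path)
  sym <- rep("", length(gi))
  for (key in rev(symbol_attrs)) {
    v <- attr_or_na(key, gi)
    ok <- !is.na(v) & nzchar(v)
    sym[ok] <- v[ok]
  }
  genes <- data.frame(id = ids, symbol = sym, scaffold = seqn[gi],
                      start = starts[gi] - 1L, end = ends[gi],
                      strand = strands[gi], stringsAsFactors = FALSE)

  # map mRNA id -> gene id, then CDS -> gene via its parent (mRNA or gene)
  parent_of <- function(i) {
    p <- md$Parent
    if (is.null(p)) return(NA_character_)
    e <- p[[i]]
    if (length(e)) as.character(e[[1]]) else NA_character_
  }
  mi <- which(type == "mRNA")
  mrna2gene <- character(0)
  if (length(mi)) {
    mids <- attr_or_na("ID", mi)
    mpar <- vapply(mi, parent_of, character(1))
    keep <- !is.na(mids) & !is.na(mpar)
    mrna2gene <- setNames(mpar[keep], mids[keep])
  }
  ci <- which(type == "CDS")
  cds <- data.frame(gene_id = character(), start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
  if (length(ci)) {
    cpar <- vapply(ci, parent_of, character(1))
    gene_of <- ifelse(cpar %in% names(mrna2gene), mrna2gene[cpar], cpar)
    orphan <- is.na(gene_of) | !(gene_of %in% genes$id)
    if (any(orphan)) {
      warning(sum(orphan), " CDS feature(s) without resolvable parent skipped")
    }
    keep <- !orphan
    cds <- data.frame(gene_id = gene_of[keep], start = starts[ci][keep] - 1L,
                      end = ends[ci][keep], stringsAsFactors = FALSE)
  }
  annotated_genome(scaffolds, genes, cds)
}

#' Write an annotated genome's annotation as GFF3
#'
#' Emits gene, mRNA and CDS features in deterministic order (scaffold id,
#' then start coordinate), converting internal 0-based half-open coordinates
#' back to GFF3's 1-based inclusive convention. CDS phase is computed from
#' cumulative coding length in transcription order.
#'
#' @param genome an `annotated_genome`.
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, path) {
  g <- genome$genes
  g <- g[order(g$scaffold, g$start, g$id), , drop = FALSE]
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d",
                     sort(names(genome$scaffolds)),
                     nchar(genome$scaffolds)[sort(names(genome$scaffolds))]))
  fmt <- function(scaf, type, s0, e0, strand, phase, attrs) {
    sprintf("%s\tsynteloss\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            scaf, type, s0 + 1L, e0, strand, phase, attrs)
  }
  for (i in seq_len(nrow(g))) {
    gid <- g$id[i]
    gattr <- sprintf("ID=%s", gid)
    if (nzchar(g$symbol[i])) {
      gattr <- sprintf("ID=%s;Name=%s;gene_name=%s", gid, g$symbol[i], g$symbol[i])
    }
    lines <- c(lines, fmt(g$scaffold[i], "gene", g$start[i], g$end[i],
                          g$strand[i], ".", gattr))
    segs <- genome$cds[genome$cds$gene_id == gid, , drop = FALSE]
    if (nrow(segs)) {
      lines <- c(lines, fmt(g$scaffold[i], "mRNA", g$start[i], g$end[i],
                            g$strand[i], ".",
                            sprintf("ID=%s.t1;Parent=%s", gid, gid)))
      segs <- segs[order(segs$start), , drop = FALSE]
      # transcription order for phase: reverse for minus strand
      ord <- if (g$strand[i] == "-") rev(seq_len(nrow(segs))) else seq_len(nrow(segs))
      cum <- 0L
      phase <- integer(nrow(segs))
      for (k in ord) {
        phase[k] <- (3L - (cum %% 3L)) %% 3L
        cum <- cum + (segs$end[k] - segs$start[k])
      }
      for (k in seq_len(nrow(segs))) {
        lines <- c(lines, fmt(g$scaffold[i], "CDS", segs$start[k], segs$end[k],
                              g$strand[i], phase[k],
                              sprintf("ID=%s.cds;Parent=%s.t1", gid, gid)))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Remove a gene from an annotated genome
#'
#' Drops the gene model (and its CDS segments) from the annotation and, by
#' default, masks the gene body with `N` - the situation an assembly gap
#' over a flank produces, where neither annotation nor homology can recover
#' the locus.
#'
#' @param genome an `annotated_genome`.
#' @param what gene symbol or id.
#' @param mask_sequence replace the gene body with `N`s (default `TRUE`).
#' @return a new `annotated_genome`.
#' @export
drop_gene <- function(genome, what, mask_sequence = TRUE) {
  g <- genome$genes
  i <- which(toupper(g$symbol) == toupper(what) | g$id == what)
  if (!length(i)) stop("no gene with symbol or id '", what, "'")
  scaffolds <- genome$scaffolds
  if (mask_sequence) {
    for (k in i) {
      sc <- g$scaffold[k]
      s <- scaffolds[[sc]]
      scaffolds[[sc]] <- paste0(
        substring(s, 1L, g$start[k]),
        strrep("N", g$end[k] - g$start[k]),
        substring(s, g$end[k] + 1L))
    }
  }
  drop_ids <- g$id[i]
  annotated_genome(scaffolds, g[-i, , drop = FALSE],
                   genome$cds[!genome$cds$gene_id %in% drop_ids, , drop = FALSE])
}

#' Extract the coding sequence of a gene
#'
#' Concatenates the gene's CDS segments in transcription order;
#' minus-strand genes are reverse-complemented.
#'
#' @param genome an `annotated_genome`.
#' @param gene_id gene identifier.
#' @return nucleotide string.
#' @export
extract_cds <- function(genome, gene_id) {
  gi <- match(gene_id, genome$genes$id)
  if (is.na(gi)) stop("no such gene: ", gene_id)
  g <- genome$genes[gi, ]
  segs <- genome$cds[genome$cds$gene_id == gene_id, , drop = FALSE]
  if (!nrow(segs)) stop("gene has no CDS segments: ", gene_id)
  segs <- segs[order(segs$start), , drop = FALSE]
  seq <- genome$scaffolds[[g$scaffold]]
  parts <- substring(seq, segs$start + 1L, segs$end)
  nt <- paste(parts, collapse = "")
  if (g$strand == "-") revcomp(nt) else nt
}

#' Translate a nucleotide string in one frame
#'
#' Standard genetic code; trailing bases short of a codon are dropped, stop
#' codons render as `*`, and any codon containing `N` renders `X`.
#'
#' @param nt nucleotide string over `A,C,G,T,N`.
#' @param offset 0, 1 or 2 bases skipped before the first codon.
#' @return amino-acid string.
#' @export
translate_nt <- function(nt, offset = 0L) {
  nt <- toupper(nt)
  bad <- gsub("[ACGTN]", "", nt)
  if (nzchar(bad)) {
    stop("non-IUPAC character(s) in sequence: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  L <- nchar(nt)
  n_codons <- (L - offset) %/% 3L
  if (n_codons <= 0L) return("")
  starts <- offset + 3L * (seq_len(n_codons) - 1L) + 1L
  codons <- substring(nt, starts, starts + 2L)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X" # codons containing N
  paste(aa, collapse = "")
}

#' Six-frame translation
#'
#' Translates all three forward and three reverse-complement frames.
#'
#' @param nt nucleotide string over `A,C,G,T,N`.
#' @return named character vector with frames `+1,+2,+3,-1,-2,-3`.
#' @export
six_frame_translate <- function(nt) {
  rc <- revcomp(nt)
  c("+1" = translate_nt(nt, 0L), "+2" = translate_nt(nt, 1L),
    "+3" = translate_nt(nt, 2L),
    "-1" = translate_nt(rc, 0L), "-2" = translate_nt(rc, 1L),
    "-3" = translate_nt(rc, 2L))
}
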