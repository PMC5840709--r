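# tiny in-code genomes shared across test files

toy_genome <- function() {
  with_seed(99, {
    sc <- setNames(c(random_nt(1200), random_nt(1000)), c("sc2", "sc1"))
    genes <- data.frame(
      id = c("gA", "gB", "gC"), symbol = c("alpha", "beta", "gamma"),
      scaffold = c("sc2", "sc2", "sc1"), start = c(100L, 400L, 50L),
      end = c(250L, 700L, 350L), strand = c("+", "-", "+"),
      stringsAsFactors = FALSE)
    cds <- data.frame(gene_id = c("gA", "gB", "gB", "gC"),
                      start = c(100L, 400L, 600L, 50L),
                      end = c(250L, 550L, 700L, 350L),
                      stringsAsFactors = FALSE)
    annotated_genome(sc, genes, cds)
  })
}

# a scaffold of n_genes named genes in order, for neighborhood tests
symbol_row_genome <- function(symbols, gene_len = 120L, gap = 80L,
                              scaffold = "scA") {
  n <- length(symbols)
  starts <- gap + (seq_len(n) - 1L) * (gene_len + gap)
  genes <- data.frame(
    id = paste0("id_", symbols), symbol = symbols, scaffold = scaffold,
    start = starts, end = starts + gene_len, strand = "+",
    stringsAsFactors = FALSE)
  sc <- setNames(with_seed(7, random_nt(max(genes$end) + gap)), scaffold)
  annotated_genome(sc, genes)
}

test_scheme_nt <- function() {
  scoring_scheme("nucleotide", match = 1, mismatch = -1, gap_open = 2,
                 gap_extend = 1, K = 0.46, lambda = 1.28)
}
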