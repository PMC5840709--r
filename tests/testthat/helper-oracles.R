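# Independent oracles, written before the aligner and synteny scorer they
# check, and kept free of any package internals.

# Affine-gap local alignment score by straightforward three-state dynamic
# programming in plain R; a gap of length L costs gap_open + L * gap_extend.
oracle_sw <- function(a, b, submat, gap_open, gap_extend) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + submat[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Exhaustive recursive enumeration of global alignments for tiny inputs;
# local score = best over all substring pairs (and the empty alignment).
oracle_sw_tiny <- function(a, b, submat, gap_open, gap_extend) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  glob <- function(ai, bi, last) {
    if (!length(ai) && !length(bi)) return(0)
    best <- -Inf
    if (length(ai) && length(bi)) {
      best <- max(best, submat[ai[1], bi[1]] + glob(ai[-1], bi[-1], "m"))
    }
    if (length(ai)) {
      cost <- if (last == "a") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + glob(ai[-1], bi, "a"))
    }
    if (length(bi)) {
      cost <- if (last == "b") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + glob(ai, bi[-1], "b"))
    }
    best
  }
  best <- 0
  for (i1 in seq_along(A)) for (i2 in i1:length(A)) {
    for (j1 in seq_along(B)) for (j2 in j1:length(B)) {
      best <- max(best, glob(A[i1:i2], B[j1:j2], "none"))
    }
  }
  best
}

# Longest common subsequence length by brute-force enumeration of all
# subsequences of the shorter vector.
oracle_lcs <- function(a, b) {
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  is_subseq <- function(s, v) {
    if (!length(s)) return(TRUE)
    k <- 1L
    for (x in v) {
      if (x == s[k]) {
        k <- k + 1L
        if (k > length(s)) return(TRUE)
      }
    }
    FALSE
  }
  best <- 0L
  for (mask in 0:(2^length(a) - 1)) {
    s <- a[bitwAnd(mask, 2^(seq_along(a) - 1)) > 0]
    if (length(s) > best && is_subseq(s, b)) best <- length(s)
  }
  best
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")
random_aa <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY",
                                               "")[[1]], n, TRUE),
                               collapse = "")
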