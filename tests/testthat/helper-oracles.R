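# Independent reference implementations used to cross-check the package.
# These deliberately share no code with the implementation under test.

# All occurrences (overlapping) of each peptide in a query, by direct
# substring comparison: O(|query| * sum |peptides|).
naive_substring_hits <- function(query, peptides) {
  out <- list()
  for (p in peptides) {
    lp <- nchar(p)
    if (lp > nchar(query)) next
    for (i in seq_len(nchar(query) - lp + 1L)) {
      if (substr(query, i, i + lp - 1L) == p)
        out[[length(out) + 1L]] <- data.frame(peptide_seq = p, start = i,
                                              end = i + lp - 1L)
    }
  }
  if (length(out) == 0L)
    return(data.frame(peptide_seq = character(), start = integer(),
                      end = integer()))
  d <- do.call(rbind, out)
  d[order(d$start, d$end, d$peptide_seq), , drop = FALSE]
}

# Brute-force Gotoh dynamic program for the optimal affine-gap local
# alignment score. Gap of length L scores gap_open + L * gap_extend (both
# penalties negative). Returns max(H), floored at 0.
sw_score_oracle <- function(a, b, mat, gap_open = -10, gap_extend = -2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L)  # gap in query (consumes subject)
  F <- matrix(NEG, n + 1L, m + 1L)  # gap in subject
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] + gap_open + gap_extend,
                     E[i, j - 1L] + gap_extend)
      F[i, j] <- max(H[i - 1L, j] + gap_open + gap_extend,
                     F[i - 1L, j] + gap_extend)
      H[i, j] <- max(0,
                     H[i - 1L, j - 1L] + mat[A[i - 1L], B[j - 1L]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Naive window scans for the deamidation / EFSA motifs.
qxp_sites_oracle <- function(seq) {
  n <- nchar(seq)
  hits <- integer()
  if (n >= 3L) for (i in 1L:(n - 2L)) {
    w <- substr(seq, i, i + 2L)
    if (substr(w, 1, 1) == "Q" && substr(w, 2, 2) != "P" &&
        substr(w, 3, 3) == "P")
      hits <- c(hits, i)
  }
  hits
}

efsa_sites_oracle <- function(seq) {
  n <- nchar(seq)
  hits <- integer()
  if (n >= 4L) for (i in 1L:(n - 3L)) {
    if (substr(seq, i, i) %in% c("Q", "E") &&
        substr(seq, i + 2L, i + 2L) == "P")
      hits <- c(hits, i)
  }
  hits
}

random_aa <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
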