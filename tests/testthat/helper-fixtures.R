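# Shared fixtures and independent brute-force oracles. The oracles use
# plain loops and base arithmetic only, so they stay independent of the
# vectorized implementation they check.

BASES4 <- c("A", "C", "G", "T")

toy_set <- function(seqs, ids = NULL, start = 1L) {
  L <- nchar(seqs[1])
  if (is.null(ids)) ids <- paste0("p", seq_along(seqs))
  promstrength:::promoter_set(ids, seqs,
                              prom_window(start, start + L - 1L))
}

# the 4-sequence worked example used throughout the matrix/scoring tests
toy4 <- function() toy_set(c("ACG", "ACG", "ATG", "GCG"))

random_set <- function(n, L, start = 1L) {
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(BASES4, L, replace = TRUE), collapse = ""), character(1))
  toy_set(seqs, start = start)
}

# --- brute-force matrix oracles (per-cell loops) -------------------------

oracle_pfm <- function(set) {
  L <- set$window$length
  counts <- matrix(0L, L, 4, dimnames = list(NULL, BASES4))
  for (s in set$sequences)
    for (i in seq_len(L)) {
      b <- substr(s, i, i)
      counts[i, b] <- counts[i, b] + 1L
    }
  counts
}

oracle_ppm <- function(counts, n, pc) {
  probs <- counts
  for (i in seq_len(nrow(counts)))
    for (j in 1:4)
      probs[i, j] <- (counts[i, j] + pc) / (n + 4 * pc)
  probs
}

oracle_pssm <- function(probs, bg) {
  vals <- probs
  for (i in seq_len(nrow(probs)))
    for (j in 1:4)
      vals[i, j] <- log2(probs[i, j] / bg[j])
  vals
}

oracle_score <- function(pssm, seq, from, to) {
  total <- 0
  for (p in from:to) {
    i <- window_index(pssm$window, p)
    total <- total + unname(pssm$values[i, substr(seq, i, i)])
  }
  total
}

# sample() treats a length-1 vector as 1:x; this always samples elements
pick1 <- function(x) x[sample.int(length(x), 1)]

# a pseudocounted PSSM over a random set, safe for scoring anything
random_pssm <- function(n = 30, L = 8, pc = 0.5) {
  set <- random_set(n, L)
  ppm_to_pssm(pfm_to_ppm(build_pfm(set), pc))
}

write_toy_fasta <- function(seqs, ids = paste0("p", seq_along(seqs)),
                            path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}
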