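BASES <- c("A", "C", "G", "T")

#' Build a position frequency matrix from an aligned promoter set
#'
#' Tallies the bases seen at every window position across all promoters in
#' the set. Because the sequences are pre-aligned at the TSS, no alignment is
#' performed: column j of the result counts bases at TSS-relative position
#' `index_position(window, j)`.
#'
#' @param promoters A `promoter_set` from [read_promoter_fasta()] or
#'   [generate_promoter_set()].
#' @return A `prom_pfm`: list with `window`, `counts` (L x 4 integer matrix,
#'   columns A,C,G,T in fixed order; rows are window positions) and
#'   `n_sequences`. Every row of `counts` sums to `n_sequences`.
#' @export
build_pfm <- function(promoters) {
  if (!inherits(promoters, "promoter_set"))
    stop("promoters must be a promoter_set", call. = FALSE)
  n <- length(promoters)
  if (n == 0L) stop("cannot build a PFM from an empty set", call. = FALSE)
  L <- promoters$window$length
  chars <- matrix(unlist(strsplit(promoters$sequences, ""), use.names = FALSE),
                  nrow = L)
  counts <- vapply(BASES, function(b) .rowSums(chars == b, L, n),
                   numeric(L))
  counts <- matrix(as.integer(counts), nrow = L,
                   dimnames = list(NULL, BASES))
  structure(list(window = promoters$window, counts = counts,
                 n_sequences = n),
            class = "prom_pfm")
}

#' Convert a frequency matrix to a probability matrix
#'
#' Each count is incremented by `pseudocount` and the position is
#' renormalized: `prob = (count + pseudocount) / (n + 4 * pseudocount)`.
#' With `pseudocount = 0` a base never observed at a position gets
#' probability 0 (and later -Inf in the scoring matrix); a positive
#' pseudocount guarantees strictly positive probabilities.
#'
#' @param pfm A `prom_pfm`.
#' @param pseudocount Non-negative real added to every cell; default 0.
#' @return A `prom_ppm`: list with `window`, `probs` (L x 4, rows sum to 1)
#'   and `pseudocount`.
#' @export
pfm_to_ppm <- function(pfm, pseudocount = 0) {
  if (!inherits(pfm, "prom_pfm")) stop("pfm must be a prom_pfm", call. = FALSE)
  if (length(pseudocount) != 1L || is.na(pseudocount) || pseudocount < 0)
    stop("pseudocount must be a single non-negative number", call. = FALSE)
  probs <- (pfm$counts + pseudocount) / (pfm$n_sequences + 4 * pseudocount)
  dimnames(probs) <- list(NULL, BASES)
  structure(list(window = pfm$window, probs = probs,
                 pseudocount = pseudocount),
            class = "prom_ppm")
}

#' Convert a probability matrix to a log-odds scoring matrix
#'
#' Computes per-position log-odds in bits against a background base
#' distribution: `value = log2(prob / background)`. Cells with zero
#' probability map to -Inf and the matrix is flagged (`has_neg_inf`);
#' [segment_score()] refuses to silently return -Inf for a query that hits
#' such a cell.
#'
#' @param ppm A `prom_ppm`.
#' @param background Length-4 positive vector summing to 1, in A,C,G,T
#'   order; default uniform (0.25 each).
#' @return A `prom_pssm`: list with `window`, `values` (L x 4 log-odds in
#'   bits), `background` and `has_neg_inf`.
#' @export
ppm_to_pssm <- function(ppm, background = rep(0.25, 4)) {
  if (!inherits(ppm, "prom_ppm")) stop("ppm must be a prom_ppm", call. = FALSE)
  background <- as.numeric(background)
  if (length(background) != 4L || any(!is.finite(background)) ||
      any(background <= 0) || abs(sum(background) - 1) > 1e-9)
    stop("background must be 4 strictly positive values summing to 1",
         call. = FALSE)
  values <- log2(sweep(ppm$probs, 2L, background, "/"))
  dimnames(values) <- list(NULL, BASES)
  structure(list(window = ppm$window, values = values,
                 background = stats::setNames(background, BASES),
                 has_neg_inf = any(is.infinite(values))),
            class = "prom_pssm")
}

#' Per-position information content of a probability matrix
#'
#' The sequence-logo height of each position, in bits:
#' `IC(p) = 2 + sum_b prob(p,b) * log2(prob(p,b))` with `0*log2(0) := 0`.
#' Ranges from 0 (uniform, no conservation) to 2 (a single base fixed).
#' This is the tabular equivalent of a motif logo of the promoter
#' population; for the yeast core promoter it highlights the conserved
#' stretch just upstream of the TSS.
#'
#' @param ppm A `prom_ppm`.
#' @return Data frame with columns `position` (TSS-relative) and
#'   `information_bits`.
#' @export
information_content <- function(ppm) {
  if (!inherits(ppm, "prom_ppm")) stop("ppm must be a prom_ppm", call. = FALSE)
  p <- ppm$probs
  plogp <- ifelse(p > 0, p * log2(p), 0)
  ic <- 2 + rowSums(plogp)
  ic <- pmin(pmax(ic, 0), 2)  # clip roundoff at the boundaries
  data.frame(position = index_position(ppm$window, seq_len(ppm$window$length)),
             information_bits = ic)
}

#' Write a position matrix to TSV with a JSON sidecar
#'
#' One row per window position, columns `position`, `A`, `C`, `G`, `T`; the
#' sidecar `<path>.json` records the window, the matrix kind, and (where
#' applicable) pseudocount, background and number of sequences so every
#' matrix file is traceable.
#'
#' @param m A `prom_pfm`, `prom_ppm` or `prom_pssm`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  kind <- c(prom_pfm = "pfm", prom_ppm = "ppm", prom_pssm = "pssm")[class(m)[1]]
  if (is.na(kind)) stop("not a promoter matrix object", call. = FALSE)
  vals <- switch(kind, pfm = m$counts, ppm = m$probs, pssm = m$values)
  df <- data.frame(position = index_position(m$window, seq_len(m$window$length)))
  df <- cbind(df, as.data.frame(vals))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(kind = kind,
               window = list(start = m$window$start, end = m$window$end),
               base_order = BASES)
  if (kind == "pfm") meta$n_sequences <- m$n_sequences
  if (kind == "ppm") meta$pseudocount <- m$pseudocount
  if (kind == "pssm") {
    meta$background <- as.numeric(m$background)
    meta$has_neg_inf <- m$has_neg_inf
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a scoring matrix written by [write_matrix_tsv()]
#'
#' @param path TSV path; `<path>.json` must exist alongside.
#' @return A `prom_pssm`.
#' @export
read_pssm_tsv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$kind, "pssm"))
    stop("matrix file is a ", meta$kind, ", not a pssm", call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  w <- prom_window(meta$window$start, meta$window$end)
  values <- as.matrix(df[, BASES])
  dimnames(values) <- list(NULL, BASES)
  structure(list(window = w, values = values,
                 background = stats::setNames(as.numeric(meta$background),
                                              BASES),
                 has_neg_inf = isTRUE(meta$has_neg_inf)),
            class = "prom_pssm")
}
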