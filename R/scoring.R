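#' A sub-segment of the core-promoter window
#'
#' TSS-relative, inclusive on both ends, e.g. `prom_segment(-49, -1)` is the
#' 49 bp upstream of the TSS and `prom_segment(-9, -1)` the most conserved
#' stretch of the yeast core promoter.
#'
#' @param from_pos,to_pos Integer TSS-relative positions, `from_pos <=
#'   to_pos`.
#' @return A `prom_segment`.
#' @export
prom_segment <- function(from_pos, to_pos) {
  from_pos <- as.integer(from_pos)
  to_pos <- as.integer(to_pos)
  if (is.na(from_pos) || is.na(to_pos) || from_pos > to_pos)
    stop("segment requires from_pos <= to_pos", call. = FALSE)
  structure(list(from_pos = from_pos, to_pos = to_pos),
            class = "prom_segment")
}

check_segment <- function(segment, window) {
  if (segment$from_pos < window$start || segment$to_pos > window$end)
    stop(sprintf("segment %+d..%+d outside window %+d..%+d",
                 segment$from_pos, segment$to_pos,
                 window$start, window$end), call. = FALSE)
  invisible(segment)
}

base_index_matrix <- function(sequences, L) {
  chars <- matrix(unlist(strsplit(sequences, ""), use.names = FALSE),
                  nrow = L)
  idx <- match(chars, BASES)
  if (anyNA(idx)) {
    pos <- which(is.na(matrix(idx, nrow = L)), arr.ind = TRUE)
    stop(sprintf("non-ACGT character at window index %d of sequence %d",
                 pos[1, 1], pos[1, 2]), call. = FALSE)
  }
  matrix(idx, nrow = L)
}

#' Log-odds score of a promoter segment
#'
#' The segment score is the sum, over every position of the segment, of the
#' scoring-matrix value for the base the promoter carries at that position.
#' It is exactly additive: partitioning a segment into consecutive pieces
#' and summing their scores reproduces the segment score.
#'
#' @param pssm A `prom_pssm`.
#' @param sequence A single window-length string over A/C/G/T (or a
#'   one-record `promoter_set`).
#' @param segment A [prom_segment()] inside the matrix window; default the
#'   full window.
#' @return Raw score in bits (a single number).
#' @export
segment_score <- function(pssm, sequence,
                          segment = prom_segment(pssm$window$start,
                                                 pssm$window$end)) {
  if (inherits(sequence, "promoter_set")) {
    if (length(sequence) != 1L)
      stop("pass a single sequence (or use score_set)", call. = FALSE)
    sequence <- sequence$sequences
  }
  scores <- segment_score_many(pssm, sequence, segment)
  scores[[1L]]
}

segment_score_many <- function(pssm, sequences, segment) {
  check_segment(segment, pssm$window)
  L <- pssm$window$length
  if (any(nchar(sequences) != L))
    stop("sequence length must equal the matrix window length (", L, ")",
         call. = FALSE)
  bidx <- base_index_matrix(toupper(sequences), L)
  rows <- window_index(pssm$window, segment$from_pos):
    window_index(pssm$window, segment$to_pos)
  vals <- pssm$values[rows, , drop = FALSE]
  per_seq <- vapply(seq_len(ncol(bidx)), function(j) {
    v <- vals[cbind(seq_along(rows), bidx[rows, j])]
    if (any(is.infinite(v)))
      stop(sprintf(
        "sequence %d hits a zero-probability matrix cell at position %+d; rebuild the matrix with a pseudocount > 0",
        j, index_position(pssm$window, rows[which(is.infinite(v))[1L]])),
        call. = FALSE)
    sum(v)
  }, numeric(1))
  per_seq
}

#' Score every promoter in a set and normalize by the reference promoter
#'
#' Computes the raw segment score for each promoter and divides it by the
#' raw score of the reference promoter on the *same* segment, so the
#' reference always has normalized score 1. The reference is identified by
#' id (pTDH3 by default), never re-detected as the maximum, so adding
#' promoters cannot silently change the normalizer; a warning is emitted if
#' any promoter outscores the reference. Negative log-odds scores are
#' allowed and keep their sign through normalization.
#'
#' @param pssm A `prom_pssm`.
#' @param promoters A `promoter_set` (must contain `reference_id`).
#' @param segment A [prom_segment()]; default the full window.
#' @param reference_id Id of the normalizing promoter.
#' @return Data frame with columns `id`, `segment_from`, `segment_to`,
#'   `raw_score`, `normalized_score`, in input order.
#' @export
score_set <- function(pssm, promoters,
                      segment = prom_segment(pssm$window$start,
                                             pssm$window$end),
                      reference_id = "pTDH3") {
  if (!inherits(promoters, "promoter_set"))
    stop("promoters must be a promoter_set", call. = FALSE)
  ref <- match(reference_id, promoters$ids)
  if (is.na(ref))
    stop("reference promoter '", reference_id, "' not in the set",
         call. = FALSE)
  raw <- segment_score_many(pssm, promoters$sequences, segment)
  ref_raw <- raw[ref]
  if (ref_raw == 0)
    stop("reference promoter '", reference_id,
         "' has raw score 0 on this segment; normalization undefined",
         call. = FALSE)
  if (any(raw > ref_raw))
    warning(sum(raw > ref_raw), " promoter(s) outscore the reference '",
            reference_id, "' on this segment", call. = FALSE)
  data.frame(id = promoters$ids,
             segment_from = segment$from_pos,
             segment_to = segment$to_pos,
             raw_score = raw,
             normalized_score = raw / ref_raw)
}
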