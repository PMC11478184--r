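#' Core-promoter window relative to the transcription start site
#'
#' Defines the fixed coordinate frame shared by every other function in the
#' package. Positions are counted relative to the transcription start site
#' (TSS), which sits at position 0; both ends are inclusive. The default
#' window, -49..+10, spans exactly 60 bp and matches the core-promoter
#' extract distributed by the Eukaryotic Promoter Database for
#' *S. cerevisiae*.
#'
#' @param start Integer, first position of the window (TSS-relative).
#' @param end Integer, last position of the window (TSS-relative, inclusive).
#' @return An object of class `prom_window` with fields `start`, `end` and
#'   `length`.
#' @examples
#' w <- prom_window()
#' w$length            # 60
#' window_index(w, 0)  # the TSS is column 50 of the matrix
#' @export
prom_window <- function(start = -49L, end = 10L) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("window start and end must be single integers", call. = FALSE)
  if (start > end)
    stop("window start must not exceed end", call. = FALSE)
  structure(
    list(start = start, end = end, length = end - start + 1L),
    class = "prom_window"
  )
}

#' @export
print.prom_window <- function(x, ...) {
  cat(sprintf("<prom_window> %+d..%+d (%d bp, TSS at 0)\n",
              x$start, x$end, x$length))
  invisible(x)
}

#' Map a TSS-relative position to a 1-based matrix column
#'
#' The map is total and invertible on the window: position `window$start`
#' maps to 1 and position `window$end` maps to `window$length`.
#'
#' @param window A [prom_window()].
#' @param pos Integer vector of TSS-relative positions.
#' @return Integer vector of 1-based indices.
#' @export
window_index <- function(window, pos) {
  pos <- as.integer(pos)
  if (any(pos < window$start | pos > window$end))
    stop("position outside window ", window$start, "..", window$end,
         call. = FALSE)
  pos - window$start + 1L
}

#' Inverse of [window_index()]
#' @param window A [prom_window()].
#' @param idx Integer vector of 1-based indices.
#' @return Integer vector of TSS-relative positions.
#' @export
index_position <- function(window, idx) {
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > window$length))
    stop("index outside 1..", window$length, call. = FALSE)
  window$start + idx - 1L
}

promoter_set <- function(ids, sequences, window) {
  structure(
    list(window = window, ids = as.character(ids),
         sequences = as.character(sequences)),
    class = "promoter_set"
  )
}

#' @export
length.promoter_set <- function(x) length(x$ids)

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("<promoter_set> %d promoters, window %+d..%+d (%d bp)\n",
              length(x), x$window$start, x$window$end, x$window$length))
  invisible(x)
}

#' Subset a promoter set
#' @param x A `promoter_set`.
#' @param i Index vector (integer, logical, or character ids).
#' @param ... Ignored.
#' @export
`[.promoter_set` <- function(x, i, ...) {
  if (is.character(i)) {
    i <- match(i, x$ids)
    if (anyNA(i)) stop("unknown promoter id(s)", call. = FALSE)
  }
  promoter_set(x$ids[i], x$sequences[i], x$window)
}

#' Read a set of fixed-window core-promoter sequences from FASTA
#'
#' Reads a multi-record FASTA of equal-length promoter windows aligned at the
#' TSS (for example an EPD core-promoter extract). Sequences are uppercased;
#' the record id is the first whitespace-delimited token of the header.
#' Records whose length differs from the window or that contain characters
#' outside A/C/G/T (including IUPAC ambiguity codes such as N) are either a
#' hard error (`on_invalid = "reject"`, the default) or dropped with a
#' message reporting the number skipped (`on_invalid = "skip"`).
#'
#' @param path Path to a FASTA file.
#' @param window A [prom_window()]; every record must have this length.
#' @param on_invalid `"reject"` or `"skip"`.
#' @return A `promoter_set`.
#' @export
read_promoter_fasta <- function(path, window = prom_window(),
                                on_invalid = c("reject", "skip")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path))
    stop("cannot read FASTA file: ", path, call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L)
    stop("FASTA file contains no records: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(seqs), "[[:space:]]+"), `[`, character(1), 1L)
  sq <- toupper(as.character(seqs))
  bad_len <- nchar(sq) != window$length
  bad_chr <- grepl("[^ACGT]", sq)
  bad <- bad_len | bad_chr
  if (any(bad)) {
    if (on_invalid == "reject") {
      first <- which(bad)[1L]
      why <- if (bad_len[first])
        sprintf("length %d != window length %d", nchar(sq[first]),
                window$length)
      else "contains non-ACGT characters"
      stop(sprintf("invalid record '%s': %s (and %d other invalid record(s))",
                   ids[first], why, sum(bad) - 1L), call. = FALSE)
    }
    message(sprintf("read_promoter_fasta: skipped %d invalid record(s) (%d wrong length, %d non-ACGT)",
                    sum(bad), sum(bad_len), sum(bad_chr & !bad_len)))
    ids <- ids[!bad]
    sq <- sq[!bad]
  }
  if (length(sq) == 0L)
    stop("no valid promoter records remain after filtering", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate promoter ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  promoter_set(ids, sq, window)
}

#' Write a promoter set to FASTA
#'
#' Inverse of [read_promoter_fasta()]: writing then re-reading reproduces
#' ids and sequences exactly.
#'
#' @param promoters A `promoter_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(promoters, path) {
  x <- Biostrings::DNAStringSet(promoters$sequences)
  names(x) <- promoters$ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a reference promoter-strength table
#'
#' Reads a tab-separated table with a header naming at least `id`, `channel`
#' and one (or both) of `fold_over_background` and `strength`. Each row ties
#' one promoter, in one fluorescence channel (e.g. Venus, mRuby2,
#' mTurquoise2) or dataset tag, to either the raw reporter fluorescence
#' folded over background autofluorescence, or a pre-computed normalized
#' strength. Lines starting with `#` are ignored.
#'
#' @param path Path to the TSV file.
#' @param reference_id Identifier of the normalizing promoter; the strongest
#'   constitutive promoter pTDH3 by default.
#' @return A `strength_table`: a data frame with columns `id`, `channel`,
#'   and `fold_over_background` and/or `strength`, carrying the reference id
#'   as an attribute.
#' @export
read_strength_table <- function(path, reference_id = "pTDH3") {
  if (!file.exists(path))
    stop("cannot read strength table: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("id", "channel")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("strength table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  has_fold <- "fold_over_background" %in% names(df)
  has_str <- "strength" %in% names(df)
  if (!has_fold && !has_str)
    stop("strength table needs a 'fold_over_background' or 'strength' column",
         call. = FALSE)
  if (has_fold) {
    df$fold_over_background <- parse_strict_numeric(df$fold_over_background,
                                                    "fold_over_background")
    bad <- !is.na(df$fold_over_background) & df$fold_over_background <= 0
    if (any(bad))
      stop("non-positive fold_over_background for id(s): ",
           paste(df$id[bad], collapse = ", "),
           " (log-strength undefined)", call. = FALSE)
  }
  if (has_str)
    df$strength <- parse_strict_numeric(df$strength, "strength")
  present <- rep(FALSE, nrow(df))
  if (has_fold) present <- present | !is.na(df$fold_over_background)
  if (has_str) present <- present | !is.na(df$strength)
  if (any(!present))
    stop("rows with neither fold_over_background nor strength: id(s) ",
         paste(df$id[!present], collapse = ", "), call. = FALSE)
  structure(df, reference_id = reference_id,
            class = c("strength_table", "data.frame"))
}

parse_strict_numeric <- function(x, what) {
  if (is.numeric(x)) return(x)
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !(is.na(x) | x == "" | x == "NA")
  if (any(bad))
    stop("non-numeric value in column '", what, "': ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  out
}

#' Write a strength table to TSV
#' @param table A `strength_table` (or plain data frame with the same
#'   columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_strength_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
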