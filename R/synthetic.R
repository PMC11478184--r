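#' Specification of a synthetic promoter study
#'
#' Bundles every parameter needed to simulate a promoter population and a
#' matched strength table with known ground truth, so each stage of the
#' pipeline can be tested against the values that generated the data.
#' Defaults mirror the shape of the real study: an 18-promoter labelled set
#' drawn from a 2000-sequence background population, strengths linear in
#' the normalized full-window score with true parameters (0.025, 0.87) and
#' Gaussian noise of sd 0.05.
#'
#' A single `seed` drives the whole simulation; sequence generation and
#' noise generation use independent sub-streams derived from it by fixed
#' offsets, so regenerating sequences never perturbs the noise draws.
#'
#' @param n_sequences Number of background promoter sequences.
#' @param window A [prom_window()].
#' @param base_composition Length-4 probabilities (A,C,G,T order) summing
#'   to 1 used at unconstrained positions.
#' @param conserved_positions Optional data frame with columns `position`
#'   (TSS-relative), `base` (one of A/C/G/T) and `level` in (0.25, 1]: at
#'   each such position the named base is drawn with probability `level`
#'   and the other three bases share the remainder evenly.
#' @param true_C0,true_C1 Ground-truth linear model parameters.
#' @param noise_sd Standard deviation of the Gaussian noise added to
#'   generated strengths.
#' @param n_labeled Size of the labelled subset used for fitting.
#' @param seed Integer seed.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_sequences = 2000L, window = prom_window(),
                           base_composition = rep(0.25, 4),
                           conserved_positions = NULL,
                           true_C0 = 0.025, true_C1 = 0.87,
                           noise_sd = 0.05, n_labeled = 18L, seed = 1L) {
  base_composition <- as.numeric(base_composition)
  if (length(base_composition) != 4L || any(base_composition < 0) ||
      abs(sum(base_composition) - 1) > 1e-9)
    stop("base_composition must be 4 non-negative values summing to 1",
         call. = FALSE)
  if (!is.null(conserved_positions)) {
    cp <- conserved_positions
    stopifnot(is.data.frame(cp),
              all(c("position", "base", "level") %in% names(cp)))
    if (!all(cp$base %in% BASES))
      stop("conserved base must be one of A/C/G/T", call. = FALSE)
    if (any(cp$level <= 0.25 | cp$level > 1))
      stop("conservation level must lie in (0.25, 1]", call. = FALSE)
    if (any(cp$position < window$start | cp$position > window$end))
      stop("conserved position outside window", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(n_sequences = as.integer(n_sequences), window = window,
                 base_composition = base_composition,
                 conserved_positions = conserved_positions,
                 true_C0 = true_C0, true_C1 = true_C1,
                 noise_sd = noise_sd, n_labeled = as.integer(n_labeled),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# independent sub-streams from one user seed, kept below 2^31
stream_seed <- function(spec, stream) {
  offset <- c(sequences = 101L, noise = 202L)[[stream]]
  (spec$seed * 1009L + offset) %% 2147483647L
}

#' Generate a synthetic promoter population
#'
#' Draws `n_sequences` window-length sequences with bases sampled
#' independently per position from `base_composition`, except at conserved
#' positions where the named base appears with the stated probability and
#' the remaining probability splits evenly over the other three bases.
#' Fully deterministic given `spec$seed`. Ids are `syn0001`, `syn0002`, ...
#'
#' @param spec A [synthetic_spec()].
#' @return A `promoter_set`.
#' @export
generate_promoter_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  L <- spec$window$length
  n <- spec$n_sequences
  if (n < 1L) stop("n_sequences must be positive", call. = FALSE)
  probs <- matrix(spec$base_composition, nrow = L, ncol = 4, byrow = TRUE)
  if (!is.null(spec$conserved_positions)) {
    for (k in seq_len(nrow(spec$conserved_positions))) {
      row <- window_index(spec$window, spec$conserved_positions$position[k])
      lev <- spec$conserved_positions$level[k]
      p <- rep((1 - lev) / 3, 4)
      p[match(spec$conserved_positions$base[k], BASES)] <- lev
      probs[row, ] <- p
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(spec, "sequences"))
  # one multinomial column per position, shared across sequences
  mat <- vapply(seq_len(L), function(i)
    sample.int(4L, n, replace = TRUE, prob = probs[i, ]), integer(n))
  seqs <- apply(mat, 1L, function(r) paste(BASES[r], collapse = ""))
  ids <- sprintf("syn%04d", seq_len(n))
  promoter_set(ids, seqs, spec$window)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate ground-truth strengths for a labelled promoter subset
#'
#' Realizes the linear model generatively: each selected promoter's
#' strength is `true_C0 + true_C1 * normalized_score + eps`, with
#' `eps ~ Normal(0, noise_sd^2)` drawn from the noise sub-stream of
#' `spec$seed`, and the normalized score computed on `segment` against
#' `reference_id`. The labelled subset is the first `spec$n_labeled`
#' promoters of `promoters` unless `ids` is given; the reference is always
#' included.
#'
#' @param promoters A `promoter_set` (typically from
#'   [generate_promoter_set()]).
#' @param pssm A `prom_pssm` used to score the promoters.
#' @param spec The [synthetic_spec()] holding `true_C0`, `true_C1`,
#'   `noise_sd` and the seed.
#' @param reference_id Id of the normalizing promoter; defaults to the
#'   top-scoring labelled promoter (mimicking pTDH3, the strongest
#'   reference).
#' @param ids Optional explicit labelled ids.
#' @param segment Segment whose score generates strength; default full
#'   window.
#' @param channel Channel label stamped on the table.
#' @param as_fold If `TRUE`, emit raw `fold_over_background` values instead
#'   of strengths, by inverting the log-ratio transform with the reference
#'   pinned at `exp(ref_ln_fold)`: `fold_i = exp(strength_i * ref_ln_fold)`.
#'   [strengths_from_fold()] then recovers the generated strengths exactly.
#' @param ref_ln_fold Natural-log fold of the reference promoter used by
#'   `as_fold`; default 4 (fold ~ 54.6, a bright constitutive reporter).
#' @return A `strength_table` with columns `id`, `channel`, and `strength`
#'   or `fold_over_background`; the reference id is carried as an
#'   attribute, and the noiseless true strengths as attribute
#'   `"true_strength"`.
#' @export
generate_strengths <- function(promoters, pssm, spec, reference_id = NULL,
                               ids = NULL,
                               segment = prom_segment(pssm$window$start,
                                                      pssm$window$end),
                               channel = "synthetic", as_fold = FALSE,
                               ref_ln_fold = 4) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(ids))
    ids <- promoters$ids[seq_len(min(spec$n_labeled, length(promoters)))]
  if (!is.null(reference_id)) ids <- unique(c(ids, reference_id))
  sub <- promoters[ids]
  if (is.null(reference_id)) {
    raw <- segment_score_many(pssm, sub$sequences, segment)
    if (all(raw == 0))
      stop("all labelled promoters score 0; cannot pick a reference",
           call. = FALSE)
    reference_id <- sub$ids[which.max(raw)]
  }
  sc <- suppressWarnings(
    score_set(pssm, sub, segment, reference_id = reference_id))
  true_strength <- spec$true_C0 + spec$true_C1 * sc$normalized_score
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(spec, "noise"))
  eps <- stats::rnorm(nrow(sc), mean = 0, sd = spec$noise_sd)
  strength <- true_strength + eps
  if (as_fold) {
    fold <- exp(strength * ref_ln_fold)
    # pin the reference exactly at exp(ref_ln_fold) so the inverse
    # transform normalizes by the intended quantity
    fold[sc$id == reference_id] <- exp(ref_ln_fold)
    df <- data.frame(id = sc$id, channel = channel,
                     fold_over_background = fold)
  } else {
    df <- data.frame(id = sc$id, channel = channel, strength = strength)
  }
  structure(df, reference_id = reference_id,
            true_strength = true_strength,
            true_C0 = spec$true_C0, true_C1 = spec$true_C1,
            class = c("strength_table", "data.frame"))
}
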