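#' Promoter strengths from fluorescence fold-over-background
#'
#' The strength of a promoter in a given reporter channel is the natural log
#' of its fluorescence fold-over-background, divided by the same quantity
#' for the reference promoter: `strength_i = ln(fold_i) / ln(fold_ref)`.
#' The reference (pTDH3, the strongest constitutive promoter in the
#' characterized set) therefore maps to strength 1 by construction. Rows
#' that already carry a pre-computed `strength` are passed through
#' unchanged.
#'
#' @param table A `strength_table` from [read_strength_table()].
#' @param channel Which fluorescence channel / dataset tag to extract.
#' @return A `strength_vector`: data frame with columns `id` and `strength`,
#'   with the channel and reference id as attributes.
#' @export
strengths_from_fold <- function(table, channel) {
  reference_id <- attr(table, "reference_id")
  if (is.null(reference_id)) reference_id <- "pTDH3"
  df <- as.data.frame(table)
  df <- df[df$channel == channel, , drop = FALSE]
  if (nrow(df) == 0L)
    stop("no rows for channel '", channel, "'", call. = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicate ids within channel '", channel, "'", call. = FALSE)
  has_fold <- "fold_over_background" %in% names(df) &&
    any(!is.na(df$fold_over_background))
  if (has_fold) {
    if (any(is.na(df$fold_over_background)))
      stop("channel '", channel, "' mixes fold and strength rows",
           call. = FALSE)
    ref <- match(reference_id, df$id)
    if (is.na(ref))
      stop("reference '", reference_id, "' absent from channel '", channel,
           "'", call. = FALSE)
    ref_fold <- df$fold_over_background[ref]
    if (ref_fold <= 1)
      stop("reference fold-over-background must exceed 1 (ln(ref) > 0 needed)",
           call. = FALSE)
    strength <- log(df$fold_over_background) / log(ref_fold)
  } else {
    if (!"strength" %in% names(df) || any(is.na(df$strength)))
      stop("channel '", channel, "' has neither complete fold nor strength",
           call. = FALSE)
    strength <- df$strength
  }
  structure(data.frame(id = df$id, strength = strength),
            channel = channel, reference_id = reference_id,
            class = c("strength_vector", "data.frame"))
}

#' Fit the linear score-to-strength model with full OLS diagnostics
#'
#' Fits `strength = C0 + C1 * score` by closed-form simple ordinary least
#' squares on the promoters present in both inputs, and reports the
#' diagnostics used to judge the fit: coefficient standard errors,
#' t-statistics and two-sided p-values, R-squared and adjusted R-squared,
#' the F-statistic with its p-value (df 1 and n-2), the residuals, the slope
#' of a second OLS of residuals on scores (a bias check; identically 0 for
#' any OLS fit with intercept), and normal QQ pairs of the residuals using
#' plotting positions `(i - 0.5)/n`.
#'
#' A degenerate perfect fit (zero residual variance) reports `r2 = 1` with
#' standard errors, t and F set to `NA` and `degenerate = TRUE` rather than
#' emitting infinities.
#'
#' @param scores Data frame with columns `id` and `normalized_score`
#'   (e.g. from [score_set()]).
#' @param strengths A `strength_vector` (or data frame with `id`,
#'   `strength`).
#' @return A `prom_fit` with fields `C0`, `C1`, `se_C0`, `se_C1`, `t_C0`,
#'   `t_C1`, `p_C0`, `p_C1`, `r2`, `adj_r2`, `F`, `p_F`, `n`, `residuals`
#'   (data frame id/residual), `residual_slope`, `qq` (data frame
#'   theoretical/sample), `degenerate`.
#' @export
fit_linear <- function(scores, strengths) {
  m <- merge(scores[, c("id", "normalized_score")],
             as.data.frame(strengths)[, c("id", "strength")],
             by = "id", sort = FALSE)
  n <- nrow(m)
  if (n < 3L)
    stop("need at least 3 promoters present in both scores and strengths (got ",
         n, ")", call. = FALSE)
  x <- m$normalized_score
  y <- m$strength
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0)
    stop("all scores identical; slope is unidentifiable", call. = FALSE)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  C1 <- sxy / sxx
  C0 <- mean(y) - C1 * mean(x)
  res <- y - (C0 + C1 * x)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
  degenerate <- rss <= 1e-14 * max(tss, 1)
  if (degenerate) {
    r2 <- 1
    se_C0 <- se_C1 <- t_C0 <- t_C1 <- p_C0 <- p_C1 <- Fstat <- p_F <- NA_real_
  } else {
    sigma2 <- rss / (n - 2)
    se_C1 <- sqrt(sigma2 / sxx)
    se_C0 <- sqrt(sigma2 * (1 / n + mean(x)^2 / sxx))
    t_C0 <- C0 / se_C0
    t_C1 <- C1 / se_C1
    p_C0 <- 2 * stats::pt(abs(t_C0), df = n - 2, lower.tail = FALSE)
    p_C1 <- 2 * stats::pt(abs(t_C1), df = n - 2, lower.tail = FALSE)
    Fstat <- (r2 / 1) / ((1 - r2) / (n - 2))
    p_F <- stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  }
  ord <- order(res)
  qq <- data.frame(
    theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
    sample = res[ord]
  )
  # second regression of residuals on scores; exact orthogonality makes
  # this 0 up to roundoff, reported as the bias check
  residual_slope <- sum((x - mean(x)) * (res - mean(res))) / sxx
  structure(list(C0 = C0, C1 = C1, se_C0 = se_C0, se_C1 = se_C1,
                 t_C0 = t_C0, t_C1 = t_C1, p_C0 = p_C0, p_C1 = p_C1,
                 r2 = r2, adj_r2 = adj_r2, F = Fstat, p_F = p_F, n = n,
                 residuals = data.frame(id = m$id, residual = res),
                 residual_slope = residual_slope, qq = qq,
                 degenerate = degenerate),
            class = "prom_fit")
}

#' @export
print.prom_fit <- function(x, ...) {
  cat("<prom_fit> strength = C0 + C1 * score\n")
  cat(sprintf("  C0 = %.4g (SE %.3g, p = %.3g)\n", x$C0, x$se_C0, x$p_C0))
  cat(sprintf("  C1 = %.4g (SE %.3g, p = %.3g)\n", x$C1, x$se_C1, x$p_C1))
  cat(sprintf("  n = %d, R2 = %.4f, adj. R2 = %.4f, F = %.3g (p = %.3g)\n",
              x$n, x$r2, x$adj_r2, x$F, x$p_F))
  if (isTRUE(x$degenerate))
    cat("  perfect fit: standard errors undefined\n")
  invisible(x)
}

#' Serialize a fit report to JSON (+ residual TSV)
#'
#' @param fit A `prom_fit`.
#' @param path Output JSON path; residuals go to `<path without
#'   .json>_residuals.tsv`.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  out <- fit[c("C0", "C1", "se_C0", "se_C1", "t_C0", "t_C1", "p_C0", "p_C1",
               "r2", "adj_r2", "F", "p_F", "n", "residual_slope",
               "degenerate")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  res_path <- paste0(sub("\\.json$", "", path), "_residuals.tsv")
  utils::write.table(fit$residuals, res_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Segment-endpoint scan of the linear model
#'
#' Fixes the left end of the scored segment at the window start (-49 by
#' default) and grows the segment one nucleotide at a time towards the TSS
#' and beyond: for each endpoint X the model is refit on the scores of
#' segment `[left, X]`. The resulting table of fit quality versus X locates
#' the minimal region needed to predict strength — on real yeast data the
#' fit stops improving near X = -1.
#'
#' Promoter scores are renormalized by the reference promoter's score on
#' each segment. Rows where the fit fails (e.g. zero score variance) are
#' flagged `ok = FALSE` rather than aborting the scan.
#'
#' @param pssm A `prom_pssm`.
#' @param promoters A `promoter_set` containing every id in `strengths` and
#'   the reference.
#' @param strengths A `strength_vector`.
#' @param reference_id Normalizing promoter id; defaults to the attribute
#'   carried by `strengths`, or "pTDH3".
#' @param left Fixed left endpoint; must equal the window start.
#' @return A `prom_scan`: data frame with one row per X in
#'   `(left+1)..window$end` and columns `X`, `C0`, `C1`, `se_C0`, `se_C1`,
#'   `r2`, `adj_r2`, `F`, `p_F`, `ok`; the full `prom_fit` objects are
#'   attached as attribute `"fits"` (named by X).
#' @export
scan_endpoints <- function(pssm, promoters, strengths,
                           reference_id = NULL, left = pssm$window$start) {
  if (left != pssm$window$start)
    stop("scan must anchor at the window start (", pssm$window$start, ")",
         call. = FALSE)
  if (is.null(reference_id))
    reference_id <- attr(strengths, "reference_id") %||% "pTDH3"
  ids <- as.data.frame(strengths)$id
  missing_ids <- setdiff(c(ids, reference_id), promoters$ids)
  if (length(missing_ids))
    stop("promoter set lacks sequence(s) for: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  sub <- promoters[unique(c(ids, reference_id))]
  L <- pssm$window$length
  bidx <- base_index_matrix(toupper(sub$sequences), L)
  per_pos <- vapply(seq_len(ncol(bidx)), function(j)
    pssm$values[cbind(seq_len(L), bidx[, j])], numeric(L))
  if (any(is.infinite(per_pos)))
    stop("a promoter hits a zero-probability matrix cell; rebuild the matrix with a pseudocount > 0",
         call. = FALSE)
  cum <- apply(per_pos, 2L, cumsum)  # cum[k, j]: score of [left, left+k-1]
  ref_col <- match(reference_id, sub$ids)
  xs <- (left + 1L):pssm$window$end
  fits <- vector("list", length(xs))
  names(fits) <- as.character(xs)
  rows <- lapply(seq_along(xs), function(i) {
    k <- window_index(pssm$window, xs[i])
    raw <- cum[k, ]
    ref_raw <- raw[ref_col]
    row_na <- data.frame(X = xs[i], C0 = NA_real_, C1 = NA_real_,
                         se_C0 = NA_real_, se_C1 = NA_real_, r2 = NA_real_,
                         adj_r2 = NA_real_, F = NA_real_, p_F = NA_real_,
                         ok = FALSE)
    if (ref_raw == 0) return(row_na)
    sc <- data.frame(id = sub$ids, normalized_score = raw / ref_raw)
    fit <- tryCatch(fit_linear(sc, strengths), error = function(e) NULL)
    if (is.null(fit)) return(row_na)
    fits[[i]] <<- fit
    data.frame(X = xs[i], C0 = fit$C0, C1 = fit$C1,
               se_C0 = fit$se_C0, se_C1 = fit$se_C1,
               r2 = fit$r2, adj_r2 = fit$adj_r2, F = fit$F, p_F = fit$p_F,
               ok = TRUE)
  })
  out <- do.call(rbind, rows)
  structure(out, fits = fits, reference_id = reference_id,
            class = c("prom_scan", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect where fit quality saturates along the endpoint scan
#'
#' Operationalizes "adding more nucleotides no longer improves the fit":
#' returns the smallest endpoint X* such that every later endpoint improves
#' R-squared by less than `delta` over X*. If quality keeps improving to the
#' last endpoint, that endpoint is returned.
#'
#' @param rows A `prom_scan` (or data frame with columns `X`, `r2`, ordered
#'   by `X`).
#' @param delta Improvement threshold on R-squared; default 0.01.
#' @return The saturation endpoint X* (a single integer position).
#' @export
detect_saturation <- function(rows, delta = 0.01) {
  df <- as.data.frame(rows)
  if ("ok" %in% names(df)) df <- df[df$ok, , drop = FALSE]
  df <- df[is.finite(df$r2), , drop = FALSE]
  if (nrow(df) == 0L) stop("no usable scan rows", call. = FALSE)
  if (is.unsorted(df$X)) stop("scan rows must be ordered by X", call. = FALSE)
  r2 <- df$r2
  n <- length(r2)
  for (i in seq_len(n)) {
    later <- if (i < n) r2[(i + 1):n] else numeric(0)
    if (all(later - r2[i] < delta)) return(df$X[i])
  }
  df$X[n]
}

#' Inverse-variance pooling of model parameters across fits
#'
#' Combines per-channel (or per-dataset) fits into a single (C0, C1) by the
#' error-bar-weighted mean: each parameter is averaged with weights
#' `1/SE^2`, and the pooled standard error is `sqrt(1 / sum(1/SE^2))`.
#'
#' @param fits A list of `prom_fit` objects (a single fit may be passed
#'   bare).
#' @return List with `C0`, `C1`, `se_C0`, `se_C1`, `n_fits`.
#' @export
pool_parameters <- function(fits) {
  if (inherits(fits, "prom_fit")) fits <- list(fits)
  if (length(fits) == 0L) stop("no fits to pool", call. = FALSE)
  get <- function(what) vapply(fits, `[[`, numeric(1), what)
  se0 <- get("se_C0"); se1 <- get("se_C1")
  if (any(!is.finite(se0)) || any(!is.finite(se1)) ||
      any(se0 == 0) || any(se1 == 0))
    stop("every fit must have finite nonzero standard errors; exclude degenerate perfect fits before pooling",
         call. = FALSE)
  pool1 <- function(est, se) {
    w <- 1 / se^2
    list(mean = sum(w * est) / sum(w), se = sqrt(1 / sum(w)))
  }
  p0 <- pool1(get("C0"), se0)
  p1 <- pool1(get("C1"), se1)
  list(C0 = p0$mean, C1 = p1$mean, se_C0 = p0$se, se_C1 = p1$se,
       n_fits = length(fits))
}

#' The published score-to-strength model
#'
#' The linear model `strength = C0 + C1 * score` with the parameters
#' obtained by pooling fits to three fluorescence channels (Venus, mRuby2,
#' mTurquoise2) and an independent five-promoter dataset: C0 = 0.025,
#' C1 = 0.87. Use [fit_linear()] / [pool_parameters()] to derive your own.
#'
#' @param C0,C1 Model parameters; defaults are the published values.
#' @param provenance Free-text note on where the parameters came from.
#' @return A `prom_model`.
#' @export
published_model <- function(C0 = 0.025, C1 = 0.87,
                            provenance = "published pooled estimate") {
  if (!is.finite(C0) || !is.finite(C1))
    stop("model parameters must be finite", call. = FALSE)
  structure(list(C0 = C0, C1 = C1, provenance = provenance),
            class = "prom_model")
}

#' Predict promoter strength from a normalized score
#'
#' @param normalized_score Numeric vector of pTDH3-normalized segment
#'   scores.
#' @param model A `prom_model`; default [published_model()].
#' @return Predicted strength(s): `C0 + C1 * normalized_score`.
#' @export
predict_strength <- function(normalized_score, model = published_model()) {
  model$C0 + model$C1 * normalized_score
}

#' Classify a predicted strength as weak / moderate / strong
#'
#' @param predicted_strength Numeric vector.
#' @param thresholds Length-2 numeric `(t_low, t_high)`, `t_low < t_high`:
#'   weak below `t_low`, moderate in `[t_low, t_high)`, strong at or above
#'   `t_high`. See [strength_tertiles()] for data-driven defaults.
#' @return Character vector in {"weak", "moderate", "strong"}.
#' @export
classify_strength <- function(predicted_strength, thresholds) {
  if (length(thresholds) != 2L || !all(is.finite(thresholds)) ||
      thresholds[1] >= thresholds[2])
    stop("thresholds must be (t_low, t_high) with t_low < t_high",
         call. = FALSE)
  ifelse(predicted_strength >= thresholds[2], "strong",
         ifelse(predicted_strength >= thresholds[1], "moderate", "weak"))
}

#' Tertile classification thresholds from a reference strength set
#'
#' @param strengths A `strength_vector` or numeric vector of strengths.
#' @return Numeric `(t_low, t_high)`: the 1/3 and 2/3 quantiles.
#' @export
strength_tertiles <- function(strengths) {
  if (is.data.frame(strengths)) strengths <- strengths$strength
  q <- stats::quantile(strengths, c(1, 2) / 3, names = FALSE, type = 7)
  if (q[1] >= q[2])
    stop("degenerate strength distribution: tertiles coincide", call. = FALSE)
  q
}

#' Score, predict and contextualize a single query promoter
#'
#' The end-user prediction: scores a 60 bp query window against a scoring
#' matrix, normalizes by the reference promoter's raw score, applies the
#' linear model, optionally classifies the result against thresholds, and
#' places the query's raw score within a background score distribution
#' (e.g. the full EPD promoter population) as a percentile
#' (`100 * rank / n`, fraction of background scores at or below the query).
#'
#' @param pssm A `prom_pssm`.
#' @param sequence Window-length query sequence (A/C/G/T).
#' @param reference_raw_score Raw score of the reference promoter (pTDH3)
#'   under the same matrix and segment; from [segment_score()].
#' @param model A `prom_model`.
#' @param id Label for the query.
#' @param segment Segment to score; default full window.
#' @param background_scores Optional numeric vector of raw scores of a
#'   background promoter population on the same segment.
#' @param thresholds Optional `(t_low, t_high)` for classification.
#' @return A `prom_prediction`: list with `id`, `raw_score`,
#'   `normalized_score`, `predicted_strength`, and where available
#'   `class_label` and `percentile`.
#' @export
predict_promoter <- function(pssm, sequence, reference_raw_score,
                             model = published_model(), id = "query",
                             segment = prom_segment(pssm$window$start,
                                                    pssm$window$end),
                             background_scores = NULL, thresholds = NULL) {
  if (!is.finite(reference_raw_score) || reference_raw_score == 0)
    stop("reference_raw_score must be finite and nonzero", call. = FALSE)
  raw <- segment_score(pssm, sequence, segment)
  norm <- raw / reference_raw_score
  pred <- predict_strength(norm, model)
  out <- list(id = id, raw_score = raw, normalized_score = norm,
              predicted_strength = pred,
              model = list(C0 = model$C0, C1 = model$C1,
                           provenance = model$provenance))
  if (!is.null(thresholds))
    out$class_label <- classify_strength(pred, thresholds)
  if (!is.null(background_scores) && length(background_scores) > 0)
    out$percentile <- 100 * mean(background_scores <= raw)
  structure(out, class = "prom_prediction")
}

#' @export
print.prom_prediction <- function(x, ...) {
  cat(sprintf("<prom_prediction> %s\n", x$id))
  cat(sprintf("  raw score         %.4f bits\n", x$raw_score))
  cat(sprintf("  normalized score  %.4f (reference = 1)\n",
              x$normalized_score))
  cat(sprintf("  predicted strength %.4f  [strength = %.3g + %.3g * score]\n",
              x$predicted_strength, x$model$C0, x$model$C1))
  if (!is.null(x$class_label))
    cat(sprintf("  class             %s\n", x$class_label))
  if (!is.null(x$percentile))
    cat(sprintf("  background percentile %.1f%%\n", x$percentile))
  invisible(x)
}
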