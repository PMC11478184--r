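make_strengths <- function(ids, strength, channel = "syn") {
  structure(data.frame(id = ids, strength = strength),
            channel = channel, reference_id = ids[1],
            class = c("strength_vector", "data.frame"))
}

make_table <- function(ids, fold, channel = "mRuby2", ref = "pTDH3") {
  structure(data.frame(id = ids, channel = channel,
                       fold_over_background = fold),
            reference_id = ref, class = c("strength_table", "data.frame"))
}

test_that("strengths are log fold-over-background ratios with reference at 1", {
  tab <- make_table(c("pTDH3", "pA"), c(exp(4), exp(2)))
  sv <- strengths_from_fold(tab, "mRuby2")
  expect_equal(sv$strength, c(1, 0.5))

  tab <- make_table(c("pTDH3", "pOne"), c(exp(2), 1))
  expect_equal(strengths_from_fold(tab, "mRuby2")$strength, c(1, 0))

  tab <- make_table(c("pTDH3", "pA", "pB"), c(exp(2), exp(1), exp(3)))
  expect_equal(strengths_from_fold(tab, "mRuby2")$strength, c(1, 0.5, 1.5))

  # reference fold <= 1 means ln(ref) <= 0: no valid normalizer
  tab <- make_table(c("pTDH3", "pA"), c(0.9, 2))
  expect_error(strengths_from_fold(tab, "mRuby2"), "exceed 1")
  expect_error(strengths_from_fold(tab, "Venus"), "no rows")
  tab <- make_table(c("pA", "pB"), c(2, 3))
  expect_error(strengths_from_fold(tab, "mRuby2"), "absent")

  # pre-normalized strengths pass through unchanged
  tab2 <- structure(data.frame(id = c("pTDH3", "pA"), channel = "mRuby2",
                               strength = c(1, 0.37)),
                    reference_id = "pTDH3",
                    class = c("strength_table", "data.frame"))
  expect_equal(strengths_from_fold(tab2, "mRuby2")$strength, c(1, 0.37))
})

test_that("closed-form OLS reproduces hand-solved fits", {
  # exact line: degenerate perfect fit
  sc <- data.frame(id = c("a", "b", "c"), normalized_score = c(0, 1, 2))
  fit <- fit_linear(sc, make_strengths(c("a", "b", "c"), c(1, 2, 3)))
  expect_equal(fit$C0, 1)
  expect_equal(fit$C1, 1)
  expect_equal(fit$r2, 1)
  expect_equal(fit$residuals$residual, rep(0, 3), tolerance = 1e-12)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$se_C1))

  # flat-slope fit solved by hand
  fit <- fit_linear(sc, make_strengths(c("a", "b", "c"), c(0, 1, 0)))
  expect_equal(fit$C1, 0, tolerance = 1e-12)
  expect_equal(fit$C0, 1 / 3)
  expect_equal(fit$r2, 0, tolerance = 1e-12)
  expect_equal(fit$F, 0, tolerance = 1e-12)

  expect_error(fit_linear(sc[1:2, ], make_strengths(c("a", "b"), c(1, 2))),
               "at least 3")
  sc0 <- data.frame(id = c("a", "b", "c"), normalized_score = c(1, 1, 1))
  expect_error(fit_linear(sc0, make_strengths(c("a", "b", "c"), c(1, 2, 3))),
               "identical")
})

test_that("fit diagnostics agree with stats::lm on random data", {
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    x <- runif(n)
    y <- 0.1 + 0.9 * x + rnorm(n, sd = 0.1)
    ids <- paste0("p", seq_len(n))
    fit <- fit_linear(data.frame(id = ids, normalized_score = x),
                      make_strengths(ids, y))
    lmfit <- stats::lm(y ~ x)
    sm <- summary(lmfit)
    expect_equal(fit$C0, unname(coef(lmfit)[1]))
    expect_equal(fit$C1, unname(coef(lmfit)[2]))
    expect_equal(fit$se_C0, unname(sm$coefficients[1, 2]))
    expect_equal(fit$se_C1, unname(sm$coefficients[2, 2]))
    expect_equal(fit$p_C1, unname(sm$coefficients[2, 4]))
    expect_equal(fit$r2, sm$r.squared)
    expect_equal(fit$adj_r2, sm$adj.r.squared)
    expect_equal(fit$F, unname(sm$fstatistic[1]))
    expect_equal(fit$p_F,
                 unname(stats::pf(sm$fstatistic[1], 1, n - 2,
                                  lower.tail = FALSE)))
    # QQ pairs use (i - 0.5)/n plotting positions on sorted residuals
    expect_equal(fit$qq$theoretical, qnorm((seq_len(n) - 0.5) / n))
    expect_equal(fit$qq$sample, sort(fit$residuals$residual))
  }
})

test_that("saturation detection implements the smallest-stable-endpoint rule", {
  rows <- data.frame(X = 1:5, r2 = c(0.1, 0.5, 0.9, 0.905, 0.907))
  expect_equal(detect_saturation(rows, delta = 0.01), 3)
  rows <- data.frame(X = 1:5, r2 = seq(0.1, 0.9, length.out = 5))
  expect_equal(detect_saturation(rows, delta = 0.01), 5)
  rows <- data.frame(X = 1:5, r2 = rep(0.4, 5))
  expect_equal(detect_saturation(rows, delta = 0.01), 1)
  expect_error(detect_saturation(data.frame(X = integer(0), r2 = numeric(0))),
               "no usable")
})

test_that("parameter pooling is the inverse-variance weighted mean", {
  fake_fit <- function(C0, C1, se) {
    structure(list(C0 = C0, C1 = C1, se_C0 = se, se_C1 = se),
              class = "prom_fit")
  }
  # equal SEs reduce to the arithmetic mean
  p <- pool_parameters(list(fake_fit(0, 0.8, 0.1), fake_fit(0, 1.0, 0.1)))
  expect_equal(p$C1, 0.9)
  # hand-computed unequal weights: (0.8/0.01 + 1.2/0.09)/(1/0.01 + 1/0.09)
  p <- pool_parameters(list(fake_fit(0, 0.8, 0.1), fake_fit(0, 1.2, 0.3)))
  expect_equal(p$C1, 0.84)
  expect_equal(p$se_C1, sqrt(1 / (1 / 0.01 + 1 / 0.09)))
  # single fit returns itself
  p <- pool_parameters(fake_fit(0.02, 0.9, 0.05))
  expect_equal(p$C1, 0.9)
  expect_equal(p$se_C1, 0.05)
  expect_error(pool_parameters(list(fake_fit(0, 1, 0))), "degenerate")
})

test_that("published model predicts and classifies strengths", {
  m <- published_model()
  expect_equal(predict_strength(1, m), 0.895)
  expect_equal(predict_strength(0, m), 0.025)
  expect_equal(predict_strength(0.5, m), 0.46)
  expect_error(published_model(C1 = Inf), "finite")

  expect_equal(classify_strength(0.46, c(0.4, 0.7)), "moderate")
  expect_equal(classify_strength(0.7, c(0.4, 0.7)), "strong")  # boundary
  expect_equal(classify_strength(0.39, c(0.4, 0.7)), "weak")
  expect_equal(classify_strength(0.4, c(0.4, 0.7)), "moderate")
  expect_error(classify_strength(0.5, c(0.7, 0.4)), "t_low < t_high")

  # tertile thresholds: 18 strengths, lowest third classified weak
  set.seed(9)
  s <- runif(18)
  th <- strength_tertiles(s)
  labs <- classify_strength(s, th)
  expect_equal(sum(labs == "weak"), sum(s < th[1]))
  expect_true(all(labs[s >= th[2]] == "strong"))
})

test_that("query prediction reports score, strength and background percentile", {
  pssm <- random_pssm(n = 30, L = 6)
  set.seed(13)
  bgset <- random_set(200, 6)
  bg <- promstrength:::segment_score_many(
    pssm, bgset$sequences, prom_segment(1, 6))
  ref_raw <- max(bg)
  q <- random_set(1, 6)$sequences
  pred <- predict_promoter(pssm, q, ref_raw, background_scores = bg,
                           thresholds = c(0.4, 0.7))
  expect_equal(pred$normalized_score, pred$raw_score / ref_raw)
  expect_equal(pred$predicted_strength,
               0.025 + 0.87 * pred$normalized_score)
  expect_equal(pred$percentile, 100 * mean(bg <= pred$raw_score))
  expect_true(pred$class_label %in% c("weak", "moderate", "strong"))
  expect_error(predict_promoter(pssm, q, 0), "nonzero")
})
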