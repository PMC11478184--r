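# promstrength

Sequence-based prediction of promoter strength in *Saccharomyces
cerevisiae* from the core-promoter window, for synthetic biologists and
promoter engineers who want a fast in-silico estimate of transcriptional
output before building a construct.

## The method

The strength of a yeast promoter is largely encoded in the 60 bp core
promoter spanning positions −49..+10 around the transcription start site
(TSS at 0, ends inclusive). `promstrength` implements a two-step model of
that relationship:

1. **Log-odds scoring.** A population of TSS-aligned core-promoter windows
   (e.g. the 5117 *S. cerevisiae* promoters extractable from the
   Eukaryotic Promoter Database) is tallied into a position frequency
   matrix, converted to base probabilities (optional pseudocount), then to
   a position-specific scoring matrix (PSSM) of log₂-odds in bits against a
   background distribution. The score of a promoter segment is the sum of
   its per-position log-odds, normalized by the score of the reference
   promoter pTDH3 (the strongest constitutive promoter in the
   characterized set), which sits at 1 by construction.

2. **A linear strength model.** Promoter strength — ln(fluorescence
   fold-over-background), normalized to pTDH3 — is modelled as

   *strength* = C₀ + C₁ × *score*

   and fit by simple ordinary least squares with full diagnostics (R²,
   adjusted R², F and t statistics, residual bias check, QQ pairs).
   Per-channel fits are pooled by inverse-variance weighting; the
   published pooled parameters are **C₀ = 0.025, C₁ = 0.87**
   (`published_model()`).

A segment-endpoint scan (`scan_endpoints()`) anchors the scored segment at
−49 and refits the model for every endpoint X up to +10, locating the
minimal region that predicts strength; `detect_saturation()` reports where
R² stops improving by more than a threshold (default 0.01). Predictions for
new promoters (`predict_promoter()`, or the `predict` subcommand of the
CLI) report the raw and normalized score, the predicted strength, a
weak/moderate/strong class, and the percentile of the query within a
background score population.

A fully seeded synthetic-data generator (`synthetic_spec()`,
`generate_promoter_set()`, `generate_strengths()`) emulates both the
sequence population and the strength table with known ground truth, so the
entire pipeline is testable offline.

## A worked example

```r
library(promstrength)

spec <- synthetic_spec(n_sequences = 500, n_labeled = 18, seed = 42)
pop  <- generate_promoter_set(spec)
pssm <- ppm_to_pssm(pfm_to_ppm(build_pfm(pop), pseudocount = 1))

tab <- generate_strengths(pop, pssm, spec)      # ground truth: 0.025 + 0.87*score
ref <- attr(tab, "reference_id")
sv  <- strengths_from_fold(tab, "synthetic")
sc  <- score_set(pssm, pop[sv$id], reference_id = ref)
fit_linear(sc, sv)
#> <prom_fit> strength = C0 + C1 * score
#>   C0 = 0.0148 (SE 0.0115, p = 0.217)
#>   C1 = 0.8678 (SE 0.0242, p = 1.05e-16)
#>   n = 18, R2 = 0.9877, adj. R2 = 0.9869, F = 1.28e+03 (p = 1.05e-16)
```

The fit recovers the generating parameters (0.025, 0.87) within one
standard error: the intercept is indistinguishable from its true value
(p = 0.22 against 0 with truth 0.025), the slope estimate 0.868 ± 0.024
brackets 0.87, and R² ≈ 0.99 reflects the noise sd of 0.05. Scoring and
classifying one promoter of the population against the full set:

```r
pred <- predict_promoter(pssm, pop$sequences[30],
                         segment_score(pssm, pop[ref]), id = pop$ids[30],
                         background_scores = sc_all, # scores of all 500
                         thresholds = strength_tertiles(sv))
pred
#> <prom_prediction> syn0030
#>   raw score         0.6285 bits
#>   normalized score  0.5541 (reference = 1)
#>   predicted strength 0.5071  [strength = 0.025 + 0.87 * score]
#>   class             strong
#>   background percentile 70.2%
```

i.e. this promoter scores 0.63 bits, 55% of the reference's score, is
predicted at 51% of the reference's strength — the upper tertile of the
labelled strengths, hence "strong" — and outscores 70% of the background
population.

The same workflow is available from a shell via the bundled CLI
(`inst/exec/promstrength`): subcommands `build-pssm`, `score`, `fit`,
`scan`, `predict` and `simulate`, each writing TSV/JSON outputs plus a
machine-readable copy of its effective configuration.

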