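# shortform

Model-based construction of short forms of full-length functional health
literacy tests (the TOFHLA family), for biostatisticians and health-services
researchers who need a screening instrument that patients can complete in a
few minutes without a trained interviewer.

## The method

The full-length Danish TOFHLA has 67 items — 17 numeracy items (interviewer
required) and 50 reading-comprehension cloze items — scored 0–100 and
classified as inadequate (0–59), marginal (60–74) or adequate (75–100)
functional health literacy. A short form is an integer-weighted linear rule
over a subset of the binary item responses C_j:

    Y = b0 + b1*C1 + b2*C2 + ... + bn*Cn,   bj integers

predicting the full-length score Y. The package derives such rules by:

1. **Sentence grouping** — the 50 reading items partition into 19 sets of
   consecutive items, each a whole sentence; sets are the atomic unit of
   selection so sentence meaning survives.
2. **Exhaustive search** — for every model size (1 item upward), all set
   combinations with that many items are fitted by least squares, trimmed to
   integer coefficients, and evaluated by leave-one-out cross-validation
   against the full-length score; the scan stops at the smallest size whose
   best pooled Pearson r reaches the quality goal (default r ≥ 0.9, reading
   items only — numeracy enters only as a fallback pass).
3. **Validation** — Cronbach's alpha, point-biserial item-scale
   correlations, Pearson r with Fisher-z CI95, a 3×3 level confusion matrix
   with one-vs-rest accuracies and ordinal off-by-k counts, plus a
   comparison table against the fixed-weight S-TOFHLA mirror models
   (36 reading × 2 points + 4 numeracy × 7 points, and its prose-only
   variant).

The packaged `ds_tofhla_model()` is the published 20-item DS-TOFHLA rule
(intercept 23, weights over six sentence sets, score range 23–95,
administration time 5 minutes versus 22 for the full test). A two-parameter
logistic latent-trait simulator generates cohorts shaped like the
development sample (n = 158, score mean ≈ 71.6, SD ≈ 18.7) so the whole
pipeline runs without patient data. See `vignette("shortform-methods")`
(source under `vignettes/`) for the model details and conventions.

## Worked example

```r
library(shortform)

bank   <- ds_tofhla_bank()                                   # 67 items, 19 sets
cohort <- simulate_cohort(bank, default_danish_config(bank, seed = 42))
full   <- score_full(cohort$responses, bank)                 # 0-100 totals
result <- exhaustive_search(group_items(bank), cohort$responses, full)
performance_curve(result)[, 1:4]
```

```
  item_count best_r best_rmse n_sets
1          1  0.544     16.15      1
2          2  0.671     14.28      2
...
8          8  0.895      8.57      4
9          9  0.905      8.20      3
```

The curve shows the best attainable LOOCV correlation at each model size;
on this synthetic cohort the goal r ≥ 0.9 is first met by a 9-item,
3-set model (synthetic cohorts are exactly unidimensional, so fewer items
suffice than on real data). Validating the derived model:

```r
report <- validate_model(cohort$responses, result$final_model, full)
report$pearson$r        # 0.916  (CI95 0.89-0.94)
report$alpha$alpha      # 0.767  -> reliable (> 0.7)
unlist(report$accuracy) # inadequate 88, marginal 80, adequate 89 (percent)
unlist(report$off_by_k) # 124 exact, 32 off by one level, 2 off by two
```

Scoring and comparing the packaged 20-item model on the same cohort:

```r
compare_models(cohort$responses, bank, ds_tofhla_model())
```

```
         model n_reading n_numeracy admin_minutes r_vs_full
1  full_length        50         17            22        NA
2     mirror_s        36          4            12     0.928
3 mirror_prose        36          0             9     0.929
4   short_form        20          0             5     0.921
```

The short form matches the 40-item mirror model's correlation at a quarter
of the administration time and with no interviewer-administered items.

A thin command-line wrapper ships at `inst/cli/shortform`
(`shortform {simulate|build|score|validate|compare}`); every run writes a
JSON manifest with input hashes and the seed next to its output.

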