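# radrec

Recommender-based bone tumour classification from radiographs.

Primary bone tumours are rare, heterogeneous, and easy to misjudge
outside specialised centres: the same entity (say, an osteochondroma)
can occur in different bones and look entirely different from case to
case. Instead of forcing one classifier to collapse all of those
appearances into a single class, `radrec` retrieves the **k most
similar previously diagnosed cases** for a query image and classifies
by **majority vote** over their diagnoses — simultaneously handing the
clinician the identifiers of those past patients, whose reports and
treatments are the actual decision support.

The pipeline, end to end:

1. **ROI crop** — lesion mask → tight bounding box → 15% per-side
   margin → crop (`mask_to_bbox()`, `expand_bbox()`, `crop_image()`).
2. **Embedding** — a pluggable extractor contract
   (`fit_extractor()`, `embed_images()`); the default is a
   deterministic reference descriptor (8×8 intensity grid + 16-bin
   gradient-orientation histogram, standardised on the training set,
   L2-normalised).
3. **Hashing & retrieval** — random-hyperplane locality-sensitive
   hashing: bit *b* of vector *v* is `1` iff `⟨v, h_b⟩ ≥ 0` for random
   directions `h_b ~ N(0, I)`. Since
   `E[hamming(sig(u), sig(v))/B] = angle(u, v)/π`, a hamming scan over
   signatures approximates angular k-NN (`build_lsh_index()`,
   `lsh_query()`, exact oracle `brute_force_knn()`).
4. **Vote & link** — odd-k majority vote with documented tie-breaks
   (`recommend()`, `batch_classify()`), patient linkage
   (`link_to_history()`).
5. **Evaluation** — precision-at-k, accuracy, macro precision/recall
   with an explicit undefined-class convention, the three-shuffle
   repeat protocol, and Shapiro-Wilk → ANOVA → Tukey HSD model
   comparison (`precision_at_k()`, `classification_metrics()`,
   `repeated_evaluation()`, `compare_models()`).

Everything runs on synthetic data shipped as code: a cohort generator
emulating a 10-entity, 809-patient reference composition with strong
class imbalance (28.31% down to 1.11%) and eligibility-exclusion
flags; a radiograph generator with per-entity multimodal shape/texture
motifs and ROI ground-truth masks; and a Gaussian embedding generator
with latent appearance modes. No clinical data are included or
required.

All user-facing functions take a data frame first and return tibbles,
so calls chain with the pipe; results have `tidy()`/`glance()` and
`autoplot()` methods.

## Worked example

```r
library(radrec)

cfg   <- synthetic_config(seed = 1)          # 10 entities x 3 latent modes
emb   <- generate_embeddings(cfg)            # 1500 labelled vectors
sp    <- split_features(emb, 0.2, seed = 2)  # stratified 80/20
index <- build_lsh_index(sp$train, bits = 128, seed = 3)
index
#> <lsh_index> 1200 items, D = 8, B = 128 bits x 1 table(s), seed 3

evaluate_k_menu(index, sp$test, ks = c(1, 3, 5, 7))
#> # A tibble: 4 × 3
#>       k precision_at_k vote_accuracy
#>   <int>          <dbl>         <dbl>
#> 1     1              1             1
#> 2     3              1             1
#> 3     5              1             1
#> 4     7              1             1

recommend(index, as.numeric(embedding_matrix(sp$test)[1, ]), k = 3,
          target_image_id = sp$test$image_id[1])
#> <retrieval_result E_ABC_m2_035> k = 3 -> ABC
#> # A tibble: 3 × 6
#>    rank image_id     patient_id    label distance angular
#>   <int> <chr>        <chr>         <chr>    <int>   <dbl>
#> 1     1 E_ABC_m2_018 SP_ABC_m2_018 ABC          2  0.0662
#> 2     2 E_ABC_m2_031 SP_ABC_m2_031 ABC          2  0.0902
#> 3     3 E_ABC_m2_044 SP_ABC_m2_044 ABC          2  0.107
```

The query (an aneurysmal bone cyst vector) retrieves three stored ABC
cases at hamming distance 2 of 128 bits; the unanimous vote predicts
`ABC`, and the `patient_id` column is the link back to those patients'
records. On this cleanly separated benchmark (cluster centroids ten
times the within-mode spread) retrieval is perfect at every k in the
menu — the interesting comparison is against a single linear
classifier on the same embeddings, which lands around 0.60–0.75
accuracy because each entity is a union of three distant appearance
modes that no single linear prototype can cover. That gap is the
method's mechanism, and the test suite asserts it.

The image route works the same way: `generate_images()` →
`crop_to_roi()` → `fit_extractor()`/`embed_images()` → the index. A
thin CLI over these functions ships in `inst/cli/radrec.R`
(`simulate`, `cohort-filter`, `cohort-split`, `embed`, `index-build`,
`recommend`, `evaluate`).

See `vignettes/retrieval-methods.Rmd` for the model, parameter and
design-decision write-up.

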