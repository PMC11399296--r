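#' Precision-at-k over a batch of retrievals
#'
#' The proportion of relevant items within the top-k: for each query,
#' the fraction of its k retrieved neighbours whose entity equals the
#' query's true entity, averaged over queries. At k = 1 this equals
#' majority-vote accuracy exactly (the single neighbour is the vote).
#'
#' @param results A [batch_classify()] tibble (uses its `neighbours`
#'   list-column and `truth` column).
#' @param truths Optional truth override: named character vector keyed
#'   by `target_image_id`, or a tibble with `target_image_id`/`image_id`
#'   and `entity`/`label`.
#' @return A single proportion in \[0, 1\].
#' @export
precision_at_k <- function(results, truths = NULL) {
  truth <- results$truth
  if (!is.null(truths)) {
    if (is.data.frame(truths)) {
      idc <- intersect(c("target_image_id", "image_id"), names(truths))[1]
      lbc <- intersect(c("entity", "label", "truth"), names(truths))[1]
      truth <- truths[[lbc]][match(results$target_image_id, truths[[idc]])]
    } else {
      truth <- unname(truths[results$target_image_id])
    }
  }
  if (anyNA(truth)) {
    abort(paste0("Missing truth label for target(s): ",
                 paste(results$target_image_id[is.na(truth)], collapse = ", ")))
  }
  per_target <- purrr::map2_dbl(results$neighbours, truth,
                                function(nb, tr) mean(nb$label == tr))
  mean(per_target)
}

#' Multiclass classification metrics
#'
#' Accuracy plus per-class and macro-averaged precision and recall.
#' Per class, precision = true positives / all predictions made for the
#' class and recall = true positives / all actual instances of the
#' class. Macro values are unweighted class means; classes where the
#' ratio is undefined are handled by `undefined`:
#' * `"exclude"` (default) — classes with zero predictions are dropped
#'   from macro precision and classes with zero support from macro
#'   recall;
#' * `"zero"` — undefined components count as 0.
#'
#' The convention used is stamped into the report.
#'
#' @param predictions,truths Aligned character vectors of labels.
#' @param class_set Label universe; defaults to the union of both.
#' @param undefined Undefined-component convention, see above.
#' @return An object of class `classification_metrics` with fields
#'   `accuracy`, `macro_precision`, `macro_recall`, `per_class` (tibble
#'   `class`, `support`, `predicted`, `tp`, `precision`, `recall`),
#'   `convention`, `n`. Has `tidy()`/`glance()` methods.
#' @export
classification_metrics <- function(predictions, truths, class_set = NULL,
                                   undefined = c("exclude", "zero")) {
  undefined <- match.arg(undefined)
  if (length(predictions) == 0 || length(predictions) != length(truths)) {
    abort("Need non-empty, aligned prediction and truth vectors.")
  }
  class_set <- class_set %||% sort(union(predictions, truths))
  bad <- setdiff(union(predictions, truths), class_set)
  if (length(bad) > 0) {
    abort(paste0("Labels outside class_set: ", paste(bad, collapse = ", ")))
  }
  per_class <- purrr::map_dfr(class_set, function(cl) {
    tp <- sum(predictions == cl & truths == cl)
    pred_n <- sum(predictions == cl)
    supp <- sum(truths == cl)
    tibble::tibble(
      class = cl, support = supp, predicted = pred_n, tp = tp,
      precision = if (pred_n > 0) tp / pred_n else NA_real_,
      recall = if (supp > 0) tp / supp else NA_real_
    )
  })
  macro <- function(x) {
    if (undefined == "zero") x[is.na(x)] <- 0 else x <- x[!is.na(x)]
    mean(x)
  }
  structure(list(
    accuracy = mean(predictions == truths),
    macro_precision = macro(per_class$precision),
    macro_recall = macro(per_class$recall),
    per_class = per_class, convention = undefined,
    n = length(predictions)
  ), class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "Classification metrics (n = %d, undefined-%s): accuracy %.4f, macro precision %.4f, macro recall %.4f\n",
    x$n, x$convention, x$accuracy, x$macro_precision, x$macro_recall))
  print(x$per_class)
  invisible(x)
}

#' @export
tidy.classification_metrics <- function(x, ...) x$per_class

#' @export
glance.classification_metrics <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy,
                 macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall, convention = x$convention)
}

#' Stratified split of a feature tibble
#'
#' Holds out `round_half_up(test_fraction * n)` items (at least one)
#' per label, deterministically given the seed. This is the
#' feature-level counterpart of [stratified_split()] for the
#' image-free embedding route, where each vector stands for one
#' single-image patient.
#'
#' @param features Labelled feature tibble.
#' @param test_fraction Held-out fraction per label. Default 0.2.
#' @param seed Integer seed.
#' @return A list with feature tibbles `train` and `test`.
#' @export
split_features <- function(features, test_fraction = 0.2, seed = 1L) {
  seed <- check_seed(seed)
  withr::with_seed(seed, {
    test_idx <- unlist(purrr::map(sort(unique(features$label)), function(l) {
      idx <- which(features$label == l)
      sample(idx, max(1L, round_half_up(test_fraction * length(idx))))
    }))
  })
  list(train = features[-test_idx, , drop = FALSE],
       test = features[test_idx, , drop = FALSE])
}

#' Repeated shuffled evaluation of the retrieval pipeline
#'
#' Runs the full synthetic pipeline `n_runs` times, each run differing
#' only in its shuffle/split seed: generate labelled embeddings from
#' `config`, split them stratified by entity, index the training part,
#' classify the held-out part by k-NN majority vote, and score
#' accuracy, macro precision/recall and precision-at-k. Means and
#' sample SDs over runs are reported; with the default three runs the
#' SD estimate is noisy and should be read as indicative only.
#'
#' @param config A [synthetic_config()]; embeddings are generated once
#'   from `config$seed`.
#' @param k Odd neighbour count. Default 3.
#' @param n_runs Number of repeats (>= 2 for an SD). Default 3.
#' @param seeds Integer vector of run seeds, length `n_runs`; defaults
#'   to `config$seed + 1:n_runs`. Identical seeds trigger a warning.
#' @param bits,tables LSH parameters.
#' @param test_fraction Held-out fraction per entity. Default 0.2.
#' @param undefined Macro convention, see [classification_metrics()].
#' @return An object of class `metric_report`: `k`, `n_runs`, `per_run`
#'   (tibble `run`, `seed`, `metric`, `value`), `summary` (tibble
#'   `metric`, `mean`, `sd`), `convention`.
#' @export
repeated_evaluation <- function(config, k = 3L, n_runs = 3L, seeds = NULL,
                                bits = 128L, tables = 1L,
                                test_fraction = 0.2,
                                undefined = c("exclude", "zero")) {
  undefined <- match.arg(undefined)
  if (n_runs < 2) abort("Need n_runs >= 2 to report an SD.")
  seeds <- seeds %||% (config$seed + seq_len(n_runs))
  if (length(seeds) != n_runs) abort("`seeds` must have length n_runs.")
  if (anyDuplicated(seeds) > 0) {
    warn("Duplicate run seeds: repeated runs will be identical.")
  }
  features <- generate_embeddings(config)
  per_run <- purrr::map_dfr(seq_len(n_runs), function(r) {
    sp <- split_features(features, test_fraction, seeds[r])
    index <- build_lsh_index(sp$train, bits = bits, tables = tables,
                             seed = seeds[r])
    res <- batch_classify(index, sp$test, k = k)
    cm <- classification_metrics(res$predicted_entity, res$truth,
                                 class_set = entity_levels(),
                                 undefined = undefined)
    tibble::tibble(run = r, seed = seeds[r],
                   metric = c("accuracy", "macro_precision", "macro_recall",
                              "precision_at_k"),
                   value = c(cm$accuracy, cm$macro_precision, cm$macro_recall,
                             precision_at_k(res)))
  })
  summary <- per_run |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
  structure(list(k = as.integer(k), n_runs = as.integer(n_runs),
                 per_run = per_run, summary = summary,
                 convention = undefined),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Metric report: k = %d, %d shuffled runs (mean +/- sample SD)\n",
              x$k, x$n_runs))
  with(x$summary, cat(sprintf("  %-16s %.4f +/- %.4f\n", metric, mean, sd),
                      sep = ""))
  invisible(x)
}

#' @export
tidy.metric_report <- function(x, ...) x$per_run

#' @export
glance.metric_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  dplyr::bind_cols(tibble::tibble(k = x$k, n_runs = x$n_runs), wide)
}

#' Compare models over repeated-run metrics
#'
#' The standard repeated-runs comparison protocol: Shapiro-Wilk normality
#' per model and metric, one-way ANOVA per metric across models, and
#' Tukey HSD pairwise comparisons. The 0.05 threshold is reported, not
#' enforced; with very few runs per model the tests are low-powered and
#' ANOVA rests on the normality the Shapiro-Wilk column probes.
#'
#' @param samples A tidy tibble with columns `model`, `metric`, `value`
#'   (one row per run), or a named list of per-run value vectors (one
#'   unnamed metric).
#' @return An object of class `model_comparison` with tibbles `shapiro`
#'   (`model`, `metric`, `W`, `p`), `anova` (`metric`, `statistic`,
#'   `p_value`), `tukey` (`metric`, `pair`, `diff`, `p_adj`), and
#'   `alpha = 0.05`.
#' @export
compare_models <- function(samples) {
  if (!is.data.frame(samples)) {
    samples <- purrr::imap_dfr(samples, function(v, m)
      tibble::tibble(model = m, metric = "metric", value = v))
  }
  stopifnot(all(c("model", "metric", "value") %in% names(samples)))
  models <- unique(samples$model)
  if (length(models) < 2) abort("Need at least two models to compare.")
  metric_sets <- purrr::map(models, function(m)
    sort(unique(samples$metric[samples$model == m])))
  if (length(unique(purrr::map_chr(metric_sets, paste, collapse = "|"))) != 1) {
    abort("All models must report the same metric set.")
  }
  counts <- dplyr::count(samples, .data$model, .data$metric)
  if (any(counts$n < 2)) abort("Need >= 2 runs per model and metric.")
  shapiro <- samples |>
    dplyr::group_by(.data$model, .data$metric) |>
    dplyr::summarise(
      W = if (stats::var(.data$value) > 0 && dplyr::n() >= 3)
        unname(shapiro.test(.data$value)$statistic) else NA_real_,
      p = if (stats::var(.data$value) > 0 && dplyr::n() >= 3)
        shapiro.test(.data$value)$p.value else NA_real_,
      .groups = "drop")
  per_metric <- purrr::map(sort(unique(samples$metric)), function(m) {
    d <- samples[samples$metric == m, ]
    d$model <- factor(d$model)
    fit <- aov(value ~ model, data = d)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$model
    list(
      anova = tibble::tibble(metric = m, statistic = an[["F value"]][1],
                             p_value = an[["Pr(>F)"]][1]),
      tukey = tibble::tibble(metric = m, pair = rownames(tk),
                             diff = tk[, "diff"], p_adj = tk[, "p adj"])
    )
  })
  structure(list(
    shapiro = shapiro,
    anova = purrr::map_dfr(per_metric, "anova"),
    tukey = purrr::map_dfr(per_metric, "tukey"),
    alpha = 0.05
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (threshold alpha =", x$alpha, "reported, not enforced)\n")
  cat("ANOVA per metric:\n"); print(x$anova)
  cat("Tukey HSD pairs:\n"); print(x$tukey)
  invisible(x)
}

#' @export
tidy.model_comparison <- function(x, ...) x$tukey

#' @export
glance.model_comparison <- function(x, ...) {
  tidyr::pivot_wider(x$anova, names_from = "metric", values_from =
                       c("statistic", "p_value"))
}

#' Linear one-vs-rest baseline classifier
#'
#' A single direct linear classifier over embeddings — ridge
#' least-squares onto class indicators, predicting the argmax score.
#' It models each entity with one linear prototype, which is exactly
#' what multimodal entities break; it serves as the direct-classification
#' baseline the k-NN majority vote is compared against.
#'
#' @param features Labelled feature tibble (training set).
#' @param lambda Ridge penalty. Default 1e-6.
#' @return An object of class `linear_classifier`.
#' @export
fit_linear_classifier <- function(features, lambda = 1e-6) {
  x <- cbind(1, embedding_matrix(features))
  classes <- sort(unique(features$label))
  y <- outer(features$label, classes, "==") * 1
  w <- solve(crossprod(x) + lambda * diag(ncol(x)), crossprod(x, y))
  structure(list(weights = w, classes = classes), class = "linear_classifier")
}

#' @param object A `linear_classifier`.
#' @param newdata Feature tibble to classify.
#' @param ... Unused.
#' @rdname fit_linear_classifier
#' @export
predict.linear_classifier <- function(object, newdata, ...) {
  scores <- cbind(1, embedding_matrix(newdata)) %*% object$weights
  object$classes[max.col(scores, ties.method = "first")]
}
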