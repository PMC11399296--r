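test_that("precision-at-k averages per-target neighbour relevance", {
  res <- fake_results(list(c("ABC", "ABC", "NOF")), truths = "ABC")
  expect_equal(precision_at_k(res), 2 / 3)

  res2 <- fake_results(list(rep("ABC", 3), rep("NOF", 3)),
                       truths = c("ABC", "NOF"))
  expect_equal(precision_at_k(res2), 1)

  res3 <- fake_results(list(rep("ABC", 3), rep("ABC", 3)),
                       truths = c("ABC", "NOF"))
  expect_equal(precision_at_k(res3), 0.5)

  # truth override by named vector and missing-truth error
  tr <- c(t01 = "ABC", t02 = "NOF")
  expect_equal(precision_at_k(res3, tr), 0.5)
  expect_error(precision_at_k(res3, tr[1]), "t02")
})

test_that("classification metrics match a hand-computed confusion matrix", {
  truths <- c("A", "A", "B", "B", "C", "C")
  preds <- c("A", "A", "A", "B", "A", "B")
  cm <- classification_metrics(preds, truths, class_set = c("A", "B", "C"))
  expect_equal(cm$accuracy, 0.5)
  pc <- cm$per_class
  expect_equal(pc$precision[pc$class == "A"], 2 / 4)
  expect_equal(pc$precision[pc$class == "B"], 1 / 2)
  expect_true(is.na(pc$precision[pc$class == "C"]))
  expect_equal(pc$recall, c(1, 0.5, 0))
  expect_equal(cm$macro_precision, 0.5)            # exclude convention
  cmz <- classification_metrics(preds, truths, class_set = c("A", "B", "C"),
                                undefined = "zero")
  expect_equal(cmz$macro_precision, 1 / 3)

  perfect <- classification_metrics(truths, truths)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_precision, 1)
  expect_equal(perfect$macro_recall, 1)

  expect_error(classification_metrics(character(0), character(0)), "empty|aligned")
})

test_that("one dominant predicted class yields high precision but ~1/C recall", {
  # the high-precision / low-recall signature of never-predicted classes
  truths <- rep(entity_levels(), each = 10)
  preds <- rep("osteochondroma", 100)
  cm <- classification_metrics(preds, truths, class_set = entity_levels())
  expect_equal(cm$macro_precision, 0.1)   # only the predicted class counts
  expect_equal(cm$macro_recall, 0.1)      # 1 of 10 classes recovered
  expect_equal(cm$accuracy, 0.1)
})

test_that("accuracy equals micro-averaged precision and survives permutation", {
  withr::with_seed(31, {
    for (rep in 1:50) {
      n <- sample(20:60, 1)
      labs <- sample(LETTERS[1:5], n, replace = TRUE)
      preds <- sample(LETTERS[1:5], n, replace = TRUE)
      cm <- classification_metrics(preds, labs, class_set = LETTERS[1:5])
      # micro precision: pooled tp over pooled predictions
      expect_equal(sum(cm$per_class$tp) / sum(cm$per_class$predicted),
                   cm$accuracy)
      perm <- sample(n)
      cmp <- classification_metrics(preds[perm], labs[perm],
                                    class_set = LETTERS[1:5])
      expect_equal(cmp$accuracy, cm$accuracy)
      expect_equal(cmp$macro_precision, cm$macro_precision)
      expect_equal(cmp$macro_recall, cm$macro_recall)
    }
  })
})

test_that("metrics agree with a brute-force confusion-matrix oracle", {
  oracle <- function(preds, truths, classes) {
    prec <- rec <- rep(NA_real_, length(classes))
    for (i in seq_along(classes)) {
      tp <- 0; fp <- 0; fn <- 0
      for (j in seq_along(preds)) {
        if (preds[j] == classes[i] && truths[j] == classes[i]) tp <- tp + 1
        if (preds[j] == classes[i] && truths[j] != classes[i]) fp <- fp + 1
        if (preds[j] != classes[i] && truths[j] == classes[i]) fn <- fn + 1
      }
      if (tp + fp > 0) prec[i] <- tp / (tp + fp)
      if (tp + fn > 0) rec[i] <- tp / (tp + fn)
    }
    list(acc = mean(preds == truths),
         mp = mean(prec, na.rm = TRUE), mr = mean(rec, na.rm = TRUE))
  }
  withr::with_seed(32, {
    for (rep in 1:100) {
      n <- sample(10:40, 1)
      classes <- LETTERS[1:sample(3:6, 1)]
      truths <- sample(classes, n, replace = TRUE)
      preds <- sample(classes, n, replace = TRUE)
      cm <- classification_metrics(preds, truths, class_set = classes)
      o <- oracle(preds, truths, classes)
      expect_equal(cm$accuracy, o$acc)
      expect_equal(cm$macro_precision, o$mp)
      expect_equal(cm$macro_recall, o$mr)
    }
  })
})

test_that("repeated evaluation reports per-run values, means and SDs", {
  cfg <- synthetic_config(vectors_per_mode = 10, seed = 33)
  expect_warning(
    rep0 <- repeated_evaluation(cfg, k = 3, n_runs = 2, seeds = c(5, 5),
                                bits = 64),
    "identical")
  sds <- rep0$summary$sd
  expect_true(all(sds == 0))   # identical seeds: a deterministic pipeline

  rep3 <- repeated_evaluation(cfg, k = 3, n_runs = 3, bits = 64)
  expect_equal(nrow(rep3$per_run), 12)
  acc <- rep3$summary$mean[rep3$summary$metric == "accuracy"]
  expect_gte(acc, 0.95)
  # per-run values reproducible from their seeds
  rep3b <- repeated_evaluation(cfg, k = 3, n_runs = 3, bits = 64)
  expect_equal(rep3$per_run, rep3b$per_run)
})

test_that("model comparison flags a shifted group and validates inputs", {
  base <- c(0.601, 0.603, 0.602)
  samples <- tibble::tibble(
    model = rep(c("resnet", "vit", "ours"), each = 3),
    metric = "accuracy",
    value = c(base, base + 0.002, base + 0.3))
  cmp <- compare_models(samples)
  expect_lt(cmp$anova$p_value, 0.05)
  tk <- cmp$tukey
  expect_lt(tk$p_adj[grepl("ours", tk$pair) & grepl("resnet", tk$pair)], 0.05)
  expect_gt(tk$p_adj[grepl("vit", tk$pair) & grepl("resnet", tk$pair)], 0.05)
  expect_true(all(cmp$shapiro$p >= 0 & cmp$shapiro$p <= 1, na.rm = TRUE))
  expect_true(all(cmp$tukey$p_adj >= 0 & cmp$tukey$p_adj <= 1))

  # two groups with the same values sit on the F = 0 boundary
  flat <- tibble::tibble(model = rep(c("a", "b"), each = 3),
                         metric = "accuracy",
                         value = rep(c(0.5, 0.51, 0.49), 2))
  expect_gt(compare_models(flat)$anova$p_value, 0.99)

  uneven <- samples
  uneven$metric[uneven$model == "ours"] <- "recall"
  expect_error(compare_models(uneven), "same metric set")
})

test_that("textbook one-way ANOVA arithmetic is reproduced", {
  # hand-checkable case: groups (1,2,3), (2,3,4), (7,8,9)
  d <- tibble::tibble(model = rep(c("g1", "g2", "g3"), each = 3),
                      metric = "m",
                      value = c(1, 2, 3, 2, 3, 4, 7, 8, 9))
  cmp <- compare_models(d)
  # between-group SS = 3*((2-4.333..)^2+(3-4.333..)^2+(8-4.333..)^2) = 62
  # within-group SS = 6; F = (62/2)/(6/6) = 31
  expect_equal(cmp$anova$statistic, 31, tolerance = 1e-10)
  expect_equal(cmp$anova$p_value, stats::pf(31, 2, 6, lower.tail = FALSE))
})
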