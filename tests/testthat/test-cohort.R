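test_that("eligibility filter partitions by flags with documented precedence", {
  # all flags false: identity, zero exclusions
  clean <- make_cohort(rep("NOF", 4))
  flt <- apply_eligibility_filter(clean)
  expect_identical(flt$included, clean)
  expect_identical(unname(flt$exclusion_counts), c(0L, 0L, 0L))

  # five hand-enumerated records: one clean, one per flag, one with
  # imaging + follow-up flags both set (precedence -> inadequate_imaging)
  flags <- rbind(c(FALSE, FALSE, FALSE),
                 c(TRUE, FALSE, FALSE),
                 c(FALSE, TRUE, FALSE),
                 c(FALSE, FALSE, TRUE),
                 c(TRUE, FALSE, TRUE))
  coh <- make_cohort(rep("ABC", 5), n_images = c(1, 0, 2, 1, 0),
                     flags = flags)
  flt <- apply_eligibility_filter(coh)
  expect_equal(nrow(flt$included), 1)
  expect_equal(flt$exclusion_counts,
               c(inadequate_imaging = 2L, incomplete_clinical = 1L,
                 lost_followup = 1L))
  expect_equal(nrow(flt$included) + sum(flt$exclusion_counts), nrow(coh))

  expect_error(apply_eligibility_filter(clean[0, ]), "empty")
})

test_that("filter conservation holds for random flag patterns", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- 40
      flags <- matrix(runif(n * 3) < 0.3, n, 3)
    })
    coh <- make_cohort(sample(entity_levels(), 40, replace = TRUE),
                       n_images = rep(1L, 40), flags = flags)
    flt <- apply_eligibility_filter(coh)
    expect_equal(nrow(flt$included) + sum(flt$exclusion_counts), 40)
    expect_false(any(rowSums(as.matrix(
      flt$included[c("flag_inadequate_imaging", "flag_incomplete_clinical",
                     "flag_lost_followup")])) > 0))
  }
})

test_that("stratified split honours quotas, determinism and the single-image rule", {
  coh <- make_cohort(rep(entity_levels(), each = 10))
  sp <- stratified_split(coh, 0.2, seed = 11)
  expect_equal(nrow(sp$test), 20)
  expect_true(all(table(sp$test$entity) == 2))
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)

  # same seed: identical membership; different seed: same counts,
  # different membership
  sp2 <- stratified_split(coh, 0.2, seed = 11)
  expect_identical(sp$test$patient_id, sp2$test$patient_id)
  sp3 <- stratified_split(coh, 0.2, seed = 12)
  expect_equal(table(sp3$test$entity), table(sp$test$entity))
  expect_false(setequal(sp3$test$patient_id, sp$test$patient_id))

  # round-half-up: 9 patients at fraction 0.2 -> 2 test patients
  coh9 <- make_cohort(c(rep("ewing_sarcoma", 9), rep("NOF", 10)))
  sp9 <- stratified_split(coh9, 0.2, seed = 1)
  expect_equal(sum(sp9$test$entity == "ewing_sarcoma"), 2)

  # multi-image patients never reach the test set
  cohm <- make_cohort(rep(entity_levels(), each = 5),
                      n_images = rep(c(1, 1, 1, 2, 3), 10))
  spm <- stratified_split(cohm, 0.2, seed = 3)
  expect_true(all(lengths(spm$test$image_ids) == 1))

  # infeasible stratification names the offending class
  cohbad <- make_cohort(rep(c("ABC", "osteosarcoma"), each = 5),
                        n_images = c(rep(2L, 5), rep(1L, 5)))
  expect_error(stratified_split(cohbad, 0.2, seed = 1), "ABC")
})

test_that("per-entity test share tracks the class share", {
  cfg <- balanced_config(n_patients = 120, seed = 8)
  coh <- generate_cohort(cfg)
  sp <- stratified_split(coh, 0.2, seed = 2)
  for (ent in unique(coh$entity)) {
    class_share <- mean(coh$entity == ent)
    test_share <- mean(sp$test$entity == ent)
    expect_lte(abs(test_share - class_share), 1 / nrow(sp$test) + 1e-12)
  }
})

test_that("cohort summary reproduces the reference composition percentages", {
  cfg <- synthetic_config(
    n_patients = 809,
    exclusion_rates = c(inadequate_imaging = 0, incomplete_clinical = 0,
                        lost_followup = 0),
    seed = 42)
  s <- summarize_cohort(generate_cohort(cfg))
  pct <- function(block, level)
    s$counts$pct[s$counts$block == block & s$counts$level == level]
  expect_equal(pct("entity", "osteochondroma"), 28.31)
  expect_equal(pct("entity", "ewing_sarcoma"), 1.11)
  expect_equal(pct("sex", "male"), 54.76)
  expect_equal(pct("sex", "female"), 45.24)
  expect_equal(pct("location", "femur"), 36.71)
  expect_equal(pct("location", "os_sacrum"), 0.12)
  # blocks sum to the cohort and to ~100% after rounding
  for (b in unique(s$counts$block)) {
    blk <- s$counts[s$counts$block == b, ]
    expect_equal(sum(blk$n), 809)
    expect_lte(abs(sum(blk$pct) - 100), 0.05)
  }
  expect_true(s$age$shapiro_w > 0 && s$age$shapiro_w <= 1)
  expect_true(s$age$shapiro_p >= 0 && s$age$shapiro_p <= 1)
})

test_that("summary handles the single-patient edge and recovers generated tables", {
  s1 <- summarize_cohort(make_cohort("osteosarcoma"))
  expect_equal(
    s1$counts$pct[s1$counts$block == "entity" &
                    s1$counts$level == "osteosarcoma"], 100)

  # summarising a cohort generated from a frequency table recovers the
  # table's counts exactly (largest-remainder round trip)
  freq <- c(0.5, 0.3, 0.2)
  names(freq) <- c("enchondroma", "NOF", "osteosarcoma")
  cfg <- synthetic_config(
    n_patients = 40, entity_frequencies = freq,
    location_frequencies = c(femur = 1),
    exclusion_rates = c(inadequate_imaging = 0, incomplete_clinical = 0,
                        lost_followup = 0),
    seed = 5)
  s <- summarize_cohort(generate_cohort(cfg))
  got <- s$counts[s$counts$block == "entity" & s$counts$n > 0, ]
  expect_equal(stats::setNames(got$n, got$level),
               c(enchondroma = 20L, NOF = 12L, osteosarcoma = 8L))
  expect_error(summarize_cohort(make_cohort(character(0))), "empty")
})

test_that("cohort CSV round-trips including multi-image id lists", {
  coh <- make_cohort(rep(c("ABC", "osteochondroma"), 3),
                     n_images = c(1, 3, 2, 1, 1, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back, coh)
})
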