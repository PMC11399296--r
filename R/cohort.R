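#' Cohort tables
#'
#' A cohort is a plain tibble with one row per patient and the columns
#' `patient_id` (character, unique), `age` (integer years), `sex`
#' (`"male"`/`"female"`), `entity` (one of [entity_levels()]), `location`
#' (one of [location_levels()]), `source` (`"internal"`/`"external"`),
#' the three eligibility flags `flag_inadequate_imaging`,
#' `flag_incomplete_clinical`, `flag_lost_followup` (logical), and
#' `image_ids` (list-column of character radiograph ids). All cohort
#' functions take this tibble first and return tibbles, so calls chain
#' with the pipe.
#'
#' @name cohort
NULL

cohort_flag_cols <- function() {
  c("flag_inadequate_imaging", "flag_incomplete_clinical", "flag_lost_followup")
}

cohort_cols <- function() {
  c("patient_id", "age", "sex", "entity", "location", "source",
    cohort_flag_cols(), "image_ids")
}

#' Validate a cohort tibble
#'
#' Checks column presence, id uniqueness, label membership and flag types.
#' Returns its input invisibly so it can sit inside a pipe.
#'
#' @param cohort A cohort tibble (see [cohort]).
#' @param require_images Require at least one image id per patient
#'   (the invariant for an *included* cohort; screened cohorts may
#'   legitimately contain imageless patients).
#' @return `cohort`, invisibly.
#' @export
validate_cohort <- function(cohort, require_images = FALSE) {
  missing_cols <- setdiff(cohort_cols(), names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(cohort$patient_id) > 0) {
    abort("Cohort patient_id values must be unique.")
  }
  bad <- setdiff(unique(cohort$entity), entity_levels())
  if (length(bad) > 0) {
    abort(paste0("Unknown entity label(s): ", paste(bad, collapse = ", ")))
  }
  if (!all(purrr::map_lgl(cohort[cohort_flag_cols()], is.logical))) {
    abort("Eligibility flags must be logical.")
  }
  if (!is.list(cohort$image_ids)) {
    abort("`image_ids` must be a list-column of character vectors.")
  }
  if (require_images && any(lengths(cohort$image_ids) < 1)) {
    abort("Every included patient must carry at least one image.")
  }
  invisible(cohort)
}

#' Apply the eligibility filter
#'
#' A patient is included iff all three exclusion flags are false. When a
#' patient carries several flags, the exclusion is attributed to a single
#' reason under the fixed precedence
#' `inadequate_imaging > incomplete_clinical > lost_followup`, so the
#' per-reason counts partition the excluded set:
#' `nrow(included) + sum(exclusion_counts) == nrow(cohort)` always holds.
#'
#' @param cohort A cohort tibble.
#' @return A list with `included` (cohort tibble) and `exclusion_counts`
#'   (named integer vector over the three reasons).
#' @export
#' @examples
#' coh <- generate_cohort(synthetic_config(n_patients = 50, seed = 1))
#' flt <- apply_eligibility_filter(coh)
#' nrow(flt$included) + sum(flt$exclusion_counts) == nrow(coh)
apply_eligibility_filter <- function(cohort) {
  validate_cohort(cohort)
  if (nrow(cohort) == 0) {
    abort("Cannot filter an empty cohort.")
  }
  reasons <- c("inadequate_imaging", "incomplete_clinical", "lost_followup")
  flags <- as.matrix(cohort[cohort_flag_cols()])
  excluded <- rowSums(flags) > 0
  # precedence: first flagged column in the documented order wins
  reason_idx <- apply(flags, 1L, function(r) if (any(r)) which(r)[1] else NA_integer_)
  counts <- vapply(seq_along(reasons),
                   function(i) sum(reason_idx == i, na.rm = TRUE), integer(1))
  names(counts) <- reasons
  included <- cohort[!excluded, , drop = FALSE]
  validate_cohort(included, require_images = nrow(included) > 0)
  list(included = included, exclusion_counts = counts)
}

#' Stratified patient-level train/test split
#'
#' Splits a cohort into training and test sets stratified by tumour
#' entity so every entity is proportionally represented. The per-entity
#' test quota is `round_half_up(test_fraction * class size)`, clamped to
#' at least 1. When `test_single_image_only` (the default) the test set
#' is drawn only from patients with exactly one radiograph, so no image
#' of a test patient can appear in training.
#'
#' @param cohort A cohort tibble (included patients).
#' @param test_fraction Proportion of patients held out per entity,
#'   in (0, 1). Default 0.2.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param test_single_image_only Restrict test patients to those with a
#'   single image. Default `TRUE`.
#' @return A list with cohort tibbles `train` and `test`.
#' @export
stratified_split <- function(cohort, test_fraction = 0.2, seed = 1L,
                             test_single_image_only = TRUE) {
  validate_cohort(cohort, require_images = TRUE)
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must lie strictly between 0 and 1.")
  }
  seed <- check_seed(seed)
  counts <- table(cohort$entity)
  if (any(counts < 2)) {
    abort(paste0("Every entity needs at least 2 patients to split; too few: ",
                 paste(names(counts)[counts < 2], collapse = ", ")))
  }
  withr::with_seed(seed, {
    test_ids <- purrr::map(sort(unique(cohort$entity)), function(ent) {
      in_class <- cohort[cohort$entity == ent, , drop = FALSE]
      quota <- max(1L, round_half_up(test_fraction * nrow(in_class)))
      pool <- if (test_single_image_only) {
        in_class$patient_id[lengths(in_class$image_ids) == 1L]
      } else {
        in_class$patient_id
      }
      if (length(pool) < quota) {
        abort(paste0("Entity '", ent, "' has only ", length(pool),
                     " eligible single-image patient(s) for a test quota of ",
                     quota, "; stratification infeasible."))
      }
      sample(pool, quota)
    })
  })
  test_ids <- unlist(test_ids)
  list(train = cohort[!cohort$patient_id %in% test_ids, , drop = FALSE],
       test  = cohort[cohort$patient_id %in% test_ids, , drop = FALSE])
}

#' Summarise a cohort
#'
#' Per-entity, per-location and per-sex counts with percentages (two
#' decimals), plus age descriptives (mean, SD, median, IQR) and a
#' Shapiro-Wilk normality test on age.
#'
#' @param cohort A cohort tibble.
#' @return An object of class `cohort_summary`: a list with `counts`
#'   (tibble `block`, `level`, `n`, `pct`), `age` (one-row tibble), and
#'   `n_patients` / `n_images`. Has `print()` and [generics::tidy()]
#'   methods.
#' @export
summarize_cohort <- function(cohort) {
  validate_cohort(cohort)
  if (nrow(cohort) == 0) {
    abort("Cannot summarise an empty cohort.")
  }
  total <- nrow(cohort)
  one_block <- function(block, values, levels) {
    cnt <- as.integer(table(factor(values, levels = levels)))
    tibble::tibble(block = block,
                   level = levels,
                   n = cnt,
                   pct = round(100 * cnt / total, 2))
  }
  counts <- dplyr::bind_rows(
    one_block("entity", cohort$entity, entity_levels()),
    one_block("sex", cohort$sex, c("female", "male")),
    one_block("location", cohort$location, location_levels())
  )
  sw <- if (total >= 3 && stats::var(cohort$age) > 0) {
    shapiro.test(cohort$age)
  } else {
    list(statistic = NA_real_, p.value = NA_real_)
  }
  age <- tibble::tibble(
    mean = mean(cohort$age), sd = sd(cohort$age),
    median = median(cohort$age),
    iqr = unname(quantile(cohort$age, 0.75) - quantile(cohort$age, 0.25)),
    shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value
  )
  structure(
    list(counts = counts, age = age, n_patients = total,
         n_images = sum(lengths(cohort$image_ids))),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary:", x$n_patients, "patients,", x$n_images, "radiographs\n")
  cat(sprintf("Age: mean %.2f (SD %.2f), median %.2f, IQR %.2f; Shapiro-Wilk W = %.3f, p = %.3g\n",
              x$age$mean, x$age$sd, x$age$median, x$age$iqr,
              x$age$shapiro_w, x$age$shapiro_p))
  for (b in unique(x$counts$block)) {
    blk <- x$counts[x$counts$block == b, ]
    blk <- blk[blk$n > 0 | b != "location", ]
    cat(b, ":\n", sep = "")
    cat(sprintf("  %-22s %5d  %6.2f%%\n", blk$level, blk$n, blk$pct), sep = "")
  }
  invisible(x)
}

#' @export
tidy.cohort_summary <- function(x, ...) x$counts

#' @export
glance.cohort_summary <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n_patients = x$n_patients,
                                  n_images = x$n_images), x$age)
}

#' Read / write a cohort CSV
#'
#' The on-disk format is a plain CSV with header
#' `patient_id,age,sex,entity,location,source,flag_inadequate_imaging,flag_incomplete_clinical,flag_lost_followup,image_ids`,
#' where `image_ids` holds the patient's radiograph ids joined by `;`.
#'
#' @param path File path.
#' @param cohort A cohort tibble.
#' @return `read_cohort()` returns a cohort tibble; `write_cohort()`
#'   returns `cohort` invisibly.
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(), age = readr::col_integer(),
    sex = readr::col_character(), entity = readr::col_character(),
    location = readr::col_character(), source = readr::col_character(),
    flag_inadequate_imaging = readr::col_logical(),
    flag_incomplete_clinical = readr::col_logical(),
    flag_lost_followup = readr::col_logical(),
    image_ids = readr::col_character()
  ))
  raw$image_ids <- purrr::map(raw$image_ids, function(s) {
    if (is.na(s) || s == "") character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
  })
  validate_cohort(raw)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort
  out$image_ids <- purrr::map_chr(cohort$image_ids, paste, collapse = ";")
  readr::write_csv(out, path)
  invisible(cohort)
}
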