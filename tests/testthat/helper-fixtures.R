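# Small in-code fixtures shared across the suite.

# hand-built cohort: one row per element of `entities`, flags default
# all-false, one image per patient unless n_images says otherwise
make_cohort <- function(entities, n_images = NULL, ages = NULL,
                        flags = NULL, sexes = NULL) {
  n <- length(entities)
  n_images <- n_images %||% rep(1L, n)
  flags <- flags %||% matrix(FALSE, n, 3)
  pid <- sprintf("T%03d", seq_len(n))
  tibble::tibble(
    patient_id = pid,
    age = ages %||% rep(30L, n),
    sex = sexes %||% rep(c("male", "female"), length.out = n),
    entity = entities,
    location = rep(location_levels(), length.out = n),
    source = "internal",
    flag_inadequate_imaging = flags[, 1],
    flag_incomplete_clinical = flags[, 2],
    flag_lost_followup = flags[, 3],
    image_ids = purrr::map2(pid, n_images, function(p, m)
      if (m == 0) character(0) else paste0(p, "_im", seq_len(m)))
  )
}

# balanced uniform-entity config with no exclusions: the workhorse for
# image-based tests
balanced_config <- function(n_patients = 30, seed = 1, ...) {
  synthetic_config(
    n_patients = n_patients,
    entity_frequencies = stats::setNames(rep(0.1, 10), entity_levels()),
    images_per_patient = c(1L, 1L),
    exclusion_rates = c(inadequate_imaging = 0, incomplete_clinical = 0,
                        lost_followup = 0),
    seed = seed, ...)
}

# feature tibble straight from a vector matrix (rows = items)
features_from_matrix <- function(m, labels = NA_character_,
                                 ids = NULL, patients = NULL) {
  n <- nrow(m)
  colnames(m) <- paste0("v", seq_len(ncol(m)))
  dplyr::bind_cols(
    tibble::tibble(image_id = ids %||% sprintf("q%03d", seq_len(n)),
                   patient_id = patients %||% sprintf("qp%03d", seq_len(n)),
                   label = rep(labels, length.out = n)),
    tibble::as_tibble(m))
}

# batch_classify-shaped tibble built by hand from neighbour label lists
fake_results <- function(neighbour_labels, truths) {
  tibble::tibble(
    target_image_id = sprintf("t%02d", seq_along(neighbour_labels)),
    truth = truths,
    predicted_entity = purrr::map_chr(neighbour_labels, function(l)
      names(sort(table(l), decreasing = TRUE))[1]),
    tie_broken = FALSE,
    vote_breakdown = purrr::map(neighbour_labels, function(l)
      as.integer(table(l))),
    neighbours = purrr::map(neighbour_labels, function(l)
      tibble::tibble(rank = seq_along(l), image_id = paste0("n", seq_along(l)),
                     patient_id = paste0("p", seq_along(l)), label = l,
                     distance = seq_along(l), angular = seq_along(l) / 10))
  )
}
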