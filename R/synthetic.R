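#' Reference cohort composition
#'
#' The per-entity, per-location and per-sex patient counts of the
#' 809-patient reference cohort the synthetic generator emulates
#' (osteochondroma the most frequent entity at 28.31%, Ewing sarcoma
#' the rarest at 1.11%; femur the most frequent site at 36.71%).
#'
#' @return Named integer vector (sums to 809).
#' @export
reference_entity_counts <- function() {
  stats::setNames(
    c(49L, 18L, 124L, 181L, 9L, 31L, 51L, 33L, 229L, 84L),
    entity_levels())
}

#' @rdname reference_entity_counts
#' @export
reference_location_counts <- function() {
  stats::setNames(
    c(7L, 4L, 297L, 42L, 124L, 62L, 24L, 8L, 11L, 1L, 7L, 42L, 12L, 17L,
      146L, 5L),
    location_levels())
}

#' @rdname reference_entity_counts
#' @export
reference_sex_counts <- function() {
  c(female = 366L, male = 443L)
}

#' Largest-remainder apportionment
#'
#' Distributes `n` units over categories proportionally to `props`:
#' each category gets the floor of its quota, remaining units go to the
#' largest fractional remainders (earlier category wins exact ties).
#' Counts always sum to `n`.
#'
#' @param n Total units.
#' @param props Named non-negative weights (normalised internally).
#' @return Named integer vector summing to `n`.
#' @export
apportion_largest_remainder <- function(n, props) {
  if (any(props < 0)) abort("Proportions must be non-negative.")
  props <- props / sum(props)
  quota <- n * props
  base <- floor(quota + 1e-9)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(-(quota - base), seq_along(props))[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' Synthetic study configuration
#'
#' One configuration object drives all three generators
#' ([generate_cohort()], [generate_images()],
#' [generate_embeddings()]). The defaults emulate the reference study
#' conditions: a ten-entity cohort with the reference class imbalance,
#' one to a few radiographs per patient, three latent appearance modes
#' per entity (the same diagnosis looks different in different
#' anatomical settings), small additive pixel noise, and Gaussian
#' embedding clusters whose centroid spread is ten times the
#' within-mode SD.
#'
#' @param n_patients Number of screened patients. Default 809.
#' @param entity_frequencies Named entity proportions (sum 1). Default:
#'   reference counts / 809.
#' @param location_frequencies,male_fraction Analogous demographics.
#' @param images_per_patient `c(min, max)` of the uniform per-patient
#'   image count. Default `c(1, 3)`.
#' @param n_images_total Optional exact total image count over included
#'   patients (each gets at least one, the remainder is spread at
#'   random); overrides `images_per_patient` for included patients.
#' @param modes_per_entity Latent appearance modes M per entity.
#'   Default 3.
#' @param image_side Square image side in pixels. Default 96.
#' @param noise_sd Additive Gaussian pixel noise SD (intensity units).
#'   Default 0.02.
#' @param placement_jitter Motif centre jitter as a fraction of the
#'   image side. Default 0.04.
#' @param embedding_dim Embedding dimension D. Default 8.
#' @param cluster_sd Within-mode Gaussian SD. Default 1.
#' @param centroid_scale SD of the mode-centroid coordinates; the
#'   separation dial. Default 10.
#' @param vectors_per_mode Embeddings drawn per (entity, mode).
#'   Default 50.
#' @param exclusion_rates Named per-flag Bernoulli probabilities
#'   (`inadequate_imaging`, `incomplete_clinical`, `lost_followup`).
#' @param exclusion_counts Optional exact per-flag exclusion counts
#'   (disjoint patients), overriding `exclusion_rates`.
#' @param external_fraction Fraction of externally sourced patients.
#'   Default 0.1.
#' @param seed Integer seed; every generator output is byte-identical
#'   given the same (config, seed).
#' @return An object of class `synthetic_config` (a list).
#' @export
synthetic_config <- function(n_patients = 809L,
                             entity_frequencies = NULL,
                             location_frequencies = NULL,
                             male_fraction = 443 / 809,
                             images_per_patient = c(1L, 3L),
                             n_images_total = NULL,
                             modes_per_entity = 3L,
                             image_side = 96L,
                             noise_sd = 0.02,
                             placement_jitter = 0.04,
                             embedding_dim = 8L,
                             cluster_sd = 1,
                             centroid_scale = 10,
                             vectors_per_mode = 50L,
                             exclusion_rates = c(inadequate_imaging = 0.05,
                                                 incomplete_clinical = 0.003,
                                                 lost_followup = 0.035),
                             exclusion_counts = NULL,
                             external_fraction = 0.1,
                             seed = 1L) {
  entity_frequencies <- entity_frequencies %||%
    (reference_entity_counts() / 809)
  location_frequencies <- location_frequencies %||%
    (reference_location_counts() / 809)
  if (abs(sum(entity_frequencies) - 1) > 1e-9) {
    abort("`entity_frequencies` must sum to 1.")
  }
  if (cluster_sd <= 0) abort("`cluster_sd` must be > 0.")
  if (n_patients < 1 || modes_per_entity < 1 || embedding_dim < 2 ||
      vectors_per_mode < 1) {
    abort("Counts and dimensions must be positive (embedding_dim >= 2).")
  }
  structure(list(
    n_patients = as.integer(n_patients),
    entity_frequencies = entity_frequencies,
    location_frequencies = location_frequencies,
    male_fraction = male_fraction,
    images_per_patient = as.integer(images_per_patient),
    n_images_total = if (is.null(n_images_total)) NULL else
      as.integer(n_images_total),
    modes_per_entity = as.integer(modes_per_entity),
    image_side = as.integer(image_side),
    noise_sd = noise_sd, placement_jitter = placement_jitter,
    embedding_dim = as.integer(embedding_dim),
    cluster_sd = cluster_sd, centroid_scale = centroid_scale,
    vectors_per_mode = as.integer(vectors_per_mode),
    exclusion_rates = exclusion_rates,
    exclusion_counts = exclusion_counts,
    external_fraction = external_fraction,
    seed = check_seed(seed)
  ), class = "synthetic_config")
}

# ages: two-component mixture (paediatric/adolescent peak + older adult
# tail) truncated to 3..89, mimicking a right-skewed bone-tumour cohort
draw_ages <- function(n) {
  young <- runif(n) < 0.5
  a <- ifelse(young, rnorm(n, 18, 7), rnorm(n, 48, 15))
  as.integer(pmin(89, pmax(3, round(a))))
}

#' Generate a synthetic screened cohort
#'
#' Entity, location and sex counts are largest-remainder apportionments
#' of the configured frequencies (so a cohort of 809 with the default
#' frequencies reproduces the reference composition exactly);
#' assignments are then randomly permuted across patients. Ages follow
#' a right-skewed mixture spanning 3–89 years. Exclusion flags are
#' drawn per `exclusion_rates`, or placed on exactly
#' `exclusion_counts` disjoint patients when given. Patients flagged
#' for inadequate imaging carry no radiographs; all other patients
#' carry `images_per_patient` images (or the `n_images_total`
#' apportionment for included patients).
#'
#' @param config A [synthetic_config()].
#' @return A cohort tibble (see [cohort]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_patients
  withr::with_seed(config$seed, {
    entity <- sample(rep(names(config$entity_frequencies),
                         apportion_largest_remainder(n, config$entity_frequencies)))
    location <- sample(rep(names(config$location_frequencies),
                           apportion_largest_remainder(n, config$location_frequencies)))
    sex <- sample(rep(c("male", "female"),
                      apportion_largest_remainder(
                        n, c(male = config$male_fraction,
                             female = 1 - config$male_fraction))))
    source <- sample(rep(c("external", "internal"),
                         apportion_largest_remainder(
                           n, c(external = config$external_fraction,
                                internal = 1 - config$external_fraction))))
    age <- draw_ages(n)
    flags <- matrix(FALSE, n, 3,
                    dimnames = list(NULL, cohort_flag_cols()))
    if (!is.null(config$exclusion_counts)) {
      cnt <- config$exclusion_counts
      if (sum(cnt) > n) abort("More exclusions than patients.")
      picked <- sample(n, sum(cnt))
      at <- 0L
      for (j in seq_along(cnt)) {
        if (cnt[j] > 0) flags[picked[at + seq_len(cnt[j])], j] <- TRUE
        at <- at + cnt[j]
      }
    } else {
      for (j in seq_len(3)) {
        flags[, j] <- runif(n) < config$exclusion_rates[j]
      }
    }
    n_img <- sample(seq(config$images_per_patient[1],
                        config$images_per_patient[2]),
                    n, replace = TRUE)
    n_img[flags[, 1]] <- 0L  # inadequate imaging: no usable radiographs
    included <- rowSums(flags) == 0
    if (!is.null(config$n_images_total)) {
      n_inc <- sum(included)
      if (config$n_images_total < n_inc) {
        abort("`n_images_total` is below one image per included patient.")
      }
      extra <- config$n_images_total - n_inc
      # each included patient starts at 1 image; spread the remainder by
      # sampling free slots (capacity max - 1 per patient) without
      # replacement, so plenty of single-image patients remain
      slots <- rep(seq_len(n_inc),
                   each = max(1L, config$images_per_patient[2] - 1L))
      if (extra > length(slots)) {
        abort("`n_images_total` exceeds images_per_patient capacity.")
      }
      alloc <- 1L + tabulate(sample(slots, extra), nbins = n_inc)
      n_img[included] <- alloc
    }
    n_img[included] <- pmax(1L, n_img[included])
  })
  patient_id <- sprintf("P%04d", seq_len(n))
  coh <- tibble::tibble(
    patient_id = patient_id, age = age, sex = sex, entity = entity,
    location = location, source = source,
    flag_inadequate_imaging = flags[, 1],
    flag_incomplete_clinical = flags[, 2],
    flag_lost_followup = flags[, 3],
    image_ids = purrr::map2(patient_id, n_img, function(p, m)
      if (m == 0) character(0) else paste0(p, "_im", seq_len(m)))
  )
  validate_cohort(coh)
  coh
}
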