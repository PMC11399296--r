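#' Render one synthetic lesion motif
#'
#' Draws the parametric motif of an (entity, mode) pair onto a blank
#' frame: each entity has a base shape (ellipse, annulus, rectangle,
#' diamond, cross, crescent, superellipse, triangle, double blob,
#' star), and each latent mode changes its size, aspect, orientation,
#' texture frequency and base intensity — the same diagnosis with
#' several distinct visual appearances. The motif's support is returned
#' as the ROI ground-truth mask; additive Gaussian noise at
#' `config$noise_sd` is applied to the pixels only.
#'
#' @param entity One of [entity_levels()].
#' @param mode Mode index in `1..config$modes_per_entity`.
#' @param config A [synthetic_config()].
#' @param jitter Centre offset in pixels, `c(row, col)`; bounded by the
#'   caller so the motif stays inside the frame.
#' @param image_id,patient_id Identifiers for the returned radiograph.
#' @return A [radiograph] with mask. The noise draw uses the current
#'   RNG state; seed via `withr::with_seed()` for reproducibility.
#' @export
render_motif <- function(entity, mode, config, jitter = c(0, 0),
                         image_id = "img", patient_id = "pat") {
  side <- config$image_side
  if (side < 32) abort("`image_side` too small to hold a motif (min 32).")
  shape_idx <- match(entity, entity_levels())
  if (is.na(shape_idx)) abort(paste0("Unknown entity: ", entity))
  m <- as.integer(mode)
  if (m < 1 || m > config$modes_per_entity) abort("Mode out of range.")

  # mode-specific geometry and texture
  scale <- 0.92 - 0.22 * ((m - 1) %% 3)
  aspect <- c(1, 0.55, 1.55)[1 + (m - 1) %% 3]
  angle <- (m - 1) * pi / 5 + (shape_idx - 1) * pi / 17
  freq <- 2 + 3 * ((m - 1) %% 3) + (shape_idx %% 2)
  base_int <- 0.55 + 0.1 * ((m - 1) %% 3)

  r <- 0.26 * side * scale
  cy <- side / 2 + jitter[1]
  cx <- side / 2 + jitter[2]
  yy <- matrix(seq_len(side), side, side) - cy
  xx <- matrix(seq_len(side), side, side, byrow = TRUE) - cx
  u <- (cos(angle) * xx + sin(angle) * yy) / (r * aspect)
  v <- (-sin(angle) * xx + cos(angle) * yy) / (r / aspect)

  inside <- switch(shape_idx,
    u^2 + v^2 <= 1,                                        # ellipse
    { d <- u^2 + v^2; d <= 1 & d >= 0.45 },                # annulus
    abs(u) <= 1 & abs(v) <= 0.8,                           # rectangle
    abs(u) + abs(v) <= 1.1,                                # diamond
    (abs(u) <= 0.35 & abs(v) <= 1) | (abs(v) <= 0.35 & abs(u) <= 1), # cross
    (u^2 + v^2 <= 1) & ((u - 0.45)^2 + v^2 > 0.55),        # crescent
    u^4 + v^4 <= 1,                                        # superellipse
    v <= 0.7 & v >= -0.7 & abs(u) <= (0.7 - v) / 1.4,      # triangle
    ((u - 0.45)^2 + v^2 <= 0.45) | ((u + 0.45)^2 + v^2 <= 0.45), # blobs
    { th <- atan2(v, u); u^2 + v^2 <= (0.75 + 0.25 * cos(5 * th))^2 } # star
  )
  texture <- base_int +
    0.22 * sin(2 * pi * freq * (u * cos(angle) - v * sin(angle)) / 2.2)
  px <- 0.15 + 0.05 * (yy + cy) / side          # faint background gradient
  px[inside] <- texture[inside]
  if (config$noise_sd > 0) {
    px <- px + rnorm(length(px), 0, config$noise_sd)
  }
  px <- pmin(pmax(px, 0), 1)  # arg order keeps the matrix dims
  radiograph(px, image_id = image_id, patient_id = patient_id,
             mask = inside * 1)
}

#' Generate synthetic radiographs for a cohort
#'
#' Assigns each patient a hidden appearance mode (uniform over
#' `modes_per_entity`); all images of a patient share the patient's
#' (entity, mode) and differ only by bounded placement jitter and pixel
#' noise. The generating mask of each motif is attached as ROI ground
#' truth. Deterministic given (`cohort`, `config$seed`).
#'
#' @param cohort An included cohort tibble (every patient has images).
#' @param config A [synthetic_config()].
#' @return List of [radiograph] objects, in cohort/image order. The
#'   hidden per-patient modes are attached as attribute `"modes"`
#'   (named by patient id) for generator diagnostics only — downstream
#'   modules never see them.
#' @export
generate_images <- function(cohort, config) {
  validate_cohort(cohort, require_images = TRUE)
  stopifnot(inherits(config, "synthetic_config"))
  jmax <- config$placement_jitter * config$image_side
  withr::with_seed(config$seed + 1L, {
    modes <- sample.int(config$modes_per_entity, nrow(cohort), replace = TRUE)
    out <- purrr::flatten(purrr::map(seq_len(nrow(cohort)), function(i) {
      purrr::map(cohort$image_ids[[i]], function(iid) {
        render_motif(cohort$entity[i], modes[i], config,
                     jitter = runif(2, -jmax, jmax),
                     image_id = iid, patient_id = cohort$patient_id[i])
      })
    }))
  })
  attr(out, "modes") <- stats::setNames(modes, cohort$patient_id)
  out
}

#' Generate labelled Gaussian embeddings
#'
#' The image-free route for exercising indexing, retrieval and voting
#' directly: each of the `10 x modes_per_entity` (entity, mode) pairs
#' gets an isotropic Gaussian centroid with coordinates drawn at SD
#' `centroid_scale`, and `vectors_per_mode` points are sampled around
#' it at SD `cluster_sd`. Labels are entities only — the modes stay
#' latent, which is exactly the structure where one linear prototype
#' per class fails while k-NN majority voting does not.
#'
#' @param config A [synthetic_config()].
#' @return Feature tibble (`image_id`, `patient_id`, `label`,
#'   `v1..vD`), with hidden modes in attribute `"modes"`.
#' @export
generate_embeddings <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  d <- config$embedding_dim
  m <- config$modes_per_entity
  npm <- config$vectors_per_mode
  ents <- names(config$entity_frequencies)
  withr::with_seed(config$seed + 2L, {
    centroids <- matrix(rnorm(length(ents) * m * d, 0, config$centroid_scale),
                        ncol = d)
    rows <- purrr::map_dfr(seq_len(length(ents) * m), function(g) {
      pts <- matrix(rnorm(npm * d, 0, config$cluster_sd), ncol = d) +
        matrix(centroids[g, ], npm, d, byrow = TRUE)
      colnames(pts) <- feature_cols(d)
      ent <- ents[1 + (g - 1) %/% m]
      idx <- sprintf("%s_m%d_%03d", ent, 1 + (g - 1) %% m, seq_len(npm))
      dplyr::bind_cols(
        tibble::tibble(image_id = paste0("E_", idx),
                       patient_id = paste0("SP_", idx),
                       label = ent),
        tibble::as_tibble(pts))
    })
  })
  attr(rows, "modes") <- rep(rep(seq_len(m), each = npm), length(ents))
  rows
}
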