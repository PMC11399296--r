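#' Extractor specification
#'
#' An extractor turns a cropped, normalised radiograph into a
#' fixed-length embedding. Two backends share one contract:
#'
#' * `"reference"` — a deterministic handcrafted descriptor: the image
#'   is padded to a square (aspect preserved), resized to
#'   `input_side` x `input_side`, then described by a `grid` x `grid`
#'   mean-intensity grid concatenated with a `bins`-bin
#'   gradient-orientation histogram. Fitting only records per-feature
#'   standardisation statistics from the training images.
#' * `"pca"` — a learned linear backbone: the reference descriptor
#'   followed by a PCA projection fitted on the training images only.
#'
#' With the defaults (8x8 grid + 16 bins) the reference descriptor has
#' dimension 80. Embeddings are L2-normalised by default so that
#' sign-of-projection hashing approximates angular distance.
#'
#' @param kind `"reference"` or `"pca"`.
#' @param grid Intensity grid side (features `grid^2`).
#' @param bins Gradient-orientation histogram bins.
#' @param input_side Square resize target in pixels.
#' @param n_components PCA output dimension (`"pca"` only).
#' @param l2_normalise L2-normalise final embeddings. Default `TRUE`.
#' @param seed Integer seed (unused by these deterministic backends but
#'   part of the contract).
#' @return An object of class `extractor_spec`.
#' @export
extractor_spec <- function(kind = c("reference", "pca"), grid = 8L,
                           bins = 16L, input_side = 128L,
                           n_components = 32L, l2_normalise = TRUE,
                           seed = 0L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, grid = as.integer(grid),
                 bins = as.integer(bins), input_side = as.integer(input_side),
                 n_components = as.integer(n_components),
                 l2_normalise = isTRUE(l2_normalise),
                 seed = check_seed(seed)),
            class = "extractor_spec")
}

# pad to square then bilinear-resize; returns side x side matrix
resize_square <- function(px, side) {
  nr <- nrow(px); nc <- ncol(px)
  if (nr == 0 || nc == 0) abort("Empty image.")
  ext <- max(nr, nc)
  sq <- matrix(0, ext, ext)
  r0 <- (ext - nr) %/% 2L
  c0 <- (ext - nc) %/% 2L
  sq[r0 + seq_len(nr), c0 + seq_len(nc)] <- px
  EBImage::resize(sq, w = side, h = side)
}

#' Raw reference descriptor of one image
#'
#' The unstandardised descriptor: coarse intensity grid means followed
#' by a magnitude-weighted gradient-orientation histogram (normalised by
#' total gradient magnitude; all-zero for a constant image).
#'
#' @param image A [radiograph] or bare pixel matrix.
#' @param grid,bins,input_side As in [extractor_spec()].
#' @return Numeric vector of length `grid^2 + bins`.
#' @export
reference_descriptor <- function(image, grid = 8L, bins = 16L,
                                 input_side = 128L) {
  px <- if (inherits(image, "radiograph")) image$pixels else image
  px <- resize_square(px, input_side)
  side <- nrow(px)
  cut_idx <- function(i) as.integer(cut(seq_len(side), breaks = grid))
  block_means <- as.vector(t(
    vapply(split(seq_len(side), cut_idx()), function(rows)
      vapply(split(seq_len(side), cut_idx()), function(cols)
        mean(px[rows, cols]), numeric(1)),
      numeric(grid))
  ))
  # central-difference gradients on the interior
  inner <- 2:(side - 1)
  gx <- px[inner, inner + 1] - px[inner, inner - 1]
  gy <- px[inner + 1, inner] - px[inner - 1, inner]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)                       # [-pi, pi]
  bin <- pmin(bins, 1L + floor((ang + pi) / (2 * pi) * bins))
  hist <- vapply(seq_len(bins), function(b) sum(mag[bin == b]), numeric(1))
  tot <- sum(mag)
  if (tot > 0) hist <- hist / tot
  c(block_means, hist)
}

raw_features <- function(images, spec) {
  t(vapply(images, reference_descriptor, numeric(spec$grid^2 + spec$bins),
           grid = spec$grid, bins = spec$bins, input_side = spec$input_side))
}

#' Fit an extractor on training images
#'
#' For the reference backend, fitting records per-feature mean and scale
#' (SD; 1 where a feature is constant) over the training descriptors.
#' For the PCA backend it additionally fits the linear projection. Only
#' the supplied images are touched; every image id read during fitting
#' is recorded in `$fitted_on` so train/test hygiene is auditable.
#'
#' @param train_images List of [radiograph] objects (training set only).
#' @param spec An [extractor_spec()].
#' @return An object of class `radrec_extractor` with fields `spec`,
#'   `dim`, `center`, `scale`, optional `rotation`, and `fitted_on`.
#' @export
fit_extractor <- function(train_images, spec = extractor_spec()) {
  stopifnot(inherits(spec, "extractor_spec"))
  if (length(train_images) < 1) abort("Need at least one training image.")
  feats <- raw_features(train_images, spec)
  if (!all(is.finite(feats))) abort("Non-finite training descriptors.")
  center <- colMeans(feats)
  scale <- apply(feats, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  ex <- list(spec = spec, center = center, scale = scale, rotation = NULL,
             dim = length(center),
             fitted_on = purrr::map_chr(train_images, "image_id"))
  if (spec$kind == "pca") {
    z <- sweep(sweep(feats, 2, center), 2, scale, "/")
    d <- min(spec$n_components, ncol(z), nrow(z))
    pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
    ex$rotation <- pc$rotation[, seq_len(d), drop = FALSE]
    ex$dim <- d
  }
  structure(ex, class = "radrec_extractor")
}

#' @export
print.radrec_extractor <- function(x, ...) {
  cat(sprintf("<radrec_extractor %s> dim %d, fitted on %d image(s)\n",
              x$spec$kind, x$dim, length(x$fitted_on)))
  invisible(x)
}

#' Embed one image
#'
#' Applies the fitted extractor: raw descriptor, train-set
#' standardisation, optional PCA projection, optional L2 normalisation.
#' Deterministic: identical images give bit-identical vectors.
#'
#' @param extractor A fitted [fit_extractor()] object.
#' @param image A [radiograph] or pixel matrix.
#' @return Numeric vector of length `extractor$dim`.
#' @export
extract_features <- function(extractor, image) {
  stopifnot(inherits(extractor, "radrec_extractor"))
  v <- reference_descriptor(image, extractor$spec$grid, extractor$spec$bins,
                            extractor$spec$input_side)
  v <- (v - extractor$center) / extractor$scale
  if (!is.null(extractor$rotation)) v <- as.vector(v %*% extractor$rotation)
  if (extractor$spec$l2_normalise) {
    n <- sqrt(sum(v^2))
    if (n > 0) v <- v / n
  }
  if (!all(is.finite(v))) abort("Non-finite embedding.")
  v
}

feature_cols <- function(d) paste0("v", seq_len(d))

#' Embed a batch of images into a feature tibble
#'
#' @param extractor A fitted extractor.
#' @param images List of [radiograph] objects.
#' @param labels Optional entity labels: a named character vector keyed
#'   by image id, or a cohort tibble (labels joined via patient id).
#' @return A tibble with columns `image_id`, `patient_id`, `label`, and
#'   `v1..vD` — the feature-store layout used by [build_lsh_index()].
#' @export
embed_images <- function(extractor, images, labels = NULL) {
  mat <- t(vapply(images, function(im) extract_features(extractor, im),
                  numeric(extractor$dim)))
  ids <- purrr::map_chr(images, "image_id")
  pats <- purrr::map_chr(images, "patient_id")
  lab <- if (is.null(labels)) {
    rep(NA_character_, length(ids))
  } else if (is.data.frame(labels)) {
    labels$entity[match(pats, labels$patient_id)]
  } else {
    unname(labels[ids])
  }
  colnames(mat) <- feature_cols(extractor$dim)
  dplyr::bind_cols(tibble::tibble(image_id = ids, patient_id = pats,
                                  label = lab),
                   tibble::as_tibble(mat))
}

#' Extract the embedding matrix from a feature tibble
#'
#' @param features A feature tibble (`image_id`, `patient_id`, `label`,
#'   `v1..vD`).
#' @return Numeric matrix, one row per image, rownames = image ids.
#' @export
embedding_matrix <- function(features) {
  vc <- grep("^v[0-9]+$", names(features), value = TRUE)
  if (length(vc) == 0) abort("No feature columns v1..vD found.")
  m <- as.matrix(features[vc[order(as.integer(sub("v", "", vc)))]])
  rownames(m) <- features$image_id
  storage.mode(m) <- "double"
  m
}

#' Persist / restore a feature store
#'
#' Writes the feature tibble as CSV plus a JSON sidecar
#' (`<path>.json`) holding the extractor specification and
#' standardisation statistics; the round trip is bit-exact.
#'
#' @param features Feature tibble, as from [embed_images()].
#' @param extractor The fitted extractor that produced it.
#' @param path CSV path.
#' @return `read_feature_store()` returns `list(features, extractor)`.
#' @export
write_feature_store <- function(features, extractor, path) {
  stopifnot(inherits(extractor, "radrec_extractor"))
  d <- ncol(embedding_matrix(features))
  if (d != extractor$dim) {
    abort(sprintf("Dimension mismatch: features have D = %d, extractor D = %d.",
                  d, extractor$dim))
  }
  out <- as.data.frame(features)
  num <- vapply(out, is.numeric, logical(1))
  # 17 significant digits guarantee a bit-exact strtod round trip
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  side <- list(spec = unclass(extractor$spec), center = extractor$center,
               scale = extractor$scale, rotation = extractor$rotation,
               dim = extractor$dim, fitted_on = extractor$fitted_on)
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(features)
}

#' @rdname write_feature_store
#' @export
read_feature_store <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  vc <- grep("^v[0-9]+$", names(raw), value = TRUE)
  raw[vc] <- lapply(raw[vc], as.numeric)  # strtod: correctly rounded
  raw$label[raw$label == "NA" | raw$label == ""] <- NA_character_
  features <- tibble::as_tibble(raw)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- do.call(extractor_spec, side$spec[c("kind", "grid", "bins",
                                              "input_side", "n_components",
                                              "l2_normalise", "seed")])
  ex <- structure(list(spec = spec, center = side$center, scale = side$scale,
                       rotation = if (is.null(side$rotation)) NULL else
                         as.matrix(side$rotation),
                       dim = side$dim, fitted_on = side$fitted_on),
                  class = "radrec_extractor")
  if (ncol(embedding_matrix(features)) != ex$dim) {
    abort("Corrupt feature store: dimension mismatch with sidecar.")
  }
  list(features = features, extractor = ex)
}
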