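#' Random-hyperplane LSH index over embeddings
#'
#' Hashes each embedding into a `bits`-long binary signature: bit *b* is
#' 1 iff the dot product with the *b*-th random hyperplane direction is
#' `>= 0` (ties hash to 1). For unit vectors the expected normalised
#' hamming distance between two signatures equals their angle divided by
#' pi, so hamming k-NN over signatures approximates angular k-NN over
#' the embeddings. With `tables > 1`, independent hyperplane sets are
#' drawn and an item's query distance is its minimum across tables.
#'
#' @param features Feature tibble (`image_id`, `patient_id`, `label`,
#'   `v1..vD`), typically [embed_images()] output on the training set.
#' @param bits Signature length B (default 128).
#' @param tables Number of independent hash tables T (default 1).
#' @param seed Integer seed for the hyperplane draws; the index is fully
#'   deterministic given (`features` order, `bits`, `tables`, `seed`).
#' @return An object of class `lsh_index`.
#' @export
build_lsh_index <- function(features, bits = 128L, tables = 1L, seed = 1L) {
  vectors <- embedding_matrix(features)
  if (nrow(vectors) == 0) abort("Cannot index an empty feature set.")
  if (ncol(vectors) < 1) abort("Zero-dimensional embeddings.")
  bits <- as.integer(bits); tables <- as.integer(tables)
  if (bits < 1 || tables < 1) abort("`bits` and `tables` must be >= 1.")
  seed <- check_seed(seed)
  d <- ncol(vectors)
  hyperplanes <- withr::with_seed(seed, {
    purrr::map(seq_len(tables), function(t)
      matrix(rnorm(bits * d), nrow = bits, ncol = d))
  })
  signatures <- purrr::map(hyperplanes, function(h) {
    s <- (vectors %*% t(h) >= 0) * 1L
    dimnames(s) <- NULL
    storage.mode(s) <- "integer"
    s
  })
  structure(list(
    bits = bits, tables = tables, dim = d, seed = seed,
    n = nrow(vectors), hyperplanes = hyperplanes, signatures = signatures,
    vectors = vectors, norms = sqrt(rowSums(vectors^2)),
    item_ids = features$image_id, patient_ids = features$patient_id,
    labels = features$label
  ), class = "lsh_index")
}

#' @export
print.lsh_index <- function(x, ...) {
  cat(sprintf("<lsh_index> %d items, D = %d, B = %d bits x %d table(s), seed %d\n",
              x$n, x$dim, x$bits, x$tables, x$seed))
  invisible(x)
}

#' Hamming distance between two bit signatures
#'
#' Accepts binary character strings (`"0101"`) or 0/1 integer/logical
#' vectors of equal length.
#'
#' @param a,b Signatures of equal length.
#' @return Integer count of differing bits.
#' @export
#' @examples
#' hamming_distance("1010", "0101")  # 4
hamming_distance <- function(a, b) {
  to_bits <- function(x) {
    if (is.character(x)) {
      as.integer(strsplit(x, "", fixed = TRUE)[[1]])
    } else {
      as.integer(x)
    }
  }
  a <- to_bits(a); b <- to_bits(b)
  if (length(a) != length(b)) {
    abort(sprintf("Signature lengths differ: %d vs %d.", length(a), length(b)))
  }
  sum(a != b)
}

# signature of one query vector under table t's hyperplanes
query_signature <- function(index, target, t = 1L) {
  as.integer(index$hyperplanes[[t]] %*% target >= 0)
}

angular_distance <- function(u, v) {
  cs <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(pmin(1, pmax(-1, cs)))
}

#' Hamming k-NN query against an LSH index
#'
#' Scans all stored signatures, ranking items by hamming distance to
#' the query's signature (minimum across tables when `tables > 1`).
#' With `rerank = TRUE` (default) hamming ties are ordered by exact
#' angular distance in the embedding space; remaining ties keep
#' insertion order.
#'
#' @param index An [build_lsh_index()] object.
#' @param target Query embedding: numeric vector of length `index$dim`.
#' @param k Number of neighbours, `1 <= k <= index$n`.
#' @param rerank Break hamming ties by true angular distance.
#' @return A tibble with `rank`, `image_id`, `patient_id`, `label`,
#'   `distance` (hamming) and `angular` (exact angular distance).
#' @export
lsh_query <- function(index, target, k, rerank = TRUE) {
  stopifnot(inherits(index, "lsh_index"))
  if (length(target) != index$dim) {
    abort(sprintf("Query dimension %d does not match index dimension %d.",
                  length(target), index$dim))
  }
  k <- as.integer(k)
  if (k < 1 || k > index$n) {
    abort(sprintf("k = %d must lie in 1..N (index holds N = %d items).",
                  k, index$n))
  }
  per_table <- vapply(seq_len(index$tables), function(t) {
    qs <- query_signature(index, target, t)
    as.integer(index$signatures[[t]] %*% (1L - 2L * qs) + sum(qs))
  }, integer(index$n))
  dist <- if (index$tables == 1) as.vector(per_table) else
    apply(per_table, 1, min)
  norms <- index$norms %||% sqrt(rowSums(index$vectors^2))
  cs <- as.vector(index$vectors %*% target) /
    (norms * sqrt(sum(target^2)))
  ang <- acos(pmin(pmax(cs, -1), 1))
  ord <- if (rerank) {
    order(dist, ang, seq_len(index$n))
  } else {
    order(dist, seq_len(index$n))
  }
  top <- ord[seq_len(k)]
  tibble::tibble(rank = seq_len(k), image_id = index$item_ids[top],
                 patient_id = index$patient_ids[top],
                 label = index$labels[top], distance = dist[top],
                 angular = ang[top])
}

#' Exact brute-force k-NN (testing oracle)
#'
#' Computes exact nearest neighbours by a full scan under the chosen
#' metric; ties keep insertion order. This is the slow exact path the
#' hash-based retrieval is checked against.
#'
#' @param features Feature tibble or bare embedding matrix.
#' @param target Query vector.
#' @param k Number of neighbours.
#' @param metric `"angular"` (scale-invariant) or `"euclidean"`.
#' @return Tibble with `rank`, `image_id` (row name or index), `distance`.
#' @export
brute_force_knn <- function(features, target, k,
                            metric = c("angular", "euclidean")) {
  metric <- match.arg(metric)
  m <- if (is.matrix(features)) features else embedding_matrix(features)
  if (k < 1 || k > nrow(m)) {
    abort(sprintf("k = %d must lie in 1..N (N = %d).", k, nrow(m)))
  }
  dist <- switch(metric,
    angular = vapply(seq_len(nrow(m)),
                     function(i) angular_distance(m[i, ], target), numeric(1)),
    euclidean = sqrt(rowSums(sweep(m, 2, target)^2))
  )
  ord <- order(dist, seq_len(nrow(m)))[seq_len(k)]
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  tibble::tibble(rank = seq_len(as.integer(k)), image_id = ids[ord],
                 distance = unname(dist[ord]))
}

bits_to_hex <- function(bits) {
  pad <- (-length(bits)) %% 4
  bits <- c(bits, rep(0L, pad))
  nib <- matrix(bits, nrow = 4)
  paste(c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
          "a", "b", "c", "d", "e", "f")[
    1 + colSums(nib * c(8L, 4L, 2L, 1L))], collapse = "")
}

hex_to_bits <- function(hex, n_bits) {
  vals <- strtoi(strsplit(hex, "", fixed = TRUE)[[1]], 16L)
  bits <- as.vector(vapply(vals, function(v)
    as.integer(bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0), integer(4)))
  bits[seq_len(n_bits)]
}

#' Persist / restore an LSH index
#'
#' JSON layout: a header (`bits`, `tables`, `dim`, `seed`, `n`),
#' hex-packed signatures per table, the item payload (ids, patient ids,
#' labels), hyperplanes and stored vectors. The round trip is bit-exact
#' and the signatures remain recomputable from hyperplanes and vectors.
#'
#' @param index An `lsh_index`.
#' @param path Output JSON path.
#' @return `read_lsh_index()` returns the restored `lsh_index`.
#' @export
write_lsh_index <- function(index, path) {
  stopifnot(inherits(index, "lsh_index"))
  obj <- list(
    header = list(bits = index$bits, tables = index$tables, dim = index$dim,
                  seed = index$seed, n = index$n),
    signatures = purrr::map(index$signatures, function(s)
      apply(s, 1, bits_to_hex)),
    item_ids = index$item_ids, patient_ids = index$patient_ids,
    labels = index$labels,
    hyperplanes = purrr::map(index$hyperplanes, identity),
    vectors = index$vectors
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(index)
}

#' @rdname write_lsh_index
#' @export
read_lsh_index <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- obj$header
  sig_list <- obj$signatures
  if (is.matrix(sig_list)) {  # simplification rbinds one row per table
    sig_list <- lapply(seq_len(nrow(sig_list)), function(i) sig_list[i, ])
  } else if (is.character(sig_list)) {
    sig_list <- list(sig_list)
  }
  hp <- obj$hyperplanes
  if (is.matrix(hp)) hp <- list(hp)
  if (is.array(hp) && length(dim(hp)) == 3) {
    hp <- purrr::map(seq_len(dim(hp)[1]), function(i) hp[i, , ])
  }
  vectors <- as.matrix(obj$vectors)
  dimnames(vectors) <- list(obj$item_ids, feature_cols(h$dim))
  structure(list(
    bits = h$bits, tables = h$tables, dim = h$dim, seed = h$seed, n = h$n,
    hyperplanes = purrr::map(hp, function(m) {
      m <- as.matrix(m); dimnames(m) <- NULL; m
    }),
    signatures = purrr::map(sig_list, function(hexes) {
      s <- t(vapply(hexes, hex_to_bits, integer(h$bits), n_bits = h$bits))
      dimnames(s) <- NULL
      s
    }),
    vectors = vectors, item_ids = obj$item_ids,
    patient_ids = obj$patient_ids, labels = obj$labels
  ), class = "lsh_index")
}
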