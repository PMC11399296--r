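#' Retrieve similar cases and classify by majority vote
#'
#' Retrieves the `k` nearest previously diagnosed images (hamming k-NN
#' over the LSH index) and predicts the query's tumour entity as the
#' most frequent label among them. `k` must be odd — odd values keep
#' two-class votes decisive — but with ten entities ties between three
#' or more classes remain possible; they are broken by (1) smallest
#' summed hamming distance among the tied classes, (2) smallest best
#' rank, (3) lexicographic label order. `tie_broken` records whether the
#' argmax was non-unique.
#'
#' @param index An [build_lsh_index()] object over training embeddings.
#' @param target Query embedding vector (length `index$dim`).
#' @param k Odd neighbour count, `k <= index$n`. Default 3; the
#'   practical menu is `{1, 3, 5, 7}` since the rarest entity may have
#'   as few as nine cases.
#' @param target_image_id Identifier carried into the result.
#' @param rerank Passed to [lsh_query()].
#' @return An object of class `retrieval_result`: list with
#'   `target_image_id`, `neighbours` (ranked tibble), `predicted_entity`,
#'   `vote_breakdown` (named integer, sums to `k`), `tie_broken`.
#' @export
recommend <- function(index, target, k = 3L, target_image_id = "target",
                      rerank = TRUE) {
  k <- as.integer(k)
  if (k %% 2L == 0L) {
    abort(sprintf(
      "k = %d is even; only odd k gives a meaningful majority vote.", k))
  }
  nb <- lsh_query(index, target, k, rerank = rerank)
  votes <- sort(table(nb$label), decreasing = TRUE)
  top <- names(votes)[votes == max(votes)]
  tie <- length(top) > 1
  if (tie) {
    summed <- vapply(top, function(l) sum(nb$distance[nb$label == l]),
                     numeric(1))
    best_rank <- vapply(top, function(l) min(nb$rank[nb$label == l]),
                        numeric(1))
    top <- top[order(summed, best_rank, top)]
  }
  breakdown <- as.integer(votes)
  names(breakdown) <- names(votes)
  structure(list(target_image_id = target_image_id, neighbours = nb,
                 predicted_entity = top[1], vote_breakdown = breakdown,
                 tie_broken = tie),
            class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat(sprintf("<retrieval_result %s> k = %d -> %s%s\n", x$target_image_id,
              nrow(x$neighbours), x$predicted_entity,
              if (x$tie_broken) " (tie broken)" else ""))
  print(x$neighbours)
  invisible(x)
}

#' @export
tidy.retrieval_result <- function(x, ...) {
  dplyr::mutate(x$neighbours, target_image_id = x$target_image_id,
                .before = 1)
}

#' @export
glance.retrieval_result <- function(x, ...) {
  tibble::tibble(target_image_id = x$target_image_id,
                 k = nrow(x$neighbours),
                 predicted_entity = x$predicted_entity,
                 tie_broken = x$tie_broken)
}

#' Link retrieved neighbours back to their patient records
#'
#' Resolves the neighbours' patient identifiers against a cohort table —
#' the bridge to prior diagnoses, reports and treatments of similar
#' past cases. Records are returned in neighbour rank order, first
#' occurrence kept when several neighbours share a patient.
#'
#' @param result A [recommend()] result.
#' @param cohort A cohort tibble containing every neighbour's patient.
#' @return Cohort tibble rows in rank order, de-duplicated.
#' @export
link_to_history <- function(result, cohort) {
  stopifnot(inherits(result, "retrieval_result"))
  validate_cohort(cohort)
  pids <- unique(result$neighbours$patient_id)
  missing_ids <- setdiff(pids, cohort$patient_id)
  if (length(missing_ids) > 0) {
    abort(paste0("Neighbour patient id(s) absent from cohort: ",
                 paste(missing_ids, collapse = ", ")))
  }
  cohort[match(pids, cohort$patient_id), , drop = FALSE]
}

#' Classify a batch of query embeddings
#'
#' Order-preserving [recommend()] over the rows of a feature tibble.
#'
#' @param index An `lsh_index` over training embeddings.
#' @param targets Feature tibble of query embeddings (test set).
#' @param k Odd neighbour count.
#' @param rerank Passed to [lsh_query()].
#' @return A tibble with one row per query: `target_image_id`,
#'   `truth` (the query's own label column, `NA` if absent),
#'   `predicted_entity`, `tie_broken`, and list-columns `vote_breakdown`
#'   and `neighbours`.
#' @export
batch_classify <- function(index, targets, k = 3L, rerank = TRUE) {
  m <- embedding_matrix(targets)
  res <- purrr::map(seq_len(nrow(m)), function(i)
    recommend(index, m[i, ], k = k,
              target_image_id = targets$image_id[i], rerank = rerank))
  tibble::tibble(
    target_image_id = targets$image_id,
    truth = if ("label" %in% names(targets)) targets$label else NA_character_,
    predicted_entity = purrr::map_chr(res, "predicted_entity"),
    tie_broken = purrr::map_lgl(res, "tie_broken"),
    vote_breakdown = purrr::map(res, "vote_breakdown"),
    neighbours = purrr::map(res, "neighbours")
  )
}
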