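random_features <- function(n, d, seed, labels = NA_character_) {
  m <- withr::with_seed(seed, matrix(rnorm(n * d), n, d))
  features_from_matrix(m, labels = labels)
}

test_that("signatures are scale-invariant, sign-complementary and seeded", {
  v <- withr::with_seed(1, rnorm(12))
  feats <- features_from_matrix(rbind(v, 2 * v, -v))
  idx <- build_lsh_index(feats, bits = 64, seed = 5)
  s <- idx$signatures[[1]]
  expect_identical(s[1, ], s[2, ])              # v and 2v collide
  expect_equal(hamming_distance(s[1, ], s[3, ]), 64)  # v and -v are complements

  idx2 <- build_lsh_index(feats, bits = 64, seed = 5)
  expect_identical(idx$signatures, idx2$signatures)
  idx3 <- build_lsh_index(feats, bits = 64, seed = 6)
  expect_false(identical(idx$signatures, idx3$signatures))

  expect_error(build_lsh_index(feats[0, ], bits = 64, seed = 1), "empty")
  expect_error(build_lsh_index(feats, bits = 0, seed = 1), ">= 1")
})

test_that("hamming distance matches a bit-loop oracle and the metric axioms", {
  expect_equal(hamming_distance("0000", "0000"), 0)
  expect_equal(hamming_distance("1010", "0101"), 4)
  expect_error(hamming_distance("101", "10"), "lengths differ")

  bit_loop <- function(a, b) {
    d <- 0L
    for (i in seq_along(a)) if (a[i] != b[i]) d <- d + 1L
    d
  }
  withr::with_seed(77, {
    for (rep in 1:200) {
      a <- sample(0:1, 16, replace = TRUE)
      b <- sample(0:1, 16, replace = TRUE)
      c <- sample(0:1, 16, replace = TRUE)
      expect_identical(hamming_distance(a, b), bit_loop(a, b))
      # identity, symmetry, triangle inequality
      expect_identical(hamming_distance(a, a), 0L)
      expect_identical(hamming_distance(a, b), hamming_distance(b, a))
      expect_lte(hamming_distance(a, c),
                 hamming_distance(a, b) + hamming_distance(b, c))
    }
  })
})

test_that("query ranking equals an exhaustive hamming scan", {
  feats <- random_features(5, 10, seed = 2)
  idx <- build_lsh_index(feats, bits = 8, seed = 3)
  target <- withr::with_seed(9, rnorm(10))
  got <- lsh_query(idx, target, k = 5, rerank = FALSE)
  # independent oracle: recompute signatures by sign projection and scan
  qs <- as.integer(idx$hyperplanes[[1]] %*% target >= 0)
  d <- apply(idx$signatures[[1]], 1, function(s) sum(s != qs))
  expect_equal(got$image_id, feats$image_id[order(d, seq_along(d))])
  expect_equal(sort(got$image_id), sort(feats$image_id))  # k = N permutation

  # an indexed vector retrieves itself at distance zero
  self <- lsh_query(idx, as.numeric(embedding_matrix(feats)[3, ]), k = 1)
  expect_equal(self$image_id, feats$image_id[3])
  expect_equal(self$distance, 0L)

  expect_error(lsh_query(idx, target, k = 9), "N = 5")
})

test_that("multi-table distances are per-item minima across tables", {
  feats <- random_features(20, 8, seed = 4)
  idx <- build_lsh_index(feats, bits = 16, tables = 3, seed = 7)
  target <- withr::with_seed(12, rnorm(8))
  got <- lsh_query(idx, target, k = 20, rerank = FALSE)
  per_table <- sapply(1:3, function(t) {
    qs <- as.integer(idx$hyperplanes[[t]] %*% target >= 0)
    apply(idx$signatures[[t]], 1, function(s) sum(s != qs))
  })
  expected <- apply(per_table, 1, min)
  expect_equal(got$distance[order(match(got$image_id, feats$image_id))],
               expected)
})

test_that("brute-force k-NN matches hand and O(N^2) oracles", {
  line <- features_from_matrix(matrix(c(0, 3, 10), ncol = 1))
  got <- brute_force_knn(line, 2, k = 3, metric = "euclidean")
  expect_equal(got$image_id, line$image_id[c(2, 1, 3)])
  expect_equal(got$distance, c(1, 2, 8))

  feats <- random_features(20, 6, seed = 5)
  m <- embedding_matrix(feats)
  target <- withr::with_seed(8, rnorm(6))
  for (metric in c("angular", "euclidean")) {
    got <- brute_force_knn(feats, target, k = 20, metric = metric)
    d <- apply(m, 1, function(r) {
      if (metric == "euclidean") sqrt(sum((r - target)^2))
      else acos(max(-1, min(1, sum(r * target) /
                              sqrt(sum(r^2) * sum(target^2)))))
    })
    expect_equal(got$image_id, rownames(m)[order(d, seq_along(d))])
  }
  # angular metric ignores positive rescaling of the query
  expect_equal(brute_force_knn(feats, 3 * target, k = 5, metric = "angular"),
               brute_force_knn(feats, target, k = 5, metric = "angular"))
})

test_that("normalised hamming distance estimates angle/pi", {
  d <- 16; n_pairs <- 300; bits <- 256
  m <- withr::with_seed(14, matrix(rnorm(2 * n_pairs * d), ncol = d))
  m <- m / sqrt(rowSums(m^2))
  idx <- build_lsh_index(features_from_matrix(m), bits = bits, seed = 15)
  s <- idx$signatures[[1]]
  errs <- vapply(seq_len(n_pairs), function(i) {
    u <- m[2 * i - 1, ]; v <- m[2 * i, ]
    theta <- acos(max(-1, min(1, sum(u * v))))
    sum(s[2 * i - 1, ] != s[2 * i, ]) / bits - theta / pi
  }, numeric(1))
  expect_lte(abs(mean(errs)), 3 * sd(errs) / sqrt(n_pairs))
})

test_that("rank agreement with the angular oracle improves with more bits", {
  feats <- random_features(80, 10, seed = 16)
  m <- embedding_matrix(feats)
  queries <- withr::with_seed(17, matrix(rnorm(15 * 10), 15, 10))
  mean_rank_cor <- function(bits) {
    idx <- build_lsh_index(feats, bits = bits, seed = 18)
    mean(vapply(seq_len(nrow(queries)), function(i) {
      got <- lsh_query(idx, queries[i, ], k = 80, rerank = FALSE)
      oracle <- brute_force_knn(feats, queries[i, ], k = 80)
      cor(match(feats$image_id, got$image_id),
          match(feats$image_id, oracle$image_id), method = "spearman")
    }, numeric(1)))
  }
  cors <- vapply(c(8, 32, 128, 512), mean_rank_cor, numeric(1))
  expect_true(all(diff(cors) > 0))
  expect_gt(cors[4], 0.95)
})

test_that("index persistence round-trips and signatures stay recomputable", {
  feats <- random_features(12, 7, seed = 19, labels = "NOF")
  idx <- build_lsh_index(feats, bits = 20, tables = 2, seed = 20)
  path <- withr::local_tempfile(fileext = ".json")
  write_lsh_index(idx, path)
  back <- read_lsh_index(path)
  expect_identical(back$signatures, idx$signatures)
  expect_equal(back$vectors, idx$vectors)
  expect_equal(back$hyperplanes, idx$hyperplanes)
  # signatures recomputable from stored hyperplanes + vectors
  recomputed <- (back$vectors %*% t(back$hyperplanes[[2]]) >= 0) * 1L
  dimnames(recomputed) <- NULL
  expect_equal(recomputed, back$signatures[[2]])
  # identical rankings after the round trip
  target <- withr::with_seed(21, rnorm(7))
  expect_equal(lsh_query(back, target, k = 5), lsh_query(idx, target, k = 5))
})
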