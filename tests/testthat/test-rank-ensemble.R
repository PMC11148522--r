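test_that("mean aggregation averages per slot over covering tensors", {
  a <- matrix(c(0, 2), 1); b <- matrix(c(2, 0), 1)
  expect_equal(aggregate_mean(list(a, b)), matrix(c(1, 1), 1))
  # k identical tensors reproduce any one of them
  expect_equal(aggregate_mean(list(a, a, a)), a)
  # union mask: a slot one tensor misses still aggregates from the others
  c1 <- matrix(c(1, NA), 1); c2 <- matrix(c(3, 4), 1)
  expect_equal(aggregate_mean(list(c1, c2)), matrix(c(2, 4), 1))
  expect_error(aggregate_mean(list(a, matrix(0, 2, 2))), "axis mismatch")
  expect_error(aggregate_mean(list()), "no tensors")
})

test_that("mean aggregation matches the elementwise oracle and stays in hull", {
  set.seed(21)
  for (rep in 1:50) {
    k <- sample(2:5, 1)
    cubes <- lapply(seq_len(k), function(i) {
      m <- matrix(rnorm(24), 4, 6)
      m[matrix(runif(24) < 0.3, 4, 6)] <- NA
      m
    })
    got <- aggregate_mean(cubes)
    for (i in 1:4) for (j in 1:6) {
      vals <- vapply(cubes, function(m) m[i, j], 0)
      vals <- vals[!is.na(vals)]
      if (!length(vals)) {
        expect_true(is.na(got[i, j]))
      } else {
        expect_equal(got[i, j], mean(vals))
        expect_gte(got[i, j], min(vals)); expect_lte(got[i, j], max(vals))
      }
    }
  }
})

test_that("change encoding maps zero and negatives to 0, positives to 1", {
  expect_identical(encode_change(-2.0), 0L)
  expect_identical(encode_change(0.0), 0L)
  expect_identical(encode_change(3.5), 1L)
  expect_identical(encode_change(c(-1, 0, 0.001, NA)), c(0L, 0L, 1L, NA))
  # idempotent on already-encoded values
  m <- matrix(c(0L, 1L, NA, 1L), 2)
  expect_identical(encode_change(m), m)
  expect_error(encode_change(Inf), "non-finite")
  expect_error(encode_change(NaN), "non-finite")
})

test_that("hamming distance counts masked disagreements exactly", {
  expect_equal(hamming_distance(matrix(c(0, 1, 1), 1), matrix(c(0, 1, 1), 1)), 0)
  expect_equal(hamming_distance(matrix(c(0, 0, 0), 1), matrix(c(1, 1, 1), 1)), 3)
  e <- matrix(c(1, NA, 0), 1); t <- matrix(c(0, 1, 0), 1)
  expect_equal(hamming_distance(e, t), 1)   # NA slot excluded
  expect_error(hamming_distance(matrix(0, 1, 2), matrix(0, 2, 1)),
               "shape mismatch")
})

test_that("hamming distance matches slot-by-slot counting on 1000 random instances", {
  set.seed(13)
  for (rep in 1:1000) {
    pair <- random_masked_pair(5, 8)
    oracle <- 0L
    for (i in 1:5) for (j in 1:8) {
      if (!is.na(pair$enc[i, j]) && pair$enc[i, j] != pair$truth[i, j])
        oracle <- oracle + 1L
    }
    d <- hamming_distance(pair$enc, pair$truth)
    expect_identical(d, oracle)
    expect_gte(d, 0); expect_lte(d, sum(!is.na(pair$enc)))
  }
})

test_that("candidates rank ascending by distance with the stated tie-breaks", {
  recs <- data.frame(
    strategy = c("LOPO", "ATU", "LTXO", "LOTPO"),
    scope = c("location", "all6", "calls+location", "all6"),
    cardinality = c(1L, 6L, 2L, 6L),
    distance = c(350, 226, 378, 267))
  ranked <- rank_candidates(recs)
  expect_equal(ranked$strategy, c("ATU", "LOTPO", "LOPO", "LTXO"))
  expect_equal(ranked$distance, c(226, 267, 350, 378))
  expect_true(all(ranked$chosen))   # one candidate per strategy here

  ties <- data.frame(strategy = "S", scope = c("a+b", "a"),
                     cardinality = c(2L, 1L), distance = c(5, 5))
  expect_equal(rank_candidates(ties)$scope, c("a", "a+b"))
  expect_error(rank_candidates(transform(ties, distance = -1)), "negative")
})

test_that("ranking matches an independent sort oracle", {
  set.seed(3)
  for (rep in 1:30) {
    n <- sample(3:12, 1)
    recs <- data.frame(
      strategy = sample(c("A", "B"), n, replace = TRUE),
      scope = replicate(n, paste(sample(letters[1:5], sample(1:3, 1)),
                                 collapse = "+")),
      cardinality = sample(1:3, n, replace = TRUE),
      distance = sample(0:20, n, replace = TRUE))
    recs <- recs[!duplicated(recs[c("strategy", "scope")]), ]
    ranked <- rank_candidates(recs)
    oracle <- recs[order(recs$distance, recs$cardinality, recs$scope), ]
    expect_equal(ranked$scope, oracle$scope)
    for (s in unique(recs$strategy)) {
      ch <- ranked[ranked$chosen & ranked$strategy == s, ]
      expect_equal(ch$distance, min(recs$distance[recs$strategy == s]))
    }
  }
})

test_that("weights invert distances, sum to one, and respect limits", {
  w <- compute_weights(c(A = 3, B = 3, C = 3, D = 3))
  expect_equal(unname(w), rep(0.25, 4))
  # zero distance dominates in the limit
  w0 <- compute_weights(c(A = 0, B = 10, C = 20))
  expect_gt(w0[["A"]], 1 - 1e-6)
  # hand oracle for the inverse normalization
  d <- c(ATU = 226, LOTPO = 267, LOPO = 350, LTXO = 378)
  inv <- 1 / d
  expect_equal(compute_weights(d), inv / sum(inv), tolerance = 1e-6)
  expect_equal(sum(compute_weights(d)), 1, tolerance = 1e-12)
  expect_error(compute_weights(c(A = -1)), "nonnegative")
})

test_that("weights are permutation-equivariant and monotone in distance", {
  set.seed(10)
  for (rep in 1:20) {
    d <- stats::setNames(sample(0:400, 4), c("a", "b", "c", "d"))
    w <- compute_weights(d)
    perm <- sample(4)
    expect_equal(unname(compute_weights(d[perm])), unname(w[perm]))
    o <- order(d)
    expect_true(all(diff(w[o]) <= 1e-15))   # larger distance, smaller weight
    ws <- compute_weights(d, weighting = "softmax")
    expect_equal(sum(ws), 1)
    expect_true(all(diff(ws[o]) <= 1e-15))
  }
})

test_that("weighted ensemble fuses with per-slot renormalization and tie rule", {
  e1 <- matrix(c(1, 0), 1); e2 <- matrix(c(0, 0), 1)
  w <- c(s1 = 1, s2 = 0)
  ens <- weighted_ensemble(list(s1 = e1, s2 = e2), w)
  expect_equal(ens$final, matrix(c(1L, 0L), 1))
  # equal weights, votes (1,1,0,0): P = 0.5 -> 1 under half_up
  votes <- lapply(c(1, 1, 0, 0), function(v) matrix(v, 1, 1))
  names(votes) <- paste0("s", 1:4)
  w4 <- stats::setNames(rep(0.25, 4), names(votes))
  expect_equal(weighted_ensemble(votes, w4)$final[1, 1], 1L)
  expect_equal(weighted_ensemble(votes, w4, tie_rule = "half_down")$final[1, 1], 0L)
  # slot covered by one strategy only: weights renormalize over coverers
  c1 <- matrix(c(1, NA), 1); c2 <- matrix(c(0, 1), 1)
  ens2 <- weighted_ensemble(list(s1 = c1, s2 = c2),
                            c(s1 = 0.5, s2 = 0.5))
  expect_equal(ens2$final, matrix(c(1L, 1L), 1))  # 0.5 ties up; lone vote wins
  expect_error(weighted_ensemble(list(s1 = e1), c(s1 = 0.7)), "sum to 1")
})

test_that("weighted ensemble matches the elementwise weighted-sum oracle", {
  set.seed(17)
  for (rep in 1:200) {
    k <- sample(2:4, 1)
    mats <- lapply(seq_len(k), function(i) {
      m <- matrix(sample(0:1, 12, replace = TRUE), 3, 4)
      m[matrix(runif(12) < 0.25, 3, 4)] <- NA
      m
    })
    names(mats) <- paste0("s", seq_len(k))
    w <- runif(k); w <- stats::setNames(w / sum(w), names(mats))
    ens <- weighted_ensemble(mats, w)
    for (i in 1:3) for (j in 1:4) {
      present <- vapply(mats, function(m) !is.na(m[i, j]), TRUE)
      if (!any(present)) {
        expect_true(is.na(ens$final[i, j]))
      } else {
        ww <- w[present] / sum(w[present])
        p <- sum(ww * vapply(mats[present], function(m) m[i, j], 0))
        expect_equal(ens$fused[i, j], p)
        expect_identical(ens$final[i, j], as.integer(p >= 0.5))
      }
    }
  }
})

test_that("ensembling identical tensors returns that tensor for any weights", {
  set.seed(30)
  m <- matrix(sample(0:1, 20, replace = TRUE), 4, 5)
  m[2, 3] <- NA
  for (rep in 1:10) {
    w <- runif(3); w <- stats::setNames(w / sum(w), c("a", "b", "c"))
    ens <- weighted_ensemble(list(a = m, b = m, c = m), w)
    expect_identical(ens$final, m)
  }
})

test_that("a zero-distance strategy makes the ensemble match truth on its slots", {
  set.seed(55)
  for (rep in 1:30) {
    truth <- matrix(sample(0:1, 30, replace = TRUE), 5, 6)
    perfect <- truth
    others <- lapply(1:3, function(i) {
      m <- matrix(sample(0:1, 30, replace = TRUE), 5, 6)
      m[matrix(runif(30) < 0.2, 5, 6)] <- NA
      m
    })
    mats <- c(list(P = perfect), stats::setNames(others, c("q", "r", "s")))
    d <- vapply(mats, hamming_distance, 0, truth = truth)
    expect_equal(unname(d["P"]), 0)
    w <- compute_weights(d)
    ens <- weighted_ensemble(mats, w)
    covered <- !is.na(perfect)
    expect_equal(ens$final[covered], truth[covered])
  }
})
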