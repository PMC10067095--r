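test_that("imputation follows the half-minimum rule", {
  m <- am(matrix(c(4, 8, NA), nrow = 1))
  expect_identical(as.numeric(impute_missing(m, "half_min")), c(4, 8, 2))
  expect_identical(as.numeric(impute_missing(m, "min")), c(4, 8, 4))
  # no missing values: identity for every method
  full <- am(matrix(2^rnorm(40, 8), nrow = 4))
  for (meth in c("half_min", "min", "knn"))
    expect_identical(unclass(impute_missing(full, meth))[, ],
                     unclass(full)[, ])
  # all-missing feature is a hard error naming the feature
  bad <- am(rbind(c(1, 2), c(NA, NA)))
  expect_error(impute_missing(bad, "half_min"), "f02")
})

test_that("knn imputation borrows from correlated neighbours", {
  set.seed(5)
  base <- 2^rnorm(30, 8, 1)
  # seven features tracking the same profile, one with a hole
  vals <- t(sapply(1:8, function(i) base * exp(rnorm(30, 0, 0.05))))
  vals[8, ] <- 2^rnorm(30, 3, 0.3)   # unrelated low feature
  vals[1, 4] <- NA
  m <- am(vals)
  out <- impute_missing(m, "knn")
  # imputed value close to the shared profile, unlike half-min
  expect_lt(abs(log2(out[1, 4]) - log2(base[4])), 1)
  expect_false(anyNA(out))
  # present cells untouched
  expect_identical(out[2, ], m[2, ])
})

test_that("PAC and CDF follow their defining formulas", {
  cm <- cm_from_entries(c(0.05, 0.0, 0.5, 0.5, 0.95, 1.0))
  f <- consensus_cdf(cm)
  expect_equal(f(0.9), 4 / 6)
  expect_equal(f(0.1), 2 / 6)
  expect_equal(pac(cm, 0.1, 0.9), 1 / 3)
  # perfect consensus: only 0/1 entries
  expect_equal(pac(cm_from_entries(c(0, 1, 0, 1, 1, 0)), 0.1, 0.9), 0)
  # maximal ambiguity: everything at 1/2
  expect_equal(pac(cm_from_entries(rep(0.5, 6)), 0.1, 0.9), 1)
  # single pair: one-step CDF
  f1 <- consensus_cdf(cm_from_entries(0.7))
  expect_equal(f1(0.69), 0)
  expect_equal(f1(0.7), 1)
  expect_error(pac(cm, 0.9, 0.1), "bounds")
})

test_that("PAC is invariant to sample permutation", {
  set.seed(13)
  n <- 12
  M <- matrix(runif(n * n), n)
  M <- (M + t(M)) / 2; diag(M) <- 1
  ids <- sprintf("s%d", 1:n); dimnames(M) <- list(ids, ids)
  cm <- structure(list(sample_ids = ids, M = M, co_count = M,
                       joint_sample_count = matrix(1, n, n)),
                  class = "consensus_matrix")
  perm <- sample(n)
  cm2 <- cm
  cm2$M <- M[perm, perm]
  expect_equal(pac(cm2), pac(cm))
})

test_that("consensus matrices are well-formed and honour duplicates", {
  m <- planted_blobs(g1 = 6, g2 = 6, seed = 2)
  # duplicate one sample exactly
  vals <- cbind(unclass(m), dup = unclass(m)[, 1])
  colnames(vals) <- c(colnames(m), "dup")
  md <- am(vals)
  run <- consensus_cluster(md, k_range = 2:3, n_resamples = 80,
                           inner = "ward", seed = 6)
  for (k in c("2", "3")) {
    cm <- run$consensus[[k]]
    expect_true(isSymmetric(unname(cm$M)))
    expect_true(all(diag(cm$M) == 1))
    expect_true(all(cm$M >= 0 & cm$M <= 1))
    expect_true(all(cm$co_count <= cm$joint_sample_count))
    # identical columns co-cluster whenever co-drawn (deterministic inner)
    i <- which(cm$sample_ids == colnames(m)[1])
    j <- which(cm$sample_ids == "dup")
    expect_equal(cm$M[i, j], 1)
  }
})

test_that("two well-separated blobs give near-binary consensus", {
  m <- planted_blobs(g1 = 10, g2 = 10, shift = 5, seed = 3)
  run <- consensus_cluster(m, k_range = 2, n_resamples = 150, seed = 3)
  M <- run$consensus[["2"]]$M
  within <- c(M[1:10, 1:10][upper.tri(M[1:10, 1:10])],
              M[11:20, 11:20][upper.tri(M[11:20, 11:20])])
  between <- M[1:10, 11:20]
  expect_true(all(within >= 0.95))
  expect_true(all(between <= 0.05))
  expect_lte(run$pac[["2"]], 0.05)
})

test_that("k selection minimizes PAC with ties toward small k", {
  fake <- function(pacs) structure(
    list(k_range = as.integer(names(pacs)), pac = pacs),
    class = "consensus_run")
  expect_identical(select_k(fake(c(`2` = 0.05, `3` = 0.2, `4` = 0.3))), 2L)
  expect_identical(select_k(fake(c(`2` = 0.1, `3` = 0.1))), 2L)
  expect_identical(select_k(fake(c(`2` = 0.3, `3` = 0.2, `4` = 0.1))), 4L)
})

test_that("final labels reproduce perfect blocks and order by size", {
  # 2 samples in one block, 4 in the other -> big block is subtype 1
  M <- matrix(0, 6, 6); M[1:2, 1:2] <- 1; M[3:6, 3:6] <- 1
  ids <- sprintf("s%d", 1:6); dimnames(M) <- list(ids, ids)
  cm <- structure(list(sample_ids = ids, M = M, co_count = M,
                       joint_sample_count = matrix(1, 6, 6)),
                  class = "consensus_matrix")
  lab <- final_labels(cm, 2)
  expect_identical(unname(lab), c(2L, 2L, 1L, 1L, 1L, 1L))
  # k = n - 1 on distinct samples merges exactly one pair
  set.seed(8)
  M2 <- matrix(runif(36, 0, 0.5), 6); M2 <- (M2 + t(M2)) / 2
  diag(M2) <- 1; dimnames(M2) <- list(ids, ids)
  cm2 <- cm; cm2$M <- M2
  lab2 <- final_labels(cm2, 5)
  expect_identical(sort(as.integer(table(lab2))), c(1L, 1L, 1L, 1L, 2L))
  expect_error(final_labels(cm, 6), "k must be")
})

test_that("pair never co-drawn raises an actionable error", {
  m <- planted_blobs(g1 = 4, g2 = 4, seed = 1)
  expect_error(
    consensus_cluster(m, k_range = 2, subsamples = list(1:6, 1:6)),
    "n_resamples")
})
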