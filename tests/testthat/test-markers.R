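test_that("target-set combination follows the two-intersection rule", {
  expect_setequal(select_targets(ls = c("a", "b", "c"), ep = c("b", "d"),
                                 pb = c("c", "e"), manual = "f"),
                  c("b", "c", "f"))
  expect_setequal(select_targets(character(), character(), character(),
                                 manual = c("x", "y")), c("x", "y"))
  s <- c("p1", "p2")
  expect_setequal(select_targets(s, s, s, manual = "m"), c(s, "m"))
})

test_that("MWW test matches exhaustive enumeration for small groups", {
  r <- mww_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)          # 2/20 assignments as extreme
  expect_equal(r$u, 0)
  # identical multisets: symmetric, p = 1
  expect_equal(mww_test(c(2, 4, 4, 7), c(2, 4, 4, 7))$p, 1)
  # empty group after NA removal -> not computable, no exception
  r2 <- mww_test(c(1, 2), c(NA_real_, NA_real_))
  expect_false(r2$computable)
  expect_true(is.na(r2$p))
  # property: exact path equals the independent oracle, ties included
  set.seed(11)
  for (i in 1:25) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(1:5, nx, replace = TRUE)
    y <- sample(1:5, ny, replace = TRUE)
    expect_equal(mww_test(x, y)$p, mww_oracle(x, y),
                 info = paste(c(x, "|", y), collapse = " "))
  }
})

test_that("large-sample MWW path agrees with the reference test", {
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(20, 0.5)
    ours <- mww_test(x, y)
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$u, unname(ref$statistic))
  }
})

test_that("group screen evaluates the three comparisons per feature", {
  set.seed(21)
  groups <- rep(c("HC1", "HC2", "StageI", "StageIV"), each = 12)
  n <- length(groups)
  vals <- matrix(2^rnorm(3 * n, 8, 0.4), nrow = 3)
  # f1: elevated in StageIV only (drives B and C)
  vals[1, groups == "StageIV"] <- vals[1, groups == "StageIV"] * 8
  # f3: missing in every StageI sample
  vals[3, groups == "StageI"] <- NA
  m <- am(vals)
  ann <- screen_annotation(groups, colnames(m))
  res <- mww_screen(m, ann, alpha = 0.05)
  expect_true(grepl("B", res$provenance[1]))
  expect_true(grepl("C", res$provenance[1]))
  expect_true(is.na(res$p_A[3]) && is.na(res$p_C[3]))
  expect_false(is.na(res$p_B[3]))
  expect_identical(res$selected, nzchar(res$provenance))
  # a required group absent entirely -> hard error
  expect_error(mww_screen(m, screen_annotation(
    sub("HC1", "HC2", groups), colnames(m))), "HC1")
})

test_that("selection is monotone in alpha", {
  set.seed(31)
  groups <- rep(c("HC1", "HC2", "StageI", "StageIV"), each = 8)
  m <- am(matrix(2^rnorm(20 * 32, 8, 0.5), nrow = 20))
  ann <- screen_annotation(groups, colnames(m))
  sel_at <- function(a) mww_screen(m, ann, alpha = a)$selected
  s1 <- sel_at(0.01); s2 <- sel_at(0.05); s3 <- sel_at(0.2)
  expect_true(all(s2[s1]))   # everything kept at 0.01 survives 0.05
  expect_true(all(s3[s2]))
})

test_that("unsupervised forest ranks a correlated separating block on top", {
  # the synthetic-contrast forest detects joint structure: a block of
  # co-elevated features separating two sample groups gains importance
  block <- sprintf("f%02d", 1:6)
  top1_hits <- 0L
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    vals <- matrix(2^rnorm(30 * n, 8, 0.5), nrow = 30)
    vals[1:6, 1:20] <- vals[1:6, 1:20] * 2^4
    rf <- unsupervised_rf(am(vals), n_trees = 400, seed = seed)
    top6 <- names(sort(rf$importance, decreasing = TRUE))[1:6]
    expect_gte(sum(top6 %in% block), 3)
    if (top6[1] %in% block) top1_hits <- top1_hits + 1L
  }
  expect_gte(top1_hits, 4L)
})

test_that("iid noise yields no standout forest importance", {
  flat <- vapply(1:5, function(seed) {
    set.seed(seed)
    m <- am(matrix(2^rnorm(30 * 20, 8, 0.5), nrow = 30))
    imp <- unsupervised_rf(m, n_trees = 300, seed = seed)$importance
    max(imp) <= 3 * median(imp)
  }, logical(1))
  expect_gte(mean(flat), 0.9)
})

test_that("forest proximity is a valid similarity matrix", {
  m <- planted_blobs(g1 = 8, g2 = 8, seed = 4)
  rf <- unsupervised_rf(m, n_trees = 200, seed = 4)
  pr <- rf$proximity
  expect_true(isSymmetric(unname(pr)))
  expect_true(all(diag(pr) == 1))
  expect_true(all(pr >= 0 & pr <= 1))
  expect_identical(length(rf$importance), nrow(m))
  expect_error(unsupervised_rf(m[, 1:3]), "4 samples")
})

test_that("MDS embedding behaves on degenerate geometries", {
  # two perfect blocks collapse to two points
  pr <- matrix(0, 6, 6); pr[1:3, 1:3] <- 1; pr[4:6, 4:6] <- 1
  dimnames(pr) <- list(letters[1:6], letters[1:6])
  xy <- mds_embed(pr)
  expect_lt(max(dist(xy[1:3, ])), 1e-6)
  expect_lt(max(dist(xy[4:6, ])), 1e-6)
  expect_gt(as.numeric(dist(rbind(xy[1, ], xy[4, ]))), 0.5)
  # identity proximity: equilateral -> all pairwise distances equal
  d3 <- dist(mds_embed(diag(3)))
  expect_equal(max(d3), min(d3), tolerance = 1e-8)
  expect_error(mds_embed(matrix(runif(9), 3)), "symmetric")
})

test_that("MDS + 2-means recovers planted subtypes", {
  m <- planted_blobs(g1 = 12, g2 = 12, shift = 4, seed = 7)
  rf <- unsupervised_rf(m, n_trees = 400, seed = 7)
  xy <- mds_embed(rf$proximity)
  set.seed(7)
  cl <- kmeans(xy, 2, nstart = 10)$cluster
  truth <- rep(1:2, each = 12)
  expect_gte(adjusted_rand_index(cl, truth), 0.8)
})

test_that("candidate assembly unions screen hits and forest top-n", {
  screen <- data.frame(
    feature_id = paste0("p", 1:5),
    p_A = c(0.01, 0.02, 0.5, 0.9, 0.7), fc_A = 1,
    p_B = 0.5, fc_B = 1, p_C = 0.5, fc_C = 1,
    rank_D = NA_integer_, rank_E = NA_integer_,
    provenance = c("A", "A", "", "", ""),
    selected = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  class(screen) <- c("candidate_selection", "data.frame")
  imp_d <- c(p2 = 10, p3 = 9, p1 = 1, p4 = 0.5, p5 = 0.2)
  imp_e <- c(p4 = 5, p1 = 0.1, p2 = 0.1, p3 = 0.1, p5 = 0.05)
  out <- assemble_candidates(screen, imp_d, imp_e, top_n = 2,
                             feature_to_protein = c(
                               p1 = "X", p2 = "X", p3 = "X",
                               p4 = "Y", p5 = "Z"))
  expect_setequal(out$feature_id[out$selected],
                  c("p1", "p2", "p3", "p4"))
  expect_identical(out$provenance[out$feature_id == "p2"], "AD")
  expect_identical(attr(out, "n_selected_features"), 4L)
  # p1..p3 share protein X -> counted once
  expect_identical(attr(out, "n_selected_proteins"), 2L)
  expect_error(assemble_candidates(screen, imp_d, imp_e, top_n = 0),
               "top_n")
})
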