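# Small in-code fixtures shared across test files.

# abundance matrix from a plain numeric matrix, auto-named
am <- function(vals, level = "protein", map = NULL) {
  if (is.null(rownames(vals)))
    rownames(vals) <- sprintf("f%02d", seq_len(nrow(vals)))
  if (is.null(colnames(vals)))
    colnames(vals) <- sprintf("s%02d", seq_len(ncol(vals)))
  abundance_matrix(vals, level = level, feature_to_protein = map)
}

# consensus_matrix with prescribed upper-triangle entries (n chosen to fit)
cm_from_entries <- function(entries) {
  n <- (1 + sqrt(1 + 8 * length(entries))) / 2
  stopifnot(n == round(n))
  M <- diag(n)
  M[upper.tri(M)] <- entries
  M <- M + t(M) - diag(n)
  ids <- sprintf("s%d", seq_len(n))
  dimnames(M) <- list(ids, ids)
  structure(list(sample_ids = ids, M = M,
                 co_count = M, joint_sample_count = matrix(1, n, n)),
            class = "consensus_matrix")
}

# annotation for a screening-cohort layout
screen_annotation <- function(groups, ids) {
  sample_annotation(data.frame(
    sample_id = ids, cohort = "cohort1", group = groups,
    stringsAsFactors = FALSE))
}

# independent brute-force MWW oracle: enumerate group assignments and
# compute the two-sided p as twice the smaller tail of the U statistic
mww_oracle <- function(x, y) {
  nx <- length(x)
  pool <- c(x, y)
  count_u <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- count_u(x, y)
  us <- apply(combn(length(pool), nx), 2L,
              function(i) count_u(pool[i], pool[-i]))
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# brute-force BH step-up oracle: sort, scale, cummin from the largest,
# restore input order
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# small planted two-group matrix for clustering tests: g1/g2 samples,
# n_sep separating features (shifted in group 1) plus noise features
planted_blobs <- function(g1 = 10, g2 = 10, n_sep = 8, n_noise = 12,
                          shift = 4, seed = 1) {
  set.seed(seed)
  n <- g1 + g2
  vals <- matrix(2^rnorm(n * (n_sep + n_noise), 10, 1),
                 nrow = n_sep + n_noise)
  vals[seq_len(n_sep), seq_len(g1)] <-
    vals[seq_len(n_sep), seq_len(g1)] * 2^shift
  am(vals)
}
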