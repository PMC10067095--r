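#' Impute missing values in an abundance matrix
#'
#' Missingness in targeted proteomics is missing-not-at-random (values
#' below the detection limit are the ones lost), so the default
#' replaces each missing cell with half of the feature's minimum
#' present value. Alternatives: the minimum itself, or a
#' feature-space k-nearest-neighbour average (k = 5) on the log scale.
#' Present values are never altered.
#'
#' @param m an \code{abundance_matrix}.
#' @param method \code{"half_min"}, \code{"min"} or \code{"knn"}.
#' @param k neighbours used by \code{"knn"}.
#' @return a complete \code{abundance_matrix}.
#' @export
impute_missing <- function(m, method = c("half_min", "min", "knn"),
                           k = 5L) {
  method <- match.arg(method)
  n_present <- rowSums(!is.na(m))
  if (any(n_present == 0L))
    stop("feature(s) with no present value: ",
         paste(head(rownames(m)[n_present == 0L], 5L), collapse = ", "))
  if (!anyNA(m)) return(m)
  out <- unclass(m)
  if (method %in% c("half_min", "min")) {
    mins <- apply(out, 1L, min, na.rm = TRUE)
    fill <- if (method == "half_min") mins / 2 else mins
    for (i in which(rowSums(is.na(out)) > 0L))
      out[i, is.na(out[i, ])] <- fill[i]
  } else {
    logm <- log2(out)
    dd <- as.matrix(dist(logm))      # pairwise-complete with rescaling
    half <- apply(out, 1L, min, na.rm = TRUE) / 2
    for (i in which(rowSums(is.na(out)) > 0L)) {
      nb <- order(dd[i, ])
      nb <- nb[nb != i & !is.na(dd[i, nb])]
      for (j in which(is.na(out[i, ]))) {
        donors <- nb[!is.na(logm[nb, j])]
        out[i, j] <- if (length(donors))
          2^mean(logm[head(donors, k), j]) else half[i]
      }
    }
  }
  abundance_matrix(out, level = attr(m, "level"),
                   feature_to_protein = attr(m, "feature_to_protein"))
}

# log2 then per-feature z-score; constant features map to 0
standardize_features <- function(m) {
  x <- log2(unclass(m))
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  s[s == 0] <- 1
  (x - mu) / s
}

inner_clusterer_fn <- function(inner) {
  if (is.function(inner)) return(inner)
  switch(inner,
    kmeans = function(x, k)
      kmeans(x, centers = k, nstart = 10L, iter.max = 50L)$cluster,
    ward = function(x, k)
      cutree(hclust(dist(x), method = "ward.D2"), k = k),
    stop("unknown inner clusterer: ", inner))
}

#' Resampling-based consensus clustering
#'
#' Monti-style consensus clustering: features are standardized (log2,
#' then per-feature z-score), and for each candidate k the samples are
#' repeatedly subsampled without replacement and partitioned by the
#' inner clusterer. The consensus index M(i, j) is the fraction of
#' rounds in which samples i and j were co-clustered, among rounds
#' where both were drawn. The empirical CDF of the consensus indices
#' and the PAC are computed per k.
#'
#' @param m a complete \code{abundance_matrix}.
#' @param k_range integer vector of candidate cluster counts (>= 2).
#' @param n_resamples number of subsampling rounds.
#' @param subsample_fraction fraction of samples per round, in (0, 1).
#' @param inner \code{"kmeans"} (10 restarts), \code{"ward"}, or a
#'   \code{function(x, k)} returning integer labels for the rows of x.
#' @param seed integer seed.
#' @param pac_bounds the (x1, x2) interval of the PAC.
#' @param subsamples optional explicit list of sample-index vectors,
#'   overriding random subsampling (used for exhaustive or scripted
#'   resampling designs; \code{n_resamples} is then ignored).
#' @return a \code{consensus_run}: per-k \code{consensus_matrix}
#'   objects (fields \code{M}, \code{co_count},
#'   \code{joint_sample_count}), per-k CDFs and PAC values, and the
#'   inputs needed to pick k and extract labels.
#' @export
consensus_cluster <- function(m, k_range = 2:8, n_resamples = 1000L,
                              subsample_fraction = 0.8,
                              inner = c("kmeans", "ward"), seed = 1L,
                              pac_bounds = c(0.1, 0.9),
                              subsamples = NULL) {
  if (anyNA(m)) stop("consensus clustering needs a complete matrix")
  if (!is.function(inner)) inner <- match.arg(inner)
  n <- ncol(m)
  k_range <- as.integer(k_range)
  if (min(k_range) < 2L) stop("k_range minimum must be >= 2")
  if (n < max(k_range) + 2L)
    stop("need at least max(k_range) + 2 samples")
  if (is.null(subsamples)) {
    if (subsample_fraction <= 0 || subsample_fraction >= 1)
      stop("subsample_fraction must be strictly between 0 and 1")
    n_sub <- ceiling(subsample_fraction * n)
  }
  x <- t(standardize_features(m))
  fn <- inner_clusterer_fn(inner)
  sid <- colnames(m)

  per_k <- list()
  for (k in k_range) {
    set.seed(stage_seed(seed, "consensus") + k)
    co <- matrix(0, n, n)
    joint <- matrix(0, n, n)
    draws <- subsamples %||%
      lapply(seq_len(n_resamples), function(r) sample.int(n, n_sub))
    for (idx in draws) {
      labs <- fn(x[idx, , drop = FALSE], k)
      joint[idx, idx] <- joint[idx, idx] + 1
      for (cl in unique(labs)) {
        mem <- idx[labs == cl]
        co[mem, mem] <- co[mem, mem] + 1
      }
    }
    off <- upper.tri(joint)
    if (any(joint[off] == 0))
      stop("sample pair(s) never co-drawn at k = ", k,
           "; increase n_resamples")
    M <- matrix(0, n, n)
    M[joint > 0] <- co[joint > 0] / joint[joint > 0]
    diag(M) <- 1
    dimnames(M) <- dimnames(co) <- dimnames(joint) <- list(sid, sid)
    cm <- structure(list(sample_ids = sid, M = M, co_count = co,
                         joint_sample_count = joint),
                    class = "consensus_matrix")
    per_k[[as.character(k)]] <- cm
  }
  cdfs <- lapply(per_k, consensus_cdf)
  pacs <- vapply(per_k, pac, numeric(1),
                 x1 = pac_bounds[1], x2 = pac_bounds[2])
  structure(list(k_range = k_range, consensus = per_k, cdf = cdfs,
                 pac = pacs, pac_bounds = pac_bounds),
            class = "consensus_run")
}

#' Empirical CDF of the consensus indices
#'
#' Right-continuous empirical distribution of the upper-triangle
#' entries of a consensus matrix: CDF(c) is the fraction of sample
#' pairs with consensus index at most c.
#'
#' @param cm a \code{consensus_matrix}.
#' @return a step function on [0, 1] (an \code{ecdf}).
#' @export
consensus_cdf <- function(cm) {
  stats::ecdf(cm$M[upper.tri(cm$M)])
}

#' Proportion of ambiguous clustering
#'
#' PAC = CDF(x2) - CDF(x1): the fraction of sample pairs whose
#' consensus index falls in the intermediate interval (x1, x2] -- the
#' pairs the resampled clusterings cannot settle. A low PAC marks a
#' flat CDF middle segment, i.e. a stable partition.
#'
#' @param cm a \code{consensus_matrix}.
#' @param x1,x2 interval bounds, 0 <= x1 < x2 <= 1.
#' @return PAC in [0, 1].
#' @export
pac <- function(cm, x1 = 0.1, x2 = 0.9) {
  if (!(x1 >= 0 && x1 < x2 && x2 <= 1))
    stop("pac bounds must satisfy 0 <= x1 < x2 <= 1")
  f <- consensus_cdf(cm)
  f(x2) - f(x1)
}

#' Select the number of clusters by minimum PAC
#'
#' @param run a \code{consensus_run}.
#' @return the k minimizing PAC; ties break toward the smallest k.
#' @export
select_k <- function(run) {
  stopifnot(inherits(run, "consensus_run"))
  pacs <- run$pac[as.character(run$k_range)]
  if (anyNA(pacs)) stop("PAC missing for part of k_range")
  run$k_range[which.min(pacs)]    # which.min takes the first minimum
}

#' Extract final subtype labels from a consensus matrix
#'
#' Samples are clustered by average-linkage agglomeration on the
#' dissimilarity 1 - M and the tree is cut into k groups. Labels are
#' renumbered by decreasing group size, so subtype 1 is always the
#' largest.
#'
#' @param cm a \code{consensus_matrix}.
#' @param k number of groups, 2 <= k <= n - 1.
#' @return named integer labels in 1..k.
#' @export
final_labels <- function(cm, k) {
  n <- length(cm$sample_ids)
  if (k < 2L || k > n - 1L) stop("k must be in [2, n - 1]")
  hc <- hclust(as.dist(1 - cm$M), method = "average")
  raw <- cutree(hc, k = k)
  sizes <- table(raw)
  if (length(sizes) < k) stop("empty group after cutting the tree")
  ord <- order(-as.numeric(sizes), as.integer(names(sizes)))
  remap <- integer(k)
  remap[as.integer(names(sizes))[ord]] <- seq_len(k)
  setNames(remap[raw], cm$sample_ids)
}
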