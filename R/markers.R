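#' Combine candidate sources into an SRM target set
#'
#' Proteins present in both the literature set and the public EV
#' database, or in both the literature set and the discovery-proteomics
#' set, are selected; a manual addition list is appended.
#'
#' @param ls literature-search protein ids.
#' @param ep discovery (experimental) proteomics protein ids.
#' @param pb public EV-database protein ids.
#' @param manual manually added protein ids.
#' @return the deduplicated target id set.
#' @export
select_targets <- function(ls, ep, pb, manual = character()) {
  unique(c(intersect(ls, pb), intersect(ls, ep), manual))
}

#' Mann-Whitney-Wilcoxon two-sample test
#'
#' The U statistic counts pairs where an \code{x} value exceeds a
#' \code{y} value (ties count 1/2). For small groups (both n <= 8) the
#' two-sided p-value is exact, from full enumeration of the
#' \eqn{\binom{n_x+n_y}{n_x}}{C(nx+ny, nx)} group assignments (so ties
#' are handled exactly); otherwise the normal approximation with tie
#' correction and continuity correction is used.
#'
#' Missing values are dropped. If either group is empty after removal
#' the result is marked not computable rather than raising an error, so
#' feature-by-feature screening can continue.
#'
#' @param x,y numeric samples.
#' @return a list with \code{u}, \code{p} and \code{computable}.
#' @export
mww_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L)
    return(list(u = NA_real_, p = NA_real_, computable = FALSE))
  u_obs <- mww_u(x, y)
  if (nx <= 8L && ny <= 8L) {
    pool <- c(x, y)
    idx <- combn(nx + ny, nx)
    us <- apply(idx, 2L, function(i) mww_u(pool[i], pool[-i]))
    eps <- 1e-9
    p_lo <- mean(us <= u_obs + eps)
    p_hi <- mean(us >= u_obs - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    n <- nx + ny
    r <- rank(c(x, y))
    ties <- table(r)
    mu <- nx * ny / 2
    sigma2 <- nx * ny / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(u = u_obs, p = 1, computable = TRUE))
    z <- u_obs - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(u = u_obs, p = p, computable = TRUE)
}

# U statistic of x vs y via the rank-sum identity
mww_u <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
}

#' Three-comparison group screen for biomarker candidates
#'
#' Runs the Mann-Whitney-Wilcoxon test per feature on present values
#' for comparisons A (StageI vs HC1), B (StageIV vs HC2) and C (StageI
#' vs StageIV). A comparison letter enters a feature's provenance when
#' its p-value is below \code{alpha} (raw, uncorrected). Fold changes
#' are ratios of geometric means of present values (first-named group
#' over second).
#'
#' @param m an \code{abundance_matrix}.
#' @param ann a \code{\link{sample_annotation}} covering the samples.
#' @param alpha raw significance level.
#' @return a \code{candidate_selection} data.frame with per-feature
#'   p-values, fold changes, provenance string and selection flag.
#' @export
mww_screen <- function(m, ann, alpha = 0.05) {
  ann <- align_annotation(m, ann)
  comps <- list(A = c("StageI", "HC1"),
                B = c("StageIV", "HC2"),
                C = c("StageI", "StageIV"))
  for (g in unique(unlist(comps)))
    if (!any(ann$group == g))
      stop("required group absent from annotation: ", g)
  out <- data.frame(feature_id = rownames(m), stringsAsFactors = FALSE)
  prov <- rep("", nrow(m))
  for (L in names(comps)) {
    g1 <- ann$group == comps[[L]][1]
    g2 <- ann$group == comps[[L]][2]
    res <- lapply(seq_len(nrow(m)),
                  function(i) mww_test(m[i, g1], m[i, g2]))
    p <- vapply(res, function(r) r$p, numeric(1))
    fc <- vapply(seq_len(nrow(m)), function(i)
      geom_mean(m[i, g1]) / geom_mean(m[i, g2]), numeric(1))
    out[[paste0("p_", L)]] <- p
    out[[paste0("fc_", L)]] <- fc
    hit <- !is.na(p) & p < alpha
    prov[hit] <- paste0(prov[hit], L)
  }
  out$rank_D <- NA_integer_
  out$rank_E <- NA_integer_
  out$provenance <- prov
  out$selected <- nzchar(prov)
  class(out) <- c("candidate_selection", "data.frame")
  out
}

#' Unsupervised random forest on a sample set
#'
#' Breiman's unsupervised random forest: a synthetic contrast class is
#' built by sampling each feature independently from its marginal
#' distribution, and a forest is grown to separate real from synthetic
#' samples. Feature importance is the mean decrease in Gini impurity;
#' the proximity of two real samples is the fraction of trees in which
#' they land in the same terminal node.
#'
#' @param m a complete (imputed) \code{abundance_matrix} restricted to
#'   the samples of interest; at least 4 samples.
#' @param n_trees number of trees.
#' @param seed integer seed.
#' @param importance_type \code{"impurity"} (mean decrease in Gini) or
#'   \code{"permutation"} (mean decrease in accuracy).
#' @return a list with \code{importance} (named numeric, one score per
#'   feature) and \code{proximity} (symmetric samples x samples matrix
#'   in [0, 1] with unit diagonal).
#' @export
unsupervised_rf <- function(m, n_trees = 1000L, seed = 1L,
                            importance_type = c("impurity", "permutation")) {
  importance_type <- match.arg(importance_type)
  if (ncol(m) < 4L) stop("unsupervised RF needs >= 4 samples")
  if (anyNA(m)) stop("impute missing values before running the RF")
  x <- as.data.frame(t(unclass(m)))
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(x = x, ntree = as.integer(n_trees),
                                    proximity = TRUE, importance = TRUE)
  imp <- randomForest::importance(
    fit, type = if (importance_type == "impurity") 2L else 1L)
  prox <- fit$proximity
  diag(prox) <- 1
  dimnames(prox) <- list(colnames(m), colnames(m))
  list(importance = setNames(as.numeric(imp), rownames(imp)),
       proximity = prox)
}

#' Classical MDS embedding of a proximity matrix
#'
#' Embeds samples in two dimensions by classical multidimensional
#' scaling of the dissimilarity \code{1 - proximity}.
#'
#' @param proximity symmetric matrix with unit diagonal, entries in
#'   [0, 1].
#' @return an n x 2 coordinate matrix (columns MDS1, MDS2).
#' @export
mds_embed <- function(proximity) {
  if (!isSymmetric(unname(proximity), tol = 1e-8))
    stop("proximity matrix must be symmetric")
  if (any(abs(diag(proximity) - 1) > 1e-8))
    stop("proximity matrix must have unit diagonal")
  d <- as.dist(1 - proximity)
  xy <- cmdscale(d, k = 2)
  if (ncol(xy) < 2L)                       # degenerate geometry
    xy <- cbind(xy, matrix(0, nrow(xy), 2L - ncol(xy)))
  colnames(xy) <- c("MDS1", "MDS2")
  rownames(xy) <- rownames(proximity)
  xy
}

#' Assemble the candidate list from screen and forest rankings
#'
#' The final candidate set is the union of the group-screen hits and
#' the top-n features of each of the two unsupervised forest runs
#' (run D: tumor-stage samples only; run E: all samples). Provenance
#' letters accumulate; counts are reported at feature level and, when
#' a peptide-to-protein mapping is supplied, at protein level.
#'
#' @param screen a \code{candidate_selection} from
#'   \code{\link{mww_screen}}.
#' @param importance_d,importance_e named importance vectors from the
#'   two forest runs.
#' @param top_n how many top features each run contributes (>= 1).
#' @param feature_to_protein optional named map feature id -> protein.
#' @return the updated \code{candidate_selection}, with attributes
#'   \code{n_selected_features} and \code{n_selected_proteins}.
#' @export
assemble_candidates <- function(screen, importance_d, importance_e,
                                top_n = 50L,
                                feature_to_protein = NULL) {
  if (top_n < 1L) stop("top_n must be >= 1")
  add_run <- function(sel, imp, letter, col) {
    if (is.null(imp)) return(sel)
    imp <- imp[names(imp) %in% sel$feature_id]
    rk <- rank(-imp, ties.method = "first")
    top <- names(imp)[rk <= top_n]
    i <- match(names(imp), sel$feature_id)
    sel[[col]][i] <- as.integer(rk)
    hit <- sel$feature_id %in% top
    sel$provenance[hit] <- paste0(sel$provenance[hit], letter)
    sel
  }
  out <- add_run(screen, importance_d, "D", "rank_D")
  out <- add_run(out, importance_e, "E", "rank_E")
  out$selected <- nzchar(out$provenance)
  sel_ids <- out$feature_id[out$selected]
  attr(out, "n_selected_features") <- length(sel_ids)
  prots <- if (is.null(feature_to_protein)) sel_ids
           else unique(unname(feature_to_protein[sel_ids]))
  attr(out, "n_selected_proteins") <- length(unique(prots))
  out
}
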