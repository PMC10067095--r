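#' Volcano screen for subtype-associated proteins
#'
#' Per protein, the fold change is the ratio of geometric means
#' (cluster 1 over cluster 2) and the p-value comes from the
#' Mann-Whitney-Wilcoxon test. A protein is flagged \code{up} when the
#' fold change is strictly greater than the threshold and the p-value
#' strictly below alpha, \code{down} for the reciprocal fold-change
#' bound, otherwise \code{ns}.
#'
#' @param m a complete \code{abundance_matrix}.
#' @param labels binary subtype label per sample (values 1 and 2, or a
#'   two-level factor whose first level is cluster 1).
#' @param fc_threshold fold-change bound (strict), default 2.
#' @param alpha p-value bound (strict), default 0.05.
#' @return a \code{volcano_result} data.frame: \code{protein},
#'   \code{fc}, \code{log2_fc}, \code{p}, \code{flag}.
#' @export
volcano_screen <- function(m, labels, fc_threshold = 2, alpha = 0.05) {
  g <- as.factor(labels)
  if (nlevels(droplevels(g)) != 2L) stop("labels must have two levels")
  if (length(labels) != ncol(m))
    stop("one label per sample required")
  in1 <- g == levels(g)[1L]
  if (sum(in1) < 2L || sum(!in1) < 2L)
    stop("each subtype needs >= 2 samples")
  fc <- vapply(seq_len(nrow(m)), function(i)
    geom_mean(m[i, in1]) / geom_mean(m[i, !in1]), numeric(1))
  p <- vapply(seq_len(nrow(m)), function(i)
    mww_test(m[i, in1], m[i, !in1])$p, numeric(1))
  # compare at 12 significant digits so that a fold change that is
  # exactly at the threshold stays unflagged under rescaling of the
  # input (the geometric-mean ratio is scale-free only up to rounding)
  fcr <- signif(fc, 12)
  flag <- rep("ns", nrow(m))
  flag[!is.na(p) & p < alpha & fcr > fc_threshold] <- "up"
  flag[!is.na(p) & p < alpha & fcr < signif(1 / fc_threshold, 12)] <- "down"
  out <- data.frame(protein = rownames(m), fc = fc, log2_fc = log2(fc),
                    p = p, flag = flag, stringsAsFactors = FALSE)
  class(out) <- c("volcano_result", "data.frame")
  out
}

#' All-pairs protein-protein correlation
#'
#' Computes the correlation of every unordered protein pair across
#' samples: Pearson on log2 abundances (default; log-normal data), or
#' Spearman on ranks. Two-sided p-values come from the t transform of
#' the coefficient. Pairs involving a zero-variance protein are marked
#' not computable (NA).
#'
#' @param m a complete \code{abundance_matrix} with >= 3 samples.
#' @param method \code{"pearson_log2"} or \code{"spearman"}.
#' @return a data.frame with \code{protein_a}, \code{protein_b},
#'   \code{r}, \code{p}; one row per unordered pair.
#' @export
correlation_matrix <- function(m, method = c("pearson_log2", "spearman")) {
  method <- match.arg(method)
  if (ncol(m) < 3L) stop("need >= 3 samples")
  if (anyNA(m)) stop("matrix must be complete (impute first)")
  x <- if (method == "pearson_log2") t(log2(unclass(m)))
       else apply(t(unclass(m)), 2L, rank)
  n <- nrow(x)
  zero_var <- apply(x, 2L, var) == 0
  r <- suppressWarnings(cor(x))
  r[zero_var, ] <- NA
  r[, zero_var] <- NA
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pm <- 2 * pt(-abs(tt), df = n - 2)
  pm[r == 1 | r == -1] <- 0
  ut <- which(upper.tri(r), arr.ind = TRUE)
  data.frame(protein_a = rownames(m)[ut[, 1L]],
             protein_b = rownames(m)[ut[, 2L]],
             r = r[ut], p = pm[ut], stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; output order
#' matches input order. NA entries pass through.
#'
#' @param pvals p-values in [0, 1].
#' @return adjusted q-values.
#' @export
bh_adjust <- function(pvals) {
  ok <- pvals[!is.na(pvals)]
  if (any(ok < 0 | ok > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Extract a correlation network at an FDR threshold
#'
#' Keeps pairs with q below the threshold (and positive r when
#' \code{positive_only}); when a focus set is given, only edges with
#' at least one endpoint in the focus are kept, and focus members
#' without any kept edge are reported as isolated.
#'
#' @param pairs a data.frame with \code{protein_a}, \code{protein_b},
#'   \code{r} and \code{q} (see \code{\link{bh_adjust}}).
#' @param q_threshold FDR threshold (strict), e.g. 1e-4.
#' @param positive_only keep only positive correlations.
#' @param focus optional protein id set to restrict edges to.
#' @return a \code{correlation_network}: \code{edges} (data.frame),
#'   \code{nodes}, \code{isolated_focus}, plus the thresholds used.
#' @export
build_network <- function(pairs, q_threshold = 1e-4,
                          positive_only = TRUE, focus = NULL) {
  stopifnot(all(c("protein_a", "protein_b", "r", "q") %in% colnames(pairs)))
  keep <- !is.na(pairs$q) & pairs$q < q_threshold
  if (positive_only) keep <- keep & pairs$r > 0
  edges <- pairs[keep, , drop = FALSE]
  if (!is.null(focus))
    edges <- edges[edges$protein_a %in% focus |
                   edges$protein_b %in% focus, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- unique(c(edges$protein_a, edges$protein_b))
  isolated <- if (is.null(focus)) character() else setdiff(focus, nodes)
  structure(list(edges = edges, nodes = nodes,
                 isolated_focus = isolated,
                 q_threshold = q_threshold,
                 positive_only = positive_only),
            class = "correlation_network")
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by summing hypergeometric probabilities of
#' tables (with the observed margins) no more probable than the
#' observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  fisher.test(table)$p.value
}
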