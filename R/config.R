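#' Pipeline configuration
#'
#' Bundles every tunable threshold of the two-stage analysis with the
#' study defaults: a signal-intensity quantification limit of 1500, a
#' raw screening level of 0.05, top-50 random-forest candidates,
#' half-minimum imputation, consensus clustering over k = 2..8 with
#' PAC bounds (0.1, 0.9), a volcano screen at fold change > 2 and
#' p < 0.05, and a correlation-network FDR threshold of 1e-4.
#'
#' @param quantification_limit intensity below which a signal is not
#'   quantifiable and is censored to missing.
#' @param screen_alpha significance level of the group-comparison
#'   screen (raw, uncorrected).
#' @param rf_top_n number of top-importance features each random-forest
#'   run contributes to the candidate list.
#' @param imputation_method \code{"half_min"}, \code{"min"} or
#'   \code{"knn"}.
#' @param k_range integer vector of candidate cluster numbers.
#' @param n_resamples consensus-clustering resampling rounds.
#' @param subsample_fraction fraction of samples drawn per round,
#'   in (0, 1).
#' @param pac_bounds numeric length-2, the (x1, x2) consensus-index
#'   interval whose CDF mass defines the PAC.
#' @param volcano_fc_threshold fold-change threshold (strict) of the
#'   subtype-marker volcano screen.
#' @param volcano_alpha p-value threshold (strict) of the volcano
#'   screen.
#' @param network_fdr_threshold BH-adjusted q-value threshold of the
#'   correlation network.
#' @param inner_clusterer consensus inner clusterer, \code{"kmeans"}
#'   or \code{"ward"}.
#' @param correlation_method \code{"pearson_log2"} or
#'   \code{"spearman"}.
#' @param seed master integer seed; every randomized stage derives its
#'   own stream from it.
#' @return a validated list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(quantification_limit = 1500,
                            screen_alpha = 0.05,
                            rf_top_n = 50L,
                            imputation_method = c("half_min", "min", "knn"),
                            k_range = 2:8,
                            n_resamples = 1000L,
                            subsample_fraction = 0.8,
                            pac_bounds = c(0.1, 0.9),
                            volcano_fc_threshold = 2,
                            volcano_alpha = 0.05,
                            network_fdr_threshold = 1e-4,
                            inner_clusterer = c("kmeans", "ward"),
                            correlation_method = c("pearson_log2", "spearman"),
                            seed = 1L) {
  cfg <- list(quantification_limit = quantification_limit,
              screen_alpha = screen_alpha,
              rf_top_n = as.integer(rf_top_n),
              imputation_method = match.arg(imputation_method),
              k_range = as.integer(k_range),
              n_resamples = as.integer(n_resamples),
              subsample_fraction = subsample_fraction,
              pac_bounds = as.numeric(pac_bounds),
              volcano_fc_threshold = volcano_fc_threshold,
              volcano_alpha = volcano_alpha,
              network_fdr_threshold = network_fdr_threshold,
              inner_clusterer = match.arg(inner_clusterer),
              correlation_method = match.arg(correlation_method),
              seed = as.integer(seed))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  req <- c("quantification_limit", "screen_alpha", "rf_top_n",
           "imputation_method", "k_range", "n_resamples",
           "subsample_fraction", "pac_bounds", "volcano_fc_threshold",
           "volcano_alpha", "network_fdr_threshold", "seed")
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    stop("config lacks required key(s): ", paste(miss, collapse = ", "))
  with(cfg, {
    if (quantification_limit < 0) stop("quantification_limit must be >= 0")
    if (screen_alpha <= 0 || screen_alpha > 1)
      stop("screen_alpha must be in (0, 1]")
    if (rf_top_n < 1) stop("rf_top_n must be >= 1")
    if (min(k_range) < 2) stop("k_range minimum must be >= 2")
    if (n_resamples < 1) stop("n_resamples must be >= 1")
    if (subsample_fraction <= 0 || subsample_fraction >= 1)
      stop("subsample_fraction must be strictly between 0 and 1")
    if (length(pac_bounds) != 2 || pac_bounds[1] < 0 ||
        pac_bounds[2] > 1 || pac_bounds[1] >= pac_bounds[2])
      stop("pac_bounds must satisfy 0 <= x1 < x2 <= 1")
    if (volcano_fc_threshold <= 0) stop("volcano_fc_threshold must be > 0")
    if (volcano_alpha <= 0 || volcano_alpha > 1)
      stop("volcano_alpha must be in (0, 1]")
    if (network_fdr_threshold <= 0)
      stop("network_fdr_threshold must be > 0")
  })
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of \code{\link{pipeline_config}}; absent
#' keys fall back to the defaults.
#'
#' @param path YAML file path.
#' @return a \code{pipeline_config}.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}
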