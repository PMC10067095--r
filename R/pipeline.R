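resolve_abundance <- function(x, level = "protein") {
  if (inherits(x, "abundance_matrix")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(load_abundance_matrix(x, level = level))
  stop("expected an abundance_matrix or a file path")
}

resolve_annotation <- function(x) {
  if (inherits(x, "sample_annotation")) return(x)
  if (is.data.frame(x)) return(sample_annotation(x))
  if (is.character(x) && length(x) == 1L) return(load_annotation(x))
  stop("expected a sample_annotation or a file path")
}

#' Run the two-stage EV-proteomics analysis end to end
#'
#' Executes, in order: quantification-limit censoring and the
#' candidate screen on the screening cohort (when supplied); then, on
#' the subtyping cohort, eligibility filtering, imputation, consensus
#' clustering with PAC-based selection of k, subtype survival
#' comparison (Kaplan-Meier / log-rank), volcano marker discovery
#' between the two major clusters, per-marker median-split survival,
#' multivariate Cox regression (age, sex, stage, log2 marker levels),
#' a curative-resection association test, and the FDR-thresholded
#' protein-protein correlation network.
#'
#' The run is a pure function of (inputs, config, seed): every
#' randomized stage derives its own stream from \code{config$seed}.
#'
#' @param config a \code{\link{pipeline_config}} (or a list of its
#'   fields).
#' @param inputs named list: \code{cohort2_abundance} and
#'   \code{cohort2_annotation} (objects or TSV paths; required),
#'   \code{cohort1_abundance} and \code{cohort1_annotation}
#'   (optional; enables the screening stage).
#' @param outdir optional directory; when given, result tables (TSV)
#'   and a machine-readable \code{summary.json} are written there.
#' @param verbose emit progress messages to stderr.
#' @return an \code{evsubtype_run} list: \code{candidates},
#'   \code{consensus}, \code{labels}, \code{survival},
#'   \code{volcano}, \code{cox}, \code{network} and \code{summary}.
#' @export
run_pipeline <- function(config, inputs, outdir = NULL,
                         verbose = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  if (is.null(inputs$cohort2_abundance) ||
      is.null(inputs$cohort2_annotation))
    stop("inputs must provide cohort2_abundance and cohort2_annotation")

  ## ---- screening cohort (optional) ----
  candidates <- NULL
  if (!is.null(inputs$cohort1_abundance)) {
    msg("screening cohort: group screen + unsupervised forests",
        verbose = verbose)
    m1 <- resolve_abundance(inputs$cohort1_abundance)
    a1 <- resolve_annotation(inputs$cohort1_annotation)
    m1 <- apply_quantification_limit(m1, cfg$quantification_limit)
    a1 <- align_annotation(m1, a1)
    screen <- mww_screen(m1, a1, alpha = cfg$screen_alpha)
    m1i <- impute_missing(m1, method = "half_min")
    stage_samples <- a1$group %in% c("StageI", "StageIV")
    rf_d <- unsupervised_rf(m1i[, stage_samples, drop = FALSE],
                            seed = stage_seed(cfg$seed, "rf"))
    rf_e <- unsupervised_rf(m1i,
                            seed = stage_seed(cfg$seed, "rf") + 1L)
    candidates <- assemble_candidates(
      screen, rf_d$importance, rf_e$importance, top_n = cfg$rf_top_n,
      feature_to_protein = attr(m1, "feature_to_protein"))
  }

  ## ---- subtyping cohort ----
  m2 <- resolve_abundance(inputs$cohort2_abundance)
  a2 <- resolve_annotation(inputs$cohort2_annotation)
  a2 <- align_annotation(m2, a2)
  keep <- which(a2$eligible)
  if (length(keep) == 0L) stop("zero eligible samples")
  m2 <- abundance_matrix(unclass(m2)[, keep, drop = FALSE],
                         level = attr(m2, "level"),
                         feature_to_protein = attr(m2, "feature_to_protein"))
  a2 <- a2[keep, , drop = FALSE]
  # only proteins quantified in >= 1 analyzed patient stay in the panel
  quantified <- rowSums(!is.na(unclass(m2))) > 0L
  if (!all(quantified)) {
    msg("dropping ", sum(!quantified),
        " protein(s) never quantified in the eligible samples",
        verbose = verbose)
    m2 <- abundance_matrix(unclass(m2)[quantified, , drop = FALSE],
                           level = attr(m2, "level"),
                           feature_to_protein = attr(m2, "feature_to_protein"))
  }

  msg("imputing (", cfg$imputation_method, ") and consensus clustering",
      verbose = verbose)
  m2i <- impute_missing(m2, method = cfg$imputation_method)
  run <- consensus_cluster(m2i, k_range = cfg$k_range,
                           n_resamples = cfg$n_resamples,
                           subsample_fraction = cfg$subsample_fraction,
                           inner = cfg$inner_clusterer %||% "kmeans",
                           seed = cfg$seed,
                           pac_bounds = cfg$pac_bounds)
  chosen_k <- select_k(run)
  labels <- final_labels(run$consensus[[as.character(chosen_k)]],
                         chosen_k)

  ## ---- survival comparison between the two major clusters ----
  msg("survival and subtype-marker characterization", verbose = verbose)
  major <- labels %in% c(1L, 2L)
  lab2 <- labels[major]
  am <- a2[major, , drop = FALSE]
  km <- lapply(split(seq_along(lab2), lab2), function(i)
    km_estimate(am$os_time[i], am$os_event[i]))
  lr <- logrank_test(am$os_time, am$os_event, lab2)

  volcano <- volcano_screen(m2i[, major, drop = FALSE],
                            lab2, cfg$volcano_fc_threshold,
                            cfg$volcano_alpha)
  hits <- volcano$protein[volcano$flag != "ns"]
  # follow-up markers: hits quantified in every sample, at most five
  complete_raw <- rownames(m2)[rowSums(is.na(m2)) == 0L]
  followup <- head(intersect(hits, complete_raw), 5L)

  median_km <- lapply(setNames(followup, followup), function(pr) {
    grp <- median_split(as.numeric(m2i[pr, ]))
    c(logrank_test(a2$os_time, a2$os_event, grp)[c("chisq", "p")])
  })

  cox <- NULL
  if (length(followup) && sum(a2$os_event, na.rm = TRUE) >= 2) {
    cov <- data.frame(age = a2$age,
                      sex = as.integer(a2$sex == "M"),
                      stage_indicators(a2$group))
    for (pr in followup) cov[[pr]] <- log2(as.numeric(m2i[pr, ]))
    cox <- cox_fit(cov, a2$os_time, a2$os_event)
  }

  fisher_p <- NA_real_
  if (any(!is.na(a2$curative_resection[major]))) {
    tab <- table(factor(lab2, levels = c(1L, 2L)),
                 factor(am$curative_resection, levels = c("yes", "no")))
    if (all(dim(tab) == c(2L, 2L)))
      fisher_p <- fisher_exact_2x2(tab)
  }

  ## ---- correlation network ----
  msg("correlation network at FDR < ", cfg$network_fdr_threshold,
      verbose = verbose)
  pairs <- correlation_matrix(m2i,
                              method = cfg$correlation_method %||%
                                "pearson_log2")
  pairs$q <- bh_adjust(pairs$p)
  net_all <- build_network(pairs, cfg$network_fdr_threshold,
                           positive_only = TRUE)
  net_focus <- build_network(pairs, cfg$network_fdr_threshold,
                             positive_only = TRUE, focus = hits)

  summary <- list(
    n_features = nrow(m2), n_samples = length(keep),
    n_candidate_features =
      if (is.null(candidates)) NA_integer_
      else attr(candidates, "n_selected_features"),
    n_candidate_proteins =
      if (is.null(candidates)) NA_integer_
      else attr(candidates, "n_selected_proteins"),
    chosen_k = chosen_k,
    pac = as.list(run$pac),
    cluster_sizes = as.list(table(labels)),
    logrank_chisq = lr$chisq, logrank_p = lr$p,
    n_up = sum(volcano$flag == "up"),
    n_down = sum(volcano$flag == "down"),
    followup_proteins = followup,
    median_split_p = lapply(median_km, `[[`, "p"),
    cox = if (is.null(cox)) NULL else cox$coefficients,
    fisher_curative_p = fisher_p,
    n_network_edges = nrow(net_all$edges),
    n_focus_edges = nrow(net_focus$edges),
    seed = cfg$seed)

  res <- structure(list(config = cfg, candidates = candidates,
                        consensus = run, chosen_k = chosen_k,
                        labels = labels, km = km, logrank = lr,
                        volcano = volcano, median_km = median_km,
                        cox = cox, fisher_curative_p = fisher_p,
                        pairs = pairs, network = net_all,
                        network_focus = net_focus,
                        imputed = m2i, annotation = a2,
                        summary = summary),
                   class = "evsubtype_run")
  if (!is.null(outdir)) write_run(res, outdir)
  res
}

#' @export
print.evsubtype_run <- function(x, ...) {
  s <- x$summary
  cat("evsubtype run\n")
  cat(sprintf("  %d proteins x %d samples; chosen k = %d (PAC %.3f)\n",
              s$n_features, s$n_samples, s$chosen_k,
              x$consensus$pac[[as.character(s$chosen_k)]]))
  cat(sprintf("  cluster sizes: %s\n",
              paste(unlist(s$cluster_sizes), collapse = "/")))
  cat(sprintf("  log-rank between clusters: chisq = %.2f, p = %.4g\n",
              s$logrank_chisq, s$logrank_p))
  cat(sprintf("  volcano: %d up, %d down; network edges (FDR < %g): %d\n",
              s$n_up, s$n_down, x$config$network_fdr_threshold,
              s$n_network_edges))
  invisible(x)
}

write_run <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name)
    write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
  if (!is.null(res$candidates)) tsv(res$candidates, "candidates.tsv")
  tsv(data.frame(sample_id = names(res$labels),
                 subtype = unname(res$labels)), "labels.tsv")
  tsv(data.frame(k = res$consensus$k_range,
                 pac = unname(res$consensus$pac)), "pac.tsv")
  tsv(res$volcano, "volcano.tsv")
  tsv(res$network$edges, "network_edges.tsv")
  if (!is.null(res$cox)) tsv(res$cox$coefficients, "cox.tsv")
  jsonlite::write_json(res$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  invisible(outdir)
}
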