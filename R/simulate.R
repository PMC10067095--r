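#' Simulation parameters for synthetic EV-proteomics cohorts
#'
#' Defaults mirror the scale of the study the pipeline is designed
#' for: 99 proteins quantified in a 110-patient subtyping cohort with
#' two latent subtypes (40/60), 12 subtype-elevated proteins at fold
#' change 2.5, a screening cohort of two tumor-stage groups and two
#' matched healthy-control groups (59 patients / 59 controls), and a
#' subtype hazard ratio of 2.5 with ~30% censoring.
#'
#' Abundances are log-normal around per-protein baselines drawn
#' log-uniformly over three orders of magnitude; values below
#' \code{detection_limit} are censored to missing, making missingness
#' missing-not-at-random by construction. With the default limit of 2
#' roughly 10\% of cells are censored.
#'
#' @param n_proteins number of proteins.
#' @param n_de_proteins size of the planted subtype-elevated set.
#' @param n_samples_per_group named counts for the screening cohort
#'   (HC1, HC2, StageI, StageIV).
#' @param n_cohort2 number of patients in the subtyping cohort.
#' @param subtype_proportions length-2 vector summing to 1; share of
#'   subtyping-cohort patients in subtypes 1 and 2.
#' @param de_fold_change multiplicative elevation (> 1) of planted
#'   proteins in subtype 1.
#' @param stage_fold_change elevation of planted proteins in StageIV
#'   screening samples (StageI gets its square root, giving all three
#'   group contrasts signal).
#' @param cv biological coefficient of variation of the log-normal
#'   abundances.
#' @param detection_limit absolute amount below which a value is
#'   censored to missing.
#' @param baseline_hazard events per day for subtype 2.
#' @param hazard_ratio subtype-1 vs subtype-2 hazard multiplier.
#' @param censor_rate target fraction of censored patients, in [0, 1].
#' @param seed integer seed.
#' @return a validated list of class \code{simulation_params}.
#' @export
simulation_params <- function(n_proteins = 99L,
                              n_de_proteins = 12L,
                              n_samples_per_group = c(HC1 = 29L, HC2 = 30L,
                                                      StageI = 29L,
                                                      StageIV = 30L),
                              n_cohort2 = 110L,
                              subtype_proportions = c(0.4, 0.6),
                              de_fold_change = 2.5,
                              stage_fold_change = 2.5,
                              cv = 0.3,
                              detection_limit = 2,
                              baseline_hazard = 5e-4,
                              hazard_ratio = 2.5,
                              censor_rate = 0.3,
                              seed = 1L) {
  p <- list(n_proteins = as.integer(n_proteins),
            n_de_proteins = as.integer(n_de_proteins),
            n_samples_per_group = n_samples_per_group,
            n_cohort2 = as.integer(n_cohort2),
            subtype_proportions = subtype_proportions,
            de_fold_change = de_fold_change,
            stage_fold_change = stage_fold_change,
            cv = cv, detection_limit = detection_limit,
            baseline_hazard = baseline_hazard,
            hazard_ratio = hazard_ratio,
            censor_rate = censor_rate, seed = as.integer(seed))
  if (p$n_de_proteins > p$n_proteins)
    stop("n_de_proteins must not exceed n_proteins")
  if (p$de_fold_change < 1) stop("de_fold_change must be >= 1")
  if (p$stage_fold_change < 1) stop("stage_fold_change must be >= 1")
  if (abs(sum(p$subtype_proportions) - 1) > 1e-8 ||
      length(p$subtype_proportions) != 2L)
    stop("subtype_proportions must be two values summing to 1")
  if (p$baseline_hazard <= 0 || p$hazard_ratio <= 0)
    stop("hazard components must be > 0")
  if (p$censor_rate < 0 || p$censor_rate > 1)
    stop("censor_rate must be in [0, 1]")
  if (any(p$n_samples_per_group < 0) ||
      is.null(names(p$n_samples_per_group)))
    stop("n_samples_per_group must be a named vector of counts")
  bad <- setdiff(names(p$n_samples_per_group), GROUP_LEVELS)
  if (length(bad))
    stop("unknown group(s) in n_samples_per_group: ",
         paste(bad, collapse = ", "))
  class(p) <- "simulation_params"
  p
}

# log-scale sd implied by a coefficient of variation
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

# Draw abundances and censor at the detection limit. A protein whose
# values are censored in every sample would never have entered a real
# targeted panel (it was never quantified), so its baseline and values
# are redrawn -- emulating panel selection while keeping censoring
# purely threshold-driven.
draw_abundances <- function(n_proteins, n, fc, sdlog, limit,
                            max_redraw = 200L) {
  theta <- 10^runif(n_proteins, 0, 3)
  vals <- theta * fc * exp(matrix(rnorm(n_proteins * n, 0, sdlog),
                                  nrow = n_proteins))
  vals[vals < limit] <- NA_real_
  for (iter in seq_len(max_redraw)) {
    dead <- which(rowSums(!is.na(vals)) == 0L)
    if (!length(dead)) break
    theta[dead] <- 10^runif(length(dead), 0, 3)
    redo <- theta[dead] * fc[dead, , drop = FALSE] *
      exp(matrix(rnorm(length(dead) * n, 0, sdlog),
                 nrow = length(dead)))
    redo[redo < limit] <- NA_real_
    vals[dead, ] <- redo
  }
  if (any(rowSums(!is.na(vals)) == 0L))
    stop("detection limit censors entire proteins; lower it")
  vals
}

#' Apply missing-not-at-random detection-limit censoring
#'
#' Sets every present value strictly below the limit to missing. This
#' is the truth-side counterpart of
#' \code{\link{apply_quantification_limit}}: the generator uses it with
#' the simulated instrument's detection limit, so low-abundance
#' proteins go missing more often than abundant ones (MNAR).
#'
#' @param m an \code{abundance_matrix}.
#' @param limit non-negative detection limit.
#' @return the censored matrix with attribute \code{n_censored}.
#' @export
apply_mnar_missingness <- function(m, limit) {
  apply_quantification_limit(m, limit)
}

#' Generate exponential survival times with subtype-dependent hazard
#'
#' Event times are exponential with hazard
#' \code{baseline_hazard * hazard_ratio^(label == 1)}; independent
#' uniform administrative censoring on (0, tau) is applied, with tau
#' solved so the expected censored fraction equals \code{censor_rate}.
#'
#' @param labels subtype label per patient, values 1 or 2; subtype 1
#'   carries the elevated hazard.
#' @param baseline_hazard events/day for subtype 2.
#' @param hazard_ratio hazard multiplier for subtype 1.
#' @param censor_rate target censored fraction in [0, 1].
#' @param seed integer seed.
#' @return a data.frame with \code{os_time} (days) and \code{os_event}
#'   (1 = death, 0 = censored) per patient.
#' @export
generate_survival <- function(labels, baseline_hazard, hazard_ratio,
                              censor_rate = 0.3, seed = 1L) {
  stopifnot(all(labels %in% c(1L, 2L)),
            baseline_hazard > 0, hazard_ratio > 0,
            censor_rate >= 0, censor_rate <= 1)
  set.seed(as.integer(seed))
  n <- length(labels)
  haz <- baseline_hazard * ifelse(labels == 1L, hazard_ratio, 1)
  t_event <- rexp(n, rate = haz)
  if (censor_rate >= 1)
    return(data.frame(os_time = runif(n, 0, 1 / baseline_hazard),
                      os_event = 0L))
  if (censor_rate <= 0)
    return(data.frame(os_time = t_event, os_event = 1L))
  # P(censored) for C ~ U(0, tau), T ~ Exp(h): (1 - exp(-h tau))/(h tau)
  w <- as.numeric(table(factor(labels, levels = c(1L, 2L)))) / n
  hs <- baseline_hazard * c(hazard_ratio, 1)
  pcens <- function(tau) sum(w * (1 - exp(-hs * tau)) / (hs * tau))
  hi <- 1 / baseline_hazard
  while (pcens(hi) > censor_rate) hi <- hi * 2
  tau <- uniroot(function(x) pcens(x) - censor_rate,
                 lower = 1e-9 / baseline_hazard, upper = hi,
                 tol = 1e-10)$root
  t_cens <- runif(n, 0, tau)
  data.frame(os_time = pmin(t_event, t_cens),
             os_event = as.integer(t_event <= t_cens))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-protein baselines log-uniformly over three orders of
#' magnitude, multiplies in subtype or stage fold changes for the
#' planted protein set, adds log-normal biological noise, applies
#' detection-limit (MNAR) censoring, and, for the subtyping cohort,
#' attaches subtype-dependent exponential survival.
#'
#' @param p a \code{\link{simulation_params}} object.
#' @param cohort \code{"cohort2"} (subtyping cohort: patients with
#'   latent subtypes and survival) or \code{"cohort1"} (screening
#'   cohort: tumor-stage and healthy-control groups).
#' @return a list with \code{abundance} (an
#'   \code{\link{abundance_matrix}}), \code{annotation} (a
#'   \code{\link{sample_annotation}}), and \code{truth} (class
#'   \code{synthetic_truth}: planted \code{subtype_label},
#'   \code{de_protein_ids}, \code{true_log_hr},
#'   \code{detection_limit}, \code{seed}).
#' @export
generate_cohort <- function(p, cohort = c("cohort2", "cohort1")) {
  stopifnot(inherits(p, "simulation_params"))
  cohort <- match.arg(cohort)
  set.seed(stage_seed(p$seed, "simulate"))

  prot_ids <- sprintf("P%03d", seq_len(p$n_proteins))
  de_ids <- prot_ids[seq_len(p$n_de_proteins)]
  sdlog <- cv_to_sdlog(p$cv)

  if (cohort == "cohort2") {
    n <- p$n_cohort2
    sid <- sprintf("C2S%03d", seq_len(n))
    n1 <- round(p$subtype_proportions[1] * n)
    labels <- rep(2L, n)
    labels[sample.int(n, n1)] <- 1L
    fc <- matrix(1, nrow = p$n_proteins, ncol = n,
                 dimnames = list(prot_ids, sid))
    fc[de_ids, labels == 1L] <- p$de_fold_change
    vals <- draw_abundances(p$n_proteins, n, fc, sdlog,
                            p$detection_limit)
    dimnames(vals) <- list(prot_ids, sid)
    m <- abundance_matrix(vals, level = "protein")

    stage <- sample(c("StageI", "StageII", "StageIII", "StageIV"),
                    n, replace = TRUE, prob = c(0.2, 0.3, 0.3, 0.2))
    surv <- generate_survival(labels, p$baseline_hazard, p$hazard_ratio,
                              p$censor_rate,
                              seed = stage_seed(p$seed, "survival"))
    cure_p <- ifelse(labels == 1L, 0.55, 0.8)
    ann <- sample_annotation(data.frame(
      sample_id = sid, cohort = "cohort2", group = stage,
      age = round(pmin(90, pmax(30, rnorm(n, 65, 10)))),
      sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.6, 0.4)),
      os_time = surv$os_time, os_event = surv$os_event,
      curative_resection = ifelse(runif(n) < cure_p, "yes", "no"),
      eligible = TRUE, stringsAsFactors = FALSE))
    truth_labels <- setNames(labels, sid)
  } else {
    sizes <- p$n_samples_per_group
    groups <- rep(names(sizes), sizes)
    n <- length(groups)
    if (n == 0L) stop("inconsistent group counts: no samples requested")
    sid <- sprintf("C1S%03d", seq_len(n))
    fc <- matrix(1, nrow = p$n_proteins, ncol = n,
                 dimnames = list(prot_ids, sid))
    fc[de_ids, groups == "StageIV"] <- p$stage_fold_change
    fc[de_ids, groups == "StageI"] <- sqrt(p$stage_fold_change)
    vals <- draw_abundances(p$n_proteins, n, fc, sdlog,
                            p$detection_limit)
    dimnames(vals) <- list(prot_ids, sid)
    m <- abundance_matrix(vals, level = "protein")
    ann <- sample_annotation(data.frame(
      sample_id = sid, cohort = "cohort1", group = groups,
      age = round(pmin(90, pmax(30, rnorm(n, 60, 12)))),
      sex = sample(c("M", "F"), n, replace = TRUE),
      os_time = NA_real_, os_event = NA_integer_,
      curative_resection = NA_character_, eligible = TRUE,
      stringsAsFactors = FALSE))
    truth_labels <- NULL
  }

  truth <- structure(list(subtype_label = truth_labels,
                          de_protein_ids = de_ids,
                          true_log_hr = log(p$hazard_ratio),
                          detection_limit = p$detection_limit,
                          seed = p$seed),
                     class = "synthetic_truth")
  list(abundance = m, annotation = ann, truth = truth)
}
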