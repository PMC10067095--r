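#' Kaplan-Meier estimate of overall survival
#'
#' Product-limit estimator; times with only censorings shrink the risk
#' set without a step in the curve.
#'
#' @param times follow-up times in days, >= 0.
#' @param events 1 = death, 0 = censored.
#' @return a \code{km_curve} data.frame with \code{time},
#'   \code{n_risk}, \code{n_event}, \code{n_censor} and
#'   \code{survival}.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("no subjects")
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#' @param curve a \code{km_curve}.
#' @param t times at which to read the survival probability.
#' @return S(t); 1 before the first event time.
#' @export
km_surv <- function(curve, t) {
  s <- c(1, curve$survival)
  vapply(t, function(ti) s[findInterval(ti, curve$time) + 1L],
         numeric(1))
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison with hypergeometric variance; the
#' statistic is referred to a chi-square distribution with 1 df.
#'
#' @param times follow-up times.
#' @param events 1 = death, 0 = censored.
#' @param group binary group label (two levels).
#' @return a list with \code{chisq}, \code{p} and \code{computable}
#'   (FALSE when there are no events at all).
#' @export
logrank_test <- function(times, events, group) {
  g <- as.factor(group)
  if (nlevels(droplevels(g)) != 2L)
    stop("log-rank needs exactly two non-empty groups")
  if (sum(events) == 0L)
    return(list(chisq = NA_real_, p = NA_real_, computable = FALSE))
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  p <- pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  list(chisq = unname(sd$chisq), p = p, computable = TRUE)
}

#' Median split of a protein level
#'
#' Patients strictly above the median form the high group; ties at the
#' median are "not above" and go to the low group.
#'
#' @param values complete numeric vector, one value per patient.
#' @return a factor with levels \code{low}, \code{high}.
#' @export
median_split <- function(values) {
  if (length(values) < 2L) stop("need >= 2 patients")
  if (anyNA(values)) stop("values must be complete (impute first)")
  if (length(unique(values)) == 1L)
    stop("all values identical: degenerate split")
  med <- median(values)
  factor(ifelse(values > med, "high", "low"),
         levels = c("low", "high"))
}

#' Cox proportional-hazards regression
#'
#' Maximizes the Cox partial likelihood with Efron handling of tied
#' event times; per-covariate Wald tests. Callers enter protein levels
#' on the log2 scale (see \code{\link{run_pipeline}}).
#'
#' @param covariates data.frame of numeric/factor covariates, no
#'   missing values.
#' @param times follow-up times.
#' @param events 1 = death, 0 = censored.
#' @return a \code{cox_fit} list: \code{coefficients} data.frame
#'   (term, beta, hr, se, z, p), \code{loglik}, \code{n},
#'   \code{n_events}.
#' @export
cox_fit <- function(covariates, times, events) {
  covariates <- as.data.frame(covariates)
  if (anyNA(covariates)) stop("covariates contain missing values")
  if (sum(events) < 2L) stop("need >= 2 events")
  const <- vapply(covariates, function(v) length(unique(v)) == 1L,
                  logical(1))
  if (any(const))
    stop("constant covariate(s): ",
         paste(names(covariates)[const], collapse = ", "))
  df <- cbind(covariates, .time = times, .event = events)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ .,
                    data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|loglik", conditionMessage(w)))
        stop("Cox fit did not converge: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("collinear covariate(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)$coefficients
  structure(list(coefficients = data.frame(
                   term = rownames(sm), beta = sm[, "coef"],
                   hr = sm[, "exp(coef)"], se = sm[, "se(coef)"],
                   z = sm[, "z"], p = sm[, "Pr(>|z|)"],
                   row.names = NULL, stringsAsFactors = FALSE),
                 loglik = fit$loglik[2L], n = fit$n,
                 n_events = fit$nevent),
            class = "cox_fit")
}

# ordinal stage indicators with StageI as reference
stage_indicators <- function(group) {
  stopifnot(all(group %in% c("StageI", "StageII", "StageIII", "StageIV")))
  data.frame(stageII = as.integer(group == "StageII"),
             stageIII = as.integer(group == "StageIII"),
             stageIV = as.integer(group == "StageIV"))
}
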