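POOR_SURVIVAL_CUTOFF_MONTHS <- 25

# patients usable for survival work: OS time and event flag both present
survival_subset <- function(cohort, quiet = FALSE) {
  ok <- !is.na(cohort$patients$os_months) & !is.na(cohort$patients$event)
  if (any(!ok) && !quiet) {
    message(sum(!ok), " patient(s) excluded from survival analysis (missing OS/event)")
  }
  keep <- cohort$patients$patient_id[ok]
  cohort$patients <- cohort$patients[ok, , drop = FALSE]
  cohort$mutations <- cohort$mutations[cohort$mutations$patient_id %in% keep, ,
                                       drop = FALSE]
  cohort
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times event/censoring times in months (non-negative).
#' @param events 1 = death, 0 = censored.
#' @return object of class \code{survival_fit}: \code{time},
#'   \code{n_risk}, \code{n_event}, \code{surv} (the step function at each
#'   observed time), \code{median_os} (smallest time with survival <= 0.5,
#'   \code{NA} when never reached) and \code{median_reached}.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop_mds("empty survival input")
  if (length(times) != length(events)) stop_mds("times/events length mismatch")
  if (any(is.na(times)) || any(times < 0)) stop_mds("times must be non-negative")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- km_median(fit$time, fit$surv)
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 surv = fit$surv, n = length(times), events = sum(events),
                 median_os = med, median_reached = !is.na(med)),
            class = "survival_fit")
}

km_median <- function(time, surv) {
  hit <- which(surv <= 0.5 + 1e-12)
  if (length(hit) == 0) NA_real_ else time[hit[1]]
}

#' @export
print.survival_fit <- function(x, ...) {
  med <- if (x$median_reached) sprintf("%.1f months", x$median_os) else "NOT_REACHED"
  cat(sprintf("survival_fit: n = %d, events = %d, median OS = %s\n",
              x$n, x$events, med))
  invisible(x)
}

#' Kaplan-Meier comparison across a patient grouping
#'
#' Fits per-group product-limit curves, reports each group's median OS and
#' a poor-survival flag (median below 25 months), and compares the groups
#' with the log-rank test. Empty groups are dropped with a warning; at
#' least two non-empty groups with at least one event are required.
#'
#' @param cohort an \code{mds_cohort}.
#' @param factor factor spec defining the groups.
#' @param context optional precomputed context (see \code{\link{crosstab}}).
#' @return object of class \code{group_comparison}: \code{groups} (a data
#'   frame with n, events, median_os, poor_survival), \code{fits},
#'   \code{logrank_stat}, \code{df}, \code{p_value}.
#' @export
km_by_factor <- function(cohort, factor, context = list()) {
  cohort <- survival_subset(cohort)
  grp <- eval_factor(cohort, factor, context)
  keep <- !is.na(grp)
  grp <- droplevels(grp[keep])
  times <- cohort$patients$os_months[keep]
  events <- cohort$patients$event[keep]
  present <- levels(grp)
  dropped <- setdiff(factor_spec(factor)$levels, present)
  if (length(dropped) > 0) {
    warn_mds("empty group(s) dropped: ", paste(dropped, collapse = ", "))
  }
  if (length(present) < 2) stop_mds("fewer than 2 non-empty groups")
  if (sum(events) == 0) stop_mds("no events in any group")
  fits <- lapply(present, function(g)
    km_estimate(times[grp == g], events[grp == g]))
  names(fits) <- present
  sd <- survival::survdiff(survival::Surv(times, events) ~ grp)
  df <- length(present) - 1L
  p <- stats::pchisq(sd$chisq, df, lower.tail = FALSE)
  groups <- data.frame(
    group = present,
    n = vapply(fits, `[[`, 0L, "n"),
    events = vapply(fits, function(f) as.integer(f$events), 0L),
    median_os = vapply(fits, `[[`, 0, "median_os"),
    median_reached = vapply(fits, `[[`, TRUE, "median_reached"),
    stringsAsFactors = FALSE)
  groups$poor_survival <- groups$median_reached &
    groups$median_os < POOR_SURVIVAL_CUTOFF_MONTHS
  rownames(groups) <- NULL
  structure(list(groups = groups, fits = fits,
                 logrank_stat = unname(sd$chisq), df = df,
                 p_value = min(max(p, .Machine$double.xmin), 1)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  print(x$groups, row.names = FALSE)
  cat(sprintf("log-rank chi-square %.3f on %d df, p = %.4g\n",
              x$logrank_stat, x$df, x$p_value))
  invisible(x)
}

#' Build a Cox covariate from a cohort
#'
#' Encodings follow the study's variate definitions: binary covariates are
#' 0/1 (\code{"age60"}: 1 when age >= 60; \code{"blast5"}: 1 when blasts
#' > 5\%; \code{"ipssr35"}: 1 for the higher-risk dichotomy;
#' \code{"gene:SYMBOL"}: 1 when mutated). Three-level ordered factors
#' (\code{"morphology"} SLD < MLD < EB and \code{"cyto3"} Good <
#' Intermediate < Poor-or-VeryPoor) enter as a single ordinal 0/1/2
#' covariate by default, or as dummy-coded factors with
#' \code{coding = "dummy"}.
#'
#' @param cohort an \code{mds_cohort} (survival subset is the caller's
#'   responsibility).
#' @param variate variate name as above.
#' @param coding \code{"ordinal"} or \code{"dummy"} (3-level factors only).
#' @param context optional precomputed context.
#' @return numeric vector (or factor under dummy coding) over patients.
#' @export
cox_covariate <- function(cohort, variate, coding = c("ordinal", "dummy"),
                          context = list()) {
  coding <- match.arg(coding)
  pts <- cohort$patients
  three_level <- function(vals, levels_) {
    if (coding == "dummy") factor(vals, levels = levels_)
    else as.numeric(factor(vals, levels = levels_)) - 1
  }
  if (grepl("^gene:", variate)) {
    return(as.numeric(eval_factor(cohort, variate, context) == "mutated"))
  }
  switch(variate,
    age60 = as.numeric(pts$age >= 60),
    blast5 = as.numeric(pts$bm_blast_pct > 5),
    ipssr35 = as.numeric(need_scores(cohort, context)$ipssr_dichotomy == "higher"),
    morphology = three_level(pts$morphology, c("SLD", "MLD", "EB")),
    cyto3 = {
      cy <- context$cyto %||% classify_cohort_cytogenetics(
        cohort, missing_karyotype = "assume_normal")
      g <- cy$group4[match(pts$patient_id, cy$patient_id)]
      g[g == "VeryPoor"] <- "Poor"
      three_level(g, c("Good", "Intermediate", "Poor"))
    },
    stop_mds("unknown Cox variate: ", variate))
}

cox_fit_frame <- function(cohort, variates, coding, context) {
  cohort <- survival_subset(cohort)
  dat <- data.frame(.time = cohort$patients$os_months,
                    .event = cohort$patients$event)
  for (v in variates) {
    dat[[make.names(v)]] <- cox_covariate(cohort, v, coding, context)
  }
  list(cohort = cohort, dat = dat, terms = make.names(variates))
}

extract_cox <- function(fit, model_type, n, events) {
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  data.frame(variate = rownames(co),
             hr = unname(co[, "exp(coef)"]),
             ci_lower = unname(ci[, "lower .95"]),
             ci_upper = unname(ci[, "upper .95"]),
             p_value = unname(co[, "Pr(>|z|)"]),
             model = model_type, n = n, events = events,
             converged = rep(is_converged(fit), nrow(co)),
             stringsAsFactors = FALSE, row.names = NULL)
}

is_converged <- function(fit) {
  # coxph flags problems through info/iter; also guard against exploded SEs
  # from complete separation
  ok <- is.null(fit$info) || !grepl("did not converge", paste(fit$info, collapse = " "))
  ses <- sqrt(diag(fit$var))
  ok && all(is.finite(ses)) && all(ses < 50)
}

#' Univariate Cox proportional-hazards model
#'
#' Partial-likelihood fit with Efron tie handling; Wald 95\% confidence
#' intervals. Patients missing OS or the event flag are excluded with a
#' logged count.
#'
#' @param cohort an \code{mds_cohort}.
#' @param variate a variate name (see \code{\link{cox_covariate}}).
#' @param coding \code{"ordinal"} (default) or \code{"dummy"}.
#' @param ties tie-handling method for the partial likelihood.
#' @param context optional precomputed context.
#' @return object of class \code{cox_result}: a data frame of hazard
#'   ratios with CI and p-values plus model metadata.
#' @export
cox_univariate <- function(cohort, variate, coding = c("ordinal", "dummy"),
                           ties = c("efron", "breslow"), context = list()) {
  coding <- match.arg(coding)
  ties <- match.arg(ties)
  ff <- cox_fit_frame(cohort, variate, coding, context)
  x <- ff$dat[[ff$terms]]
  if (length(unique(stats::na.omit(as.numeric(x)))) < 2) {
    stop_mds("variate '", variate, "' is inestimable: constant in the data")
  }
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(.time, .event) ~", ff$terms)),
    data = ff$dat, ties = ties)
  res <- extract_cox(fit, "univariate", nrow(ff$dat), sum(ff$dat$.event))
  res$variate <- sub(paste0("^", ff$terms), variate, res$variate)
  if (!all(res$converged)) {
    warn_mds("Cox fit for '", variate,
             "' flagged as non-converged (possible complete separation)")
  }
  structure(list(table = res, model = "univariate"), class = "cox_result")
}

#' Multivariate Cox proportional-hazards model
#'
#' Joint fit over several variates with the same contracts as
#' \code{\link{cox_univariate}}. Exactly collinear variates are rejected
#' with an error naming the pair; fewer than 10 events triggers a warning.
#'
#' @param cohort an \code{mds_cohort}.
#' @param variates character vector of at least two variate names.
#' @param coding,ties,context see \code{\link{cox_univariate}}.
#' @return object of class \code{cox_result}.
#' @export
cox_multivariate <- function(cohort, variates, coding = c("ordinal", "dummy"),
                             ties = c("efron", "breslow"), context = list()) {
  coding <- match.arg(coding)
  ties <- match.arg(ties)
  if (length(variates) < 2) stop_mds("multivariate model needs >= 2 variates")
  ff <- cox_fit_frame(cohort, variates, coding, context)
  num <- vapply(ff$terms, function(t) as.numeric(ff$dat[[t]]),
                numeric(nrow(ff$dat)))
  qr_ <- qr(cbind(1, num))
  if (qr_$rank < ncol(num) + 1) {
    cc <- stats::cor(num)
    pair <- which(abs(cc) > 1 - 1e-8 & upper.tri(cc), arr.ind = TRUE)
    pair_txt <- if (nrow(pair) > 0) {
      paste(variates[pair[1, 1]], "and", variates[pair[1, 2]])
    } else "unidentified pair"
    stop_mds("exactly collinear variates: ", pair_txt)
  }
  ev <- sum(ff$dat$.event)
  if (ev < 10) warn_mds("only ", ev, " events; multivariate estimates unstable")
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(.time, .event) ~",
                            paste(ff$terms, collapse = " + "))),
    data = ff$dat, ties = ties)
  res <- extract_cox(fit, "multivariate", nrow(ff$dat), ev)
  for (i in seq_along(variates)) {
    res$variate <- sub(paste0("^", ff$terms[i]), variates[i], res$variate)
  }
  structure(list(table = res, model = "multivariate"), class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox %s model (n = %d, events = %d)\n", x$model,
              x$table$n[1], x$table$events[1]))
  print(x$table[c("variate", "hr", "ci_lower", "ci_upper", "p_value",
                  "converged")], row.names = FALSE)
  invisible(x)
}
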