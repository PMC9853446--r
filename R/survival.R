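# Survival association: Kaplan-Meier estimation, two-group log-rank test,
# multivariate Cox proportional-hazards fitting (Efron ties), and
# score-versus-clinical two-group comparison. The survival package provides
# the estimators; these wrappers enforce the clinical-record contract and
# return plain, serialisable result objects.

check_records <- function(records) {
  check(is.data.frame(records), "records must be a data frame")
  check(all(c("time", "event") %in% names(records)),
        "records need 'time' and 'event' columns")
  check(all(records$time > 0), "all survival times must be positive")
  check(all(records$event %in% c(0, 1)), "event must be 0/1")
  invisible(TRUE)
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimates, optionally per group. With no censoring the curve
#' equals the empirical survival function.
#'
#' @param records data frame with columns `time`, `event` and (if
#'   `by_group`) `group`.
#' @param by_group estimate one curve per level of `group` (default TRUE).
#' @return data frame of class `km_curve` with columns `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(records, by_group = TRUE) {
  check_records(records)
  if (by_group) {
    check("group" %in% names(records), "records need a 'group' column")
    check(all(table(records$group) >= 1L), "empty group")
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = records)
    grp <- sub("^group=", "", rep(names(fit$strata), fit$strata))
  } else {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
    grp <- rep("all", length(fit$time))
  }
  out <- data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv, stringsAsFactors = FALSE)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d time points, %d group(s)\n",
              nrow(x), length(unique(x$group))))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic over the pooled risk sets,
#' referred to a chi-square distribution with 1 df.
#'
#' @param records data frame with `time`, `event`, `group` (exactly two
#'   levels, each non-empty).
#' @return list of class `logrank_result` with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(records) {
  check_records(records)
  check("group" %in% names(records), "records need a 'group' column")
  lev <- unique(as.character(records$group))
  check(length(lev) == 2L, "log-rank test requires exactly two groups")
  check(all(table(records$group) >= 1L), "one group is empty")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = records)
  chi2 <- fit$chisq
  p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = 1L, p = p), class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi2 = %.3f (df = %d), p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Multivariate Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron handling of tied event times
#' (Breslow available), Newton-Raphson with tight convergence
#' (`eps = 1e-9`, at most 50 iterations). Character/factor covariates are
#' converted via `model.matrix`; `group` is encoded with `high` as 1 when
#' present so the reported log hazard ratio refers to the high-score group.
#'
#' @param records clinical data frame (`time`, `event`, covariates).
#' @param covariates character vector of covariate column names
#'   (default `c("group", "age", "stage", "mmr")`, intersected with the
#'   available columns).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return list of class `cox_fit` with a per-covariate `coefficients` data
#'   frame (`term`, `beta`, `se`, `z`, `p`, `hr`), `converged`, `iterations`,
#'   `n`, `n_events`.
#' @export
cox_fit <- function(records, covariates = c("group", "age", "stage", "mmr"),
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_records(records)
  check(sum(records$event) >= 1L, "need at least one event")
  covariates <- intersect(covariates, names(records))
  check(length(covariates) >= 1L, "no covariate column found in records")
  df <- records[, c("time", "event", covariates), drop = FALSE]
  if ("group" %in% covariates) {
    # encode high = 1 so beta is the log-HR of the high-score group
    df$group <- as.integer(as.character(df$group) == "high")
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50L)),
    warning = function(w) {
      warning(conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  beta <- stats::coef(fit)
  converged <- all(is.finite(beta)) && all(abs(beta) < 15) &&
    fit$iter < 50L
  if (!converged) {
    warning("Cox fit did not converge cleanly (possible separation); estimates reported with caution",
            call. = FALSE)
  }
  coefs <- data.frame(term = names(beta), beta = as.numeric(beta),
                      se = s$coefficients[, "se(coef)"],
                      z = s$coefficients[, "z"],
                      p = s$coefficients[, "Pr(>|z|)"],
                      hr = exp(as.numeric(beta)),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(coefficients = coefs, converged = converged,
                 iterations = fit$iter, ties = ties,
                 n = nrow(records), n_events = sum(records$event)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n = %d, events = %d%s\n",
              x$ties, x$n, x$n_events,
              if (x$converged) "" else "  [NOT converged]"))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Two-group comparison of scores across a clinical parameter
#'
#' Welch two-sample t-test of signature scores between the two levels of a
#' categorical clinical variable (e.g. MMR proficient vs deficient).
#'
#' @param scores numeric vector of per-sample scores.
#' @param labels two-level categorical vector aligned with `scores`.
#' @return list with `t`, `p`, `means` (named by level), `levels`.
#' @export
score_vs_clinical <- function(scores, labels) {
  check(is.numeric(scores) && length(scores) == length(labels),
        "scores and labels must be aligned numeric/categorical vectors")
  labels <- as.character(labels)
  lev <- unique(labels)
  check(length(lev) == 2L, "labels must have exactly two levels")
  check(all(table(labels) >= 2L), "each level needs at least 2 samples")
  x <- scores[labels == lev[[1]]]
  y <- scores[labels == lev[[2]]]
  check(stats::sd(x) > 0 || stats::sd(y) > 0,
        "scores are constant in both groups; t-test undefined")
  ht <- stats::t.test(x, y)
  means <- c(mean(x), mean(y))
  names(means) <- lev
  list(t = unname(ht$statistic), p = ht$p.value, means = means, levels = lev)
}
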