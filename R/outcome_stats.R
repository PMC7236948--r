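# The statistics layer: 2x2 contingency analyses, survival, Cox models,
# backward-AIC logistic selection, AUROC, rank statistics.
#
# Engines: stats::fisher.test, survival::{survfit,survdiff,coxph} (Efron
# ties), stats::glm; the risk-ratio Wald interval and the midrank AUROC are
# computed directly.

#' Risk ratio with a Wald log-scale confidence interval
#'
#' Rows are the two comparison groups, columns the outcome (e.g.
#' PHBR < 0.5 / PHBR >= 0.5). RR = (a/(a+b)) / (c/(c+d));
#' CI = exp(log RR +/- z * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))).
#' No continuity correction is applied; a zero numerator cell makes the
#' Wald interval undefined and raises an error.
#'
#' @param a,b,c,d Cell counts: row 1 = (a, b), row 2 = (c, d); column 1 is
#'   the outcome of interest.
#' @param conf_level Confidence level, default 0.95.
#' @return List with `rr`, `ci_low`, `ci_high`, `conf_level`.
#' @export
risk_ratio <- function(a, b, c, d, conf_level = 0.95) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    pkg_error("cell counts must be nonnegative integers", "invalid_input")
  }
  if (a + b == 0 || c + d == 0) {
    pkg_error("both row totals must be positive", "invalid_input")
  }
  if (a == 0 || c == 0) {
    pkg_error("zero numerator cell: Wald risk-ratio CI undefined", "undefined_estimate")
  }
  rr <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(rr) + c(-1, 1) * z * se)
  list(rr = rr, ci_low = ci[1L], ci_high = ci[2L], conf_level = conf_level)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' @inheritParams risk_ratio
#' @return List with `p` (two-sided) and the conditional odds-ratio
#'   estimate.
#' @export
fisher_exact <- function(a, b, c, d) {
  m <- matrix(c(a, c, b, d), nrow = 2L)
  ft <- stats::fisher.test(m)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Kaplan-Meier fit for one group
#'
#' Product-limit estimator; the median is the smallest time with
#' S(t) <= 0.5 or "not reached". When the median is not reached, median
#' follow-up is reported via the reverse Kaplan-Meier (event flags
#' flipped).
#'
#' @param times Nonnegative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return List with `fit` (the `survfit` object), `curve` (data frame
#'   time/surv/n_risk), `median` (NA if not reached), `reached`,
#'   `median_followup`.
#' @export
km_fit <- function(times, events) {
  if (!length(times)) pkg_error("empty group", "empty_input")
  if (any(times < 0, na.rm = TRUE)) pkg_error("negative time", "domain_error")
  events <- as.integer(events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- unname(summary(fit)$table["median"])
  rfit <- survival::survfit(survival::Surv(times, 1L - events) ~ 1)
  mfu <- unname(summary(rfit)$table["median"])
  list(fit = fit,
       curve = data.frame(time = fit$time, surv = fit$surv, n_risk = fit$n.risk),
       median = med, reached = !is.na(med), median_followup = mfu)
}

#' Log-rank test across two or more groups
#'
#' For two groups an unadjusted Cox hazard ratio (Efron ties) accompanies
#' the test statistic.
#'
#' @param times,events Follow-up times and event flags.
#' @param group Grouping factor with >= 2 nonempty levels.
#' @return List with `chisq`, `df`, `p`, and for two groups `hr`,
#'   `hr_ci_low`, `hr_ci_high` (second level vs first).
#' @export
log_rank <- function(times, events, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) {
    pkg_error("log-rank needs at least two nonempty groups", "arity_error")
  }
  sd <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ group)
  df <- length(sd$n) - 1L
  res <- list(chisq = unname(sd$chisq), df = df,
              p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
  if (nlevels(group) == 2L) {
    cx <- survival::coxph(survival::Surv(times, as.integer(events)) ~ group,
                          ties = "efron")
    ci <- exp(stats::confint(cx))
    res$hr <- unname(exp(stats::coef(cx)))
    res$hr_ci_low <- ci[1L]
    res$hr_ci_high <- ci[2L]
  }
  res
}

#' Cox proportional-hazards regression, optionally stratified
#'
#' Partial-likelihood maximization with Efron's tie handling. When `strata`
#' is given each stratum keeps its own baseline hazard, so the model
#' quantifies covariate effects within strata (e.g. the PHBR effect within
#' TMB-high and TMB-low patients).
#'
#' @param times,events Follow-up times and event flags.
#' @param covariates Data frame of covariates (complete cases are used).
#' @param strata Optional stratification factor.
#' @return List with `fit` and `coefficients` (term, coef, hr, ci_low,
#'   ci_high, p).
#' @export
cox_ph <- function(times, events, covariates, strata = NULL) {
  events <- as.integer(events)
  if (sum(events, na.rm = TRUE) == 0L) {
    pkg_error("no events: Cox model degenerate", "degenerate_model")
  }
  dat <- as.data.frame(covariates)
  dat$.time <- times
  dat$.event <- events
  rhs <- names(covariates)
  if (!is.null(strata)) {
    if (!any(tapply(events, strata, sum, default = 0L) >= 1L)) {
      pkg_error("no stratum contains an event", "degenerate_model")
    }
    dat$.strata <- strata
    rhs <- c(rhs, "strata(.strata)")
  }
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(rhs, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  if (!is.null(fit$info) && isTRUE(!fit$info$converged)) {
    warning("Cox partial likelihood did not converge; estimates reported with diagnostics")
  }
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  list(fit = fit,
       coefficients = data.frame(
         term = rownames(co),
         coef = co[, "coef"],
         hr = co[, "exp(coef)"],
         ci_low = ci[, 3L],
         ci_high = ci[, 4L],
         p = co[, "Pr(>|z|)"],
         row.names = NULL, stringsAsFactors = FALSE))
}

#' Rank-based AUROC
#'
#' The Mann-Whitney form with midranks for ties: the probability that a
#' randomly chosen positive scores higher than a randomly chosen negative
#' (ties counted half).
#'
#' @param scores Numeric predictor scores.
#' @param labels Binary outcome (logical, 0/1, or two-level factor; the
#'   second level / TRUE / 1 is the positive class).
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2L]
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    pkg_error("AUROC undefined: both classes must be present", "undefined_estimate")
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Backward AIC elimination for a logistic model, then forced additions
#'
#' Starting from the full candidate set, single terms are removed one at a
#' time; a removal is accepted iff the resulting AIC does not exceed the
#' current AIC (the candidate whose removal lowers AIC most is taken
#' first), repeating until no acceptable removal remains. Forced terms
#' (e.g. TMB then PHBR) are then added sequentially and the AIC recorded at
#' each addition, together with each model's AUROC.
#'
#' @param data Data frame (complete cases are used).
#' @param outcome Name of the binary outcome column.
#' @param candidates Character vector of candidate confounder columns.
#' @param forced Character vector of terms added after selection, in order.
#' @return List with `retained`, `trace` (step/action/term/aic), `fit`
#'   (final glm with forced terms), `coefficients`, `auroc` (named vector:
#'   selected model and each forced addition), `separation` flag.
#' @export
backward_aic_logistic <- function(data, outcome, candidates, forced = NULL) {
  vars <- unique(c(outcome, candidates, forced))
  dat <- stats::na.omit(data[, vars, drop = FALSE])
  y <- dat[[outcome]]
  if (is.factor(y)) y <- y == levels(y)[2L]
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2L) {
    pkg_error("outcome must take both values", "degenerate_model")
  }
  dat[[outcome]] <- y
  separation <- FALSE
  fit_terms <- function(terms) {
    fml <- stats::reformulate(if (length(terms)) terms else "1", response = outcome)
    fit <- withCallingHandlers(
      stats::glm(fml, family = stats::binomial(), data = dat),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    fit
  }
  current <- candidates
  fit <- fit_terms(current)
  trace <- data.frame(step = 0L, action = "start", term = NA_character_,
                      aic = stats::AIC(fit), stringsAsFactors = FALSE)
  step <- 0L
  while (length(current)) {
    aics <- vapply(current, function(tm) {
      stats::AIC(fit_terms(setdiff(current, tm)))
    }, numeric(1L))
    best <- which.min(aics)
    if (aics[best] <= stats::AIC(fit)) {
      step <- step + 1L
      trace <- rbind(trace, data.frame(step = step, action = "remove",
                                       term = current[best], aic = aics[best],
                                       stringsAsFactors = FALSE))
      current <- current[-best]
      fit <- fit_terms(current)
    } else break
  }
  retained <- current
  auc <- c(selected = model_auroc(fit, dat, outcome))
  for (tm in forced) {
    step <- step + 1L
    current <- c(current, tm)
    fit <- fit_terms(current)
    trace <- rbind(trace, data.frame(step = step, action = "add_forced",
                                     term = tm, aic = stats::AIC(fit),
                                     stringsAsFactors = FALSE))
    auc[paste0("+", tm)] <- model_auroc(fit, dat, outcome)
  }
  if (separation) {
    warning("complete or quasi-complete separation detected; coefficients may be unstable")
  }
  sm <- summary(fit)$coefficients
  list(retained = retained, trace = trace, fit = fit,
       coefficients = data.frame(term = rownames(sm), estimate = sm[, 1L],
                                 se = sm[, 2L], p = sm[, 4L],
                                 row.names = NULL, stringsAsFactors = FALSE),
       auroc = auc, separation = separation)
}

model_auroc <- function(fit, dat, outcome) {
  auroc(stats::predict(fit, type = "response"), dat[[outcome]])
}

#' Spearman rank correlation
#'
#' Midrank handling of ties; the two-sided p value uses the t
#' approximation (exact enumeration is infeasible in the presence of ties).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho` and `p`.
#' @export
spearman_cor <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) pkg_error("need at least 3 paired observations", "invalid_input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    pkg_error("Spearman rho undefined for a constant vector", "undefined_estimate")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with tie correction; exact p for small untied samples
#' (stats::wilcox.test defaults).
#'
#' @param x,y Numeric samples.
#' @return List with `U` (statistic for `x`) and two-sided `p`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) pkg_error("both samples must be nonempty", "empty_input")
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  list(U = unname(wt$statistic), p = wt$p.value)
}
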