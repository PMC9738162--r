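#' Kaplan-Meier product-limit estimate
#'
#' Returns the step function evaluated at the distinct event times, the
#' median (earliest time at which the estimate drops to 0.5 or below;
#' undefined when it never does) and the analogous 25th/75th percentile
#' times.
#'
#' @param time follow-up times (> 0)
#' @param event 1 = event, 0 = right-censored
#' @return list with `time`, `n_risk`, `n_event`, `surv`, `median`, `q25`,
#'   `q75` (percentile times NA when undefined)
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1,
            all(time > 0))
  event <- as.integer(event)
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  et <- sort(unique(time[event == 1]))
  n <- length(time)
  n_risk <- n_event <- integer(length(et))
  surv <- numeric(length(et))
  s <- 1
  for (k in seq_along(et)) {
    n_risk[k] <- sum(time >= et[k])
    n_event[k] <- sum(time == et[k] & event == 1)
    s <- s * (1 - n_event[k] / n_risk[k])
    surv[k] <- s
  }
  qtime <- function(p) {
    hit <- which(surv <= p)
    if (!length(hit)) NA_real_ else et[min(hit)]
  }
  list(time = et, n_risk = n_risk, n_event = n_event, surv = surv,
       median = qtime(0.5), q25 = qtime(0.75), q75 = qtime(0.25))
}

#' Logrank test across groups
#'
#' Standard observed-minus-expected chi-square over the pooled event times
#' with hypergeometric variance; `df = groups - 1`. Empty groups are
#' dropped with a warning.
#'
#' @param time follow-up times
#' @param event event indicators
#' @param group group labels
#' @return list with `statistic`, `df`, `p`, `observed`, `expected`
#' @export
logrank <- function(time, event, group) {
  group <- factor(group)
  if (any(table(group) == 0)) {
    warning("dropping empty groups")
    group <- droplevels(group)
  }
  G <- nlevels(group)
  if (G < 2) stopf("need >= 2 groups")
  if (sum(event) < 1) stopf("need >= 1 event")
  et <- sort(unique(time[event == 1]))
  O <- E <- numeric(G)
  V <- matrix(0, G, G)
  for (t in et) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(time == t & event == 1)
    n_g <- tabulate(group[at_risk], G)
    d_g <- tabulate(group[time == t & event == 1], G)
    O <- O + d_g
    E <- E + d_t * n_g / n_t
    if (n_t > 1) {
      frac <- n_g / n_t
      vt <- d_t * (n_t - d_t) / (n_t - 1) *
        (diag(frac, G) - outer(frac, frac))
      V <- V + vt
    }
  }
  dif <- (O - E)[-1]
  Vi <- V[-1, -1, drop = FALSE]
  stat <- as.numeric(t(dif) %*% solve(Vi, dif))
  list(statistic = stat, df = G - 1,
       p = stats::pchisq(stat, G - 1, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling. Categorical covariates
#' are expanded against their stated reference level (molecular profile:
#' BRCAm; density strata: the low stratum). Monotone likelihood
#' (separation) is flagged with a warning.
#'
#' @param data data.frame
#' @param time,event column names of the outcome
#' @param covariates character vector of covariate column names
#' @param references named list of reference levels for factor covariates
#' @return a `cox_fit`: list with `coefficients` table (term, coef, hr,
#'   lower, upper, se, p), `loglik`, `fit` (the underlying model object)
#' @export
cox_fit <- function(data, time = "os_months", event = "os_event",
                    covariates, references = list()) {
  stopifnot(length(covariates) >= 1)
  if (sum(data[[event]]) < 1) stopf("need >= 1 event")
  df <- data
  for (v in covariates) {
    if (is.character(df[[v]]) || is.factor(df[[v]]) || is.logical(df[[v]])) {
      df[[v]] <- factor(df[[v]])
      if (!is.null(references[[v]]))
        df[[v]] <- stats::relevel(df[[v]], ref = references[[v]])
    } else if (stats::sd(df[[v]], na.rm = TRUE) == 0)
      stopf("constant covariate: %s", v)
  }
  fml <- stats::as.formula(paste0("survival::Surv(", time, ", ", event,
                                  ") ~ ", paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  sm <- summary(fit)
  cf <- sm$coefficients
  if (any(abs(cf[, "coef"]) > 15, na.rm = TRUE))
    warning("possible monotone likelihood (separation) in Cox fit")
  tab <- data.frame(term = rownames(cf), coef = cf[, "coef"],
                    hr = exp(cf[, "coef"]),
                    lower = exp(cf[, "coef"] - 1.96 * cf[, "se(coef)"]),
                    upper = exp(cf[, "coef"] + 1.96 * cf[, "se(coef)"]),
                    se = cf[, "se(coef)"], p = cf[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = tab, loglik = fit$loglik[2], fit = fit),
            class = "cox_fit")
}

#' Univariable screen plus backward-selected multivariable Cox model
#'
#' Candidates are screened univariably at `entry_p`; survivors enter a
#' joint model together with the adjustment set (always retained), and
#' backward elimination repeatedly drops the screened candidate with the
#' largest Wald p above `stay_p` until the model is stable. When no
#' candidate survives, the adjustment-set-only fit is returned with a note.
#'
#' @inheritParams cox_fit
#' @param candidates covariates subject to screening and elimination
#' @param adjust_set covariates always retained (may be empty)
#' @param entry_p univariable screening threshold (default 0.10)
#' @param stay_p backward-elimination stay threshold (default 0.05)
#' @return a `cox_fit` with attributes `selected` (retained candidates) and
#'   `screened` (candidates passing the univariable screen)
#' @export
multivariable_select <- function(data, time = "os_months",
                                 event = "os_event", candidates,
                                 adjust_set = character(0),
                                 entry_p = 0.10, stay_p = 0.05,
                                 references = list()) {
  stopifnot(length(candidates) >= 1)
  screened <- character(0)
  for (v in candidates) {
    fit <- cox_fit(data, time, event, v, references)
    if (min(fit$coefficients$p) < entry_p) screened <- c(screened, v)
  }
  current <- screened
  note <- NULL
  repeat {
    if (!length(current)) {
      note <- "no candidate survived selection; adjustment-set-only model"
      if (!length(adjust_set)) stopf("empty final model and no adjust set")
      final <- cox_fit(data, time, event, adjust_set, references)
      break
    }
    final <- cox_fit(data, time, event, c(current, adjust_set), references)
    worst_p <- -Inf; worst <- NULL
    for (v in current) {
      pv <- min(final$coefficients$p[grep(paste0("^", v),
                                          final$coefficients$term)])
      if (pv > worst_p) { worst_p <- pv; worst <- v }
    }
    if (worst_p > stay_p) current <- setdiff(current, worst) else break
  }
  attr(final, "selected") <- current
  attr(final, "screened") <- screened
  attr(final, "note") <- note
  final
}
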