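#' Compare a continuous variable across groups
#'
#' Two groups: independent-sample two-sided t-test (pooled variance).
#' More than two groups: one-way ANOVA.
#'
#' @param values numeric vector.
#' @param groups group labels (coerced to factor).
#' @return list with `method`, `statistic`, `df`, `p`.
#' @export
group_compare <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("group_compare: need at least 2 groups")
  if (any(table(groups) < 2L))
    stop("group_compare: every group needs at least 2 observations")
  if (nlevels(groups) == 2L) {
    tt <- stats::t.test(values ~ groups, var.equal = TRUE)
    list(method = "t-test", statistic = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value)
  } else {
    av <- stats::oneway.test(values ~ groups, var.equal = TRUE)
    list(method = "anova", statistic = unname(av$statistic),
         df = unname(av$parameter), p = av$p.value)
  }
}

## Greenhouse-Geisser epsilon from the within-subject covariance matrix:
## with S the k x k covariance of the (complete-case) network columns and
## C the double-centering projector, eps = tr(CSC)^2 / ((k-1) * tr((CSC)^2)).
gg_epsilon <- function(sigma) {
  k <- ncol(sigma)
  cc <- diag(k) - matrix(1 / k, k, k)
  m <- cc %*% sigma %*% cc
  sum(diag(m))^2 / ((k - 1) * sum(m * m))
}

#' Mixed repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject factor: network (the columns of `fc_matrix`); optional
#' between-subject factor.  Rows with missing values are removed (listwise
#' deletion).  Degrees of freedom of the within-subject tests are
#' multiplied by the Greenhouse-Geisser epsilon estimated from the
#' within-subject covariance.
#'
#' @param fc_matrix numeric matrix, subjects x within-levels (e.g. the 7
#'   network FC columns).
#' @param between_factor optional vector of between-subject labels.
#' @return list with `epsilon_gg`, `within` (F, uncorrected df, GG df, p),
#'   `between` (F, df, p or `NULL`), `interaction` (when a between factor
#'   is present) and `n_used`.
#' @export
rm_anova_gg <- function(fc_matrix, between_factor = NULL) {
  fc_matrix <- as.matrix(fc_matrix)
  k <- ncol(fc_matrix)
  if (k < 2L) stop("rm_anova_gg: need at least 2 within-subject levels")
  keep <- complete.cases(fc_matrix) &
    (if (is.null(between_factor)) TRUE else !is.na(between_factor))
  y <- fc_matrix[keep, , drop = FALSE]
  if (nrow(y) < 3L) stop("rm_anova_gg: too few complete cases")
  grp <- if (is.null(between_factor)) NULL else factor(between_factor[keep])
  idata <- data.frame(network = factor(seq_len(k)))
  mod <- if (is.null(grp)) lm(y ~ 1) else lm(y ~ grp)
  av <- car::Anova(mod, idata = idata, idesign = ~network, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  # epsilon from the pooled within-group residual covariance; degenerate
  # (zero within-subject variation) data are treated as spherical
  res <- stats::residuals(mod)
  sigma <- crossprod(res) / stats::df.residual(mod)
  eps <- if (k == 2L) 1 else gg_epsilon(sigma)
  if (!is.finite(eps)) eps <- 1
  gg_p <- function(row) {
    f <- ut[row, "F value"]
    if (!is.finite(f)) f <- 0   # zero effect and zero error SS
    df1 <- ut[row, "num Df"] * eps
    df2 <- ut[row, "den Df"] * eps
    list(F = unname(f), df1 = unname(df1), df2 = unname(df2),
         p = unname(pf(f, df1, df2, lower.tail = FALSE)))
  }
  within <- gg_p("network")
  between <- NULL
  interaction <- NULL
  if (!is.null(grp)) {
    between <- list(F = unname(ut["grp", "F value"]),
                    df1 = unname(ut["grp", "num Df"]),
                    df2 = unname(ut["grp", "den Df"]),
                    p = unname(pf(ut["grp", "F value"], ut["grp", "num Df"],
                                  ut["grp", "den Df"], lower.tail = FALSE)))
    interaction <- gg_p("grp:network")
  }
  list(epsilon_gg = eps, within = within, between = between,
       interaction = interaction, n_used = nrow(y))
}

#' Kaplan-Meier curves with a log-rank test
#'
#' @param time survival times (months).
#' @param event event indicator (1 = death, 0 = censored).
#' @param groups group labels (>= 2 groups).
#' @return list with `fit` (a `survival::survfit`), `chisq`, `df`, `p` and
#'   `medians` (per-group median survival: first time the survivor function
#'   drops to 0.5 or below; `NA` if never reached).
#' @export
km_logrank <- function(time, event, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("km_logrank: need at least 2 groups")
  if (sum(event) < 1L) stop("km_logrank: need at least one event")
  dat <- data.frame(time = time, event = event, g = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data = dat)
  sd0 <- survival::survdiff(survival::Surv(time, event) ~ g, data = dat)
  df <- length(sd0$n) - 1L
  # median = first time the survivor function drops to 0.5 or below
  sf <- summary(fit)
  strat <- if (is.null(sf$strata)) factor(rep(levels(groups)[1],
                                              length(sf$time))) else sf$strata
  med <- vapply(levels(strat), function(s) {
    tt <- sf$time[strat == s][sf$surv[strat == s] <= 0.5]
    if (length(tt)) min(tt) else NA_real_
  }, numeric(1))
  names(med) <- sub("^g=", "", names(med))
  list(fit = fit, chisq = unname(sd0$chisq), df = df,
       p = pchisq(sd0$chisq, df, lower.tail = FALSE), medians = med)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group subjects by median or quartile extremes
#'
#' `"median"` splits at the median into `low`/`high` (values at the cut go
#' low).  `"quartile-extremes"` labels the lower quartile, the two middle
#' quartiles and the upper quartile (`lower-quartile` / `middle` /
#' `upper-quartile`), the grouping used for survival stratification by FC.
#'
#' @param values numeric vector (no missing values).
#' @param scheme `"median"` or `"quartile-extremes"`.
#' @return factor of group labels; cut values in the `"cuts"` attribute and
#'   the number of observations tied with a cut in `"n_ties"`.
#' @export
quantile_groups <- function(values, scheme = c("median", "quartile-extremes")) {
  scheme <- match.arg(scheme)
  if (anyNA(values)) stop("quantile_groups: missing values not allowed")
  if (length(unique(values)) == 1L)
    stop("quantile_groups: all values equal; degenerate grouping")
  if (scheme == "median") {
    cut <- median(values)
    g <- factor(ifelse(values <= cut, "low", "high"),
                levels = c("low", "high"))
    cuts <- c(median = cut)
  } else {
    if (length(values) < 4L)
      stop("quantile_groups: quartile scheme needs n >= 4")
    q <- quantile(values, c(0.25, 0.75))
    g <- factor(ifelse(values <= q[1], "lower-quartile",
                ifelse(values > q[2], "upper-quartile", "middle")),
                levels = c("lower-quartile", "middle", "upper-quartile"))
    cuts <- c(q1 = unname(q[1]), q3 = unname(q[2]))
  }
  structure(g, cuts = cuts, n_ties = sum(values %in% cuts))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit (Efron tie handling by default) returning, per
#' covariate, the log hazard ratio, hazard ratio, 95% Wald confidence
#' interval and Wald p-value.
#'
#' @param data `data.frame` with time, event and covariate columns.
#' @param covariates character vector of covariate column names.
#' @param time,event column names of the survival time and event flag.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return a `cox_result`: `data.frame` of per-term estimates with the
#'   fitted model in the `"fit"` attribute and its log-likelihood in
#'   `"loglik"`.
#' @export
cox_fit <- function(data, covariates, time = "os_months", event = "event",
                    ties = "efron") {
  if (!length(covariates)) stop("cox_fit: no covariates given")
  n_events <- sum(data[[event]])
  if (n_events < length(covariates) + 1L)
    warning(sprintf("cox_fit: only %d events for %d covariates", n_events,
                    length(covariates)))
  f <- reformulate(covariates,
                   sprintf("survival::Surv(%s, %s)", time, event))
  fit <- survival::coxph(f, data = data, ties = ties)
  if (any(is.na(coef(fit))))
    stop("cox_fit: coefficients not estimable (separation or collinearity)")
  sm <- summary(fit)
  res <- data.frame(term = rownames(sm$coefficients),
                    coef = sm$coefficients[, "coef"],
                    hazard_ratio = sm$coefficients[, "exp(coef)"],
                    ci_lo = sm$conf.int[, "lower .95"],
                    ci_hi = sm$conf.int[, "upper .95"],
                    p_wald = sm$coefficients[, "Pr(>|z|)"],
                    row.names = NULL)
  structure(res, fit = fit, loglik = fit$loglik[2], class =
              c("cox_result", "data.frame"))
}

## Score test for adding `candidate` to the model containing `base` (whose
## coefficients are held at their MLE): coxph evaluated at the initial
## values with zero iterations returns the global score statistic, which at
## the base MLE reduces to the 1-df score test for the new term.  With an
## empty base this is the classical log-rank / score test.
cox_score_test_p <- function(data, base, candidate, time, event, ties) {
  init_base <- if (length(base)) {
    coef(attr(cox_fit(data, base, time, event, ties), "fit"))
  } else numeric(0)
  f <- reformulate(c(base, candidate),
                   sprintf("survival::Surv(%s, %s)", time, event))
  f0 <- suppressWarnings(
    survival::coxph(f, data = data, ties = ties,
                    init = c(init_base, 0),
                    control = survival::coxph.control(iter.max = 0)))
  pchisq(f0$score, df = 1, lower.tail = FALSE)
}

#' Stepwise Cox covariate selection
#'
#' Forward: repeatedly add the candidate with the smallest score-test
#' p-value while it is below `p_enter`.  Backward: start from the full
#' model and repeatedly drop the covariate with the largest Wald p-value
#' while it exceeds `p_remove`.  An empty final model is a valid outcome.
#'
#' @param data `data.frame` with time, event and candidate columns.
#' @param candidates character vector of candidate covariate names.
#' @param p_enter forward entry threshold (default 0.05).
#' @param p_remove backward removal threshold (default 0.10).
#' @param direction `"forward"` or `"backward"`.
#' @inheritParams cox_fit
#' @return list with `selected` (character), `result` (a `cox_result` or
#'   `NULL` for the empty model) and `trace` (`data.frame` of steps).
#' @export
cox_stepwise <- function(data, candidates, p_enter = 0.05, p_remove = 0.10,
                         direction = c("forward", "backward"),
                         time = "os_months", event = "event",
                         ties = "efron") {
  direction <- match.arg(direction)
  if (!length(candidates)) stop("cox_stepwise: no candidates given")
  trace <- data.frame(step = integer(0), action = character(0),
                      term = character(0), p = numeric(0))
  if (direction == "forward") {
    sel <- character(0); pool <- candidates; step <- 0L
    repeat {
      if (!length(pool)) break
      ps <- vapply(pool, function(cn)
        cox_score_test_p(data, sel, cn, time, event, ties), numeric(1))
      if (min(ps) >= p_enter) break
      step <- step + 1L
      add <- pool[which.min(ps)]
      trace <- rbind(trace, data.frame(step = step, action = "add",
                                       term = add, p = min(ps)))
      sel <- c(sel, add); pool <- setdiff(pool, add)
    }
  } else {
    sel <- candidates; step <- 0L
    while (length(sel)) {
      res <- cox_fit(data, sel, time, event, ties)
      worst <- which.max(res$p_wald)
      if (res$p_wald[worst] <= p_remove) break
      step <- step + 1L
      trace <- rbind(trace, data.frame(step = step, action = "drop",
                                       term = res$term[worst],
                                       p = res$p_wald[worst]))
      sel <- setdiff(sel, res$term[worst])
    }
  }
  result <- if (length(sel)) cox_fit(data, sel, time, event, ties) else NULL
  list(selected = sel, result = result, trace = trace)
}

#' Univariate Cox models, one covariate at a time
#'
#' @inheritParams cox_stepwise
#' @param covariates covariate names, each fitted alone.
#' @return `data.frame`, one row per covariate, with the [cox_fit()]
#'   columns.
#' @export
cox_univariate <- function(data, covariates, time = "os_months",
                           event = "event", ties = "efron") {
  do.call(rbind, lapply(covariates, function(cv)
    as.data.frame(cox_fit(data, cv, time, event, ties))))
}
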