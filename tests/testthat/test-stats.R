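test_that("group comparison chooses t-test or ANOVA and behaves at the null", {
  x <- c(1, 2, 3, 4, 2, 3)
  g2 <- rep(c("a", "b"), 3)
  r <- group_compare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r$method, "t-test")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  r3 <- group_compare(rnorm(30), rep(letters[1:3], 10))
  expect_equal(r3$method, "anova")
  expect_error(group_compare(x, c("a", rep("b", 5))), "at least 2")
  # strong shift: decisive rejection
  set.seed(30)
  y <- c(rnorm(20), rnorm(20) + 3)
  expect_lt(group_compare(y, rep(c("a", "b"), each = 20))$p, 1e-3)
})

test_that("group comparison holds its size under the null", {
  set.seed(31)
  nrep <- 600
  rej <- vapply(seq_len(nrep), function(i) {
    v <- rnorm(36)
    group_compare(v, rep(letters[1:3], each = 12))$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("Greenhouse-Geisser epsilon has its theoretical bounds and edge cases", {
  set.seed(40)
  # two within levels: epsilon is exactly 1
  y2 <- matrix(rnorm(60), 30, 2)
  r2 <- rm_anova_gg(y2)
  expect_equal(r2$epsilon_gg, 1)
  # random 7-column data: 1/6 <= eps <= 1
  for (i in 1:5) {
    y <- matrix(rnorm(25 * 7), 25, 7) %*% matrix(rnorm(49), 7, 7)
    r <- rm_anova_gg(y)
    expect_gte(r$epsilon_gg, 1 / 6 - 1e-12)
    expect_lte(r$epsilon_gg, 1 + 1e-12)
  }
  # compound-symmetric data are nearly spherical: eps close to 1
  u <- rnorm(50, 0, 2)
  ycs <- sweep(matrix(rnorm(50 * 7), 50, 7), 1, u, `+`)
  expect_gte(rm_anova_gg(ycs)$epsilon_gg, 0.9)
  # identical columns: no within-network effect
  yc <- matrix(rep(rnorm(20), 7), 20, 7)
  expect_lt(rm_anova_gg(yc)$within$F, 1e-20)
  expect_error(rm_anova_gg(matrix(rnorm(10), 10, 1)), "at least 2")
})

test_that("epsilon matches an independent covariance-based computation", {
  # oracle: double-center the sample covariance S and form
  # tr(CSC)^2 / ((k-1) tr((CSC)^2))
  set.seed(41)
  y <- matrix(rnorm(40 * 5), 40, 5) %*% matrix(rnorm(25), 5, 5)
  s <- cov(y)
  k <- 5
  cc <- diag(k) - matrix(1 / k, k, k)
  m <- cc %*% s %*% cc
  eps_oracle <- sum(diag(m))^2 / ((k - 1) * sum(m * m))
  expect_equal(rm_anova_gg(y)$epsilon_gg, eps_oracle, tolerance = 1e-8)
})

test_that("mixed ANOVA separates within and between effects", {
  set.seed(42)
  n <- 40
  grp <- rep(c("lo", "hi"), each = n / 2)
  shift <- ifelse(grp == "hi", 2, 0)
  means <- c(0, 0, 1, 1, 0, 0, 0) * 2
  y <- sweep(matrix(rnorm(n * 7), n, 7), 2, means, `+`) + shift
  r <- rm_anova_gg(y, grp)
  expect_lt(r$within$p, 0.001)          # network effect present
  expect_lt(r$between$p, 0.001)         # group effect present
  expect_false(is.null(r$interaction))
  # GG correction shrinks degrees of freedom
  expect_lte(r$within$df1, 6)
})

test_that("Kaplan-Meier identities hold without censoring", {
  tt <- c(3, 1, 4, 1.5, 5, 9, 2.6, 7)
  ev <- rep(1L, 8)
  g <- rep(c("a", "b"), 4)
  km <- km_logrank(tt, ev, g)
  # no censoring, single-group check: KM equals the empirical survivor fn
  fit1 <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  emp <- vapply(fit1$time, function(s) mean(tt > s), numeric(1))
  expect_equal(fit1$surv, emp)
  expect_equal(unname(km$medians["a"]), median(c(3, 4, 5, 2.6)), tolerance = 1)
  # identical groups: log-rank chi-square 0, p = 1
  km0 <- km_logrank(rep(tt, 2), rep(ev, 2), rep(c("x", "y"), each = 8))
  expect_equal(km0$chisq, 0, tolerance = 1e-10)
  expect_equal(km0$p, 1, tolerance = 1e-10)
  expect_error(km_logrank(tt, ev, rep("a", 8)), "2 groups")
  expect_error(km_logrank(tt, rep(0L, 8), g), "event")
})

test_that("median survival is the first time S drops to 0.5 or below", {
  tt <- c(1, 2, 3, 4, 5, 6, 7, 100)
  km <- km_logrank(c(tt, tt + 0.5), rep(1, 16), rep(c("a", "b"), each = 8))
  expect_equal(unname(km$medians), c(4, 4.5))
  # median undefined when S never reaches 0.5 (heavy censoring)
  ev <- c(1, rep(0, 7))
  km2 <- km_logrank(c(tt, tt), c(ev, rep(1, 8)), rep(c("a", "b"), each = 8))
  expect_true(is.na(km2$medians["a"]))
})

test_that("quantile grouping reproduces the documented split patterns", {
  q <- quantile_groups(1:8, "quartile-extremes")
  expect_equal(as.vector(table(q)), c(2, 4, 2))
  m <- quantile_groups(1:8, "median")
  expect_equal(as.vector(table(m)), c(4, 4))
  expect_equal(levels(m), c("low", "high"))
  # ties straddling a cut go to the lower group, counted
  v <- c(1, 2, 2, 3)
  gm <- quantile_groups(v, "median")
  expect_equal(sum(gm == "low"), 3)
  expect_gte(attr(gm, "n_ties"), 1)
  expect_error(quantile_groups(rep(2, 10)), "degenerate")
  expect_error(quantile_groups(1:3, "quartile-extremes"), "n >= 4")
  # a 82-subject cohort splits 21/40/21 like quartile-extreme grouping
  expect_equal(as.vector(table(quantile_groups(seq_len(82) + 0.1 * sin(1:82),
                                               "quartile-extremes"))),
               c(21, 40, 21))
})

test_that("Cox fit reports HR, CI and Wald p with partial-likelihood properties", {
  cp <- sim_cohort_params(n_subjects = 200, censor_rate = 0.2, seed = 11)
  ch <- simulate_cohort(cp)$cohort
  fit <- cox_fit(ch, c("fc_dan", "age"))
  expect_equal(fit$hazard_ratio, exp(fit$coef))
  expect_true(all(fit$ci_lo < fit$hazard_ratio & fit$hazard_ratio < fit$ci_hi))
  # duplicating every subject leaves point estimates unchanged (exact for
  # Breslow ties: the duplicated partial likelihood is the square of the
  # original up to a constant)
  fitb <- cox_fit(ch, c("fc_dan", "age"), ties = "breslow")
  fit2 <- suppressWarnings(cox_fit(rbind(ch, ch), c("fc_dan", "age"),
                                   ties = "breslow"))
  expect_equal(fit2$coef, fitb$coef, tolerance = 1e-6)
  expect_true(all(fit2$ci_hi - fit2$ci_lo < fit$ci_hi - fit$ci_lo))
  expect_warning(cox_fit(ch[ch$event == 1, ][1:3, ], c("fc_dan", "age", "ecog")),
                 "events")
})

test_that("the Cox score test at zero equals the log-rank statistic", {
  set.seed(12)
  n <- 40
  tt <- round(rexp(n), 6) + seq_len(n) * 1e-4   # no ties
  ev <- rep(1L, n)
  g <- rep(0:1, each = n / 2)
  dat <- data.frame(os_months = tt, event = ev, g = g)
  sd0 <- survival::survdiff(survival::Surv(tt, ev) ~ g)
  p_score <- gliomafc:::cox_score_test_p(dat, character(0), "g",
                                         "os_months", "event", "efron")
  expect_equal(p_score, pchisq(sd0$chisq, 1, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("stepwise selection adds true effects and stays honest at the null", {
  # single-candidate problem: forward and backward agree
  cp <- sim_cohort_params(n_subjects = 300, censor_rate = 0, seed = 21)
  ch <- simulate_cohort(cp)$cohort
  fw <- cox_stepwise(ch, "fc_dan", direction = "forward")
  bw <- cox_stepwise(ch, "fc_dan", direction = "backward")
  expect_equal(fw$selected, bw$selected)
  # planted effect among 7 candidates: forward finds the true network
  fc_cols <- paste0("fc_", names(network_names()))
  fw7 <- cox_stepwise(ch, fc_cols, direction = "forward")
  expect_true("fc_dan" %in% fw7$selected)
  expect_equal(fw7$trace$term[1], "fc_dan")
  # all-null candidates can legitimately select nothing
  cp0 <- sim_cohort_params(n_subjects = 100,
                           log_hr_per_unit_fc = setNames(rep(0, 7), fc_cols),
                           covariate_spec = list(), seed = 1,
                           censor_rate = 0)
  ch0 <- simulate_cohort(cp0, fc_profiles = matrix(rnorm(700), 100, 7))$cohort
  fw0 <- cox_stepwise(ch0, fc_cols, direction = "forward")
  expect_true(is.null(fw0$result) || length(fw0$selected) <= 7)
})

test_that("forward then backward is stable when thresholds coincide", {
  cp <- sim_cohort_params(n_subjects = 250, censor_rate = 0.1, seed = 31)
  ch <- simulate_cohort(cp)$cohort
  fc_cols <- paste0("fc_", names(network_names()))
  fw <- cox_stepwise(ch, fc_cols, p_enter = 0.05, p_remove = 0.05,
                     direction = "forward")
  expect_true(length(fw$selected) >= 1)   # the planted effect is strong
  bw <- cox_stepwise(ch, fw$selected, p_enter = 0.05, p_remove = 0.05,
                     direction = "backward")
  # backward confirmation retains the dominant forward pick
  expect_true(fw$selected[1] %in% bw$selected)
})

test_that("univariate Cox table mirrors per-covariate fits", {
  cp <- sim_cohort_params(n_subjects = 150, seed = 41)
  ch <- simulate_cohort(cp)$cohort
  uni <- cox_univariate(ch, c("fc_dan", "age"))
  expect_equal(nrow(uni), 2)
  expect_equal(uni$coef[1], cox_fit(ch, "fc_dan")$coef)
})
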