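test_that("product-limit estimate matches the hand-worked example", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$time, c(1, 3))
  expect_equal(km$survival, c(2 / 3, 0))
  expect_equal(km_survival_at(km, c(0.5, 1, 2.5, 10)), c(1, 2 / 3, 2 / 3, 0))
})

test_that("with all subjects censored the curve stays at 1", {
  km <- km_estimate(c(2, 5, 9), c(0, 0, 0))
  expect_equal(nrow(km), 0)
  expect_equal(km_survival_at(km, c(0, 100)), c(1, 1))
})

test_that("without censoring KM equals the empirical survival fraction", {
  set.seed(12)
  for (rep in 1:5) {
    t <- round(rexp(40, 0.1), 1)
    km <- km_estimate(t, rep(1, 40))
    expect_equal(km_survival_at(km, km$time), unname(colMeans(outer(t, km$time, ">"))))
  }
})

test_that("KM agrees with survival::survfit under censoring", {
  skip_if_not_installed("survival")
  set.seed(13)
  t <- round(rexp(60, 0.1), 1)
  e <- rbinom(60, 1, 0.7)
  km <- km_estimate(t, e)
  sf <- summary(survival::survfit(survival::Surv(t, e) ~ 1),
                times = km$time)
  expect_equal(km$survival, sf$surv, tolerance = 1e-12)
  expect_equal(km$n_risk, sf$n.risk)
})

test_that("Gehan statistic matches the hand-evaluated weighted sums", {
  # A events at 1,3,5; B events at 2,4,6; U = 3, Var = 22
  gw <- gehan_wilcoxon(c(1, 3, 5), c(1, 1, 1), c(2, 4, 6), c(1, 1, 1))
  expect_equal(gw$statistic, 9 / 22)
  expect_equal(gw$p, pchisq(9 / 22, 1, lower.tail = FALSE))
})

test_that("identical groups give statistic 0 and p 1", {
  t <- c(3, 6, 9, 12); e <- c(1, 0, 1, 1)
  gw <- gehan_wilcoxon(t, e, t, e)
  expect_equal(gw$statistic, 0)
  expect_equal(gw$p, 1)
  expect_warning(gehan_wilcoxon(c(1, 2), c(0, 0), c(3, 4), c(0, 0)),
                 "no events")
})

test_that("log-rank mode matches survival::survdiff", {
  skip_if_not_installed("survival")
  set.seed(14)
  t <- round(rexp(50, 0.1), 1)
  e <- rbinom(50, 1, 0.8)
  g <- rep(0:1, 25)
  lr <- gehan_wilcoxon(t[g == 1], e[g == 1], t[g == 0], e[g == 0],
                       method = "logrank")
  sd <- survival::survdiff(survival::Surv(t, e) ~ g)
  expect_equal(lr$statistic, unname(sd$chisq), tolerance = 1e-10)
})

test_that("the test statistic is invariant to time rescaling", {
  set.seed(15)
  ta <- rexp(30); ea <- rbinom(30, 1, 0.7)
  tb <- rexp(30, 2); eb <- rbinom(30, 1, 0.7)
  a <- gehan_wilcoxon(ta, ea, tb, eb)
  b <- gehan_wilcoxon(7 * ta, ea, 7 * tb, eb)
  expect_equal(a$statistic, b$statistic)
})

test_that("Gehan p-values are uniform and calibrated under the null", {
  set.seed(16)
  p <- vapply(1:800, function(i) {
    t <- rexp(100, 0.05); c <- rexp(100, 0.03)
    time <- pmin(t, c); event <- as.numeric(t <= c)
    g <- rep(0:1, 50)
    gehan_wilcoxon(time[g == 1], event[g == 1],
                   time[g == 0], event[g == 0])$p
  }, numeric(1))
  rej <- mean(p < 0.05)
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.072)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("Cox estimate maximizes the partial likelihood (grid oracle)", {
  set.seed(17)
  t <- c(1.1, 2.3, 3.7, 4.2, 5.9, 6.4, 7.8, 9.1)
  e <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- rnorm(8)
  fit <- cox_univariate(t, e, x)
  grid <- seq(-5, 5, by = 1e-4)
  ll <- partial_loglik_untied(grid, t, e, x)
  expect_lt(abs(fit$beta - grid[which.max(ll)]), 2e-4)
})

test_that("Cox agrees with survival::coxph for both tie methods", {
  skip_if_not_installed("survival")
  set.seed(18)
  t <- round(rexp(80, 0.1))  # heavy ties
  t[t == 0] <- 1
  e <- rbinom(80, 1, 0.7)
  x <- rnorm(80)
  for (ties in c("efron", "breslow")) {
    mine <- cox_univariate(t, e, x, ties = ties)
    ref <- survival::coxph(survival::Surv(t, e) ~ x, ties = ties)
    expect_equal(mine$beta, unname(coef(ref)), tolerance = 1e-7)
    expect_equal(mine$se, sqrt(unname(vcov(ref)[1, 1])), tolerance = 1e-7)
  }
})

test_that("Cox matches the grid oracle on exhaustive small instances", {
  set.seed(19)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    t <- sort(runif(n))  # untied by construction
    e <- rbinom(n, 1, 0.7)
    if (sum(e) == 0) e[1] <- 1
    x <- rnorm(n)
    fit <- suppressWarnings(cox_univariate(t, e, x))
    if (!fit$converged) next  # separated instances are checked elsewhere
    grid <- seq(-5, 5, by = 1e-3)
    best <- grid[which.max(partial_loglik_untied(grid, t, e, x))]
    if (abs(best) > 4.9) next  # oracle truncated by its own grid
    expect_lt(abs(fit$beta - best), 2e-3)
  }
})

test_that("degenerate Cox inputs are rejected or flagged", {
  expect_error(cox_univariate(1:4, c(1, 1, 0, 1), rep(2, 4)), "constant")
  expect_error(cox_univariate(1:4, rep(0, 4), rnorm(4)), "one event")
  # monotone likelihood: event subject always has the largest covariate
  expect_warning(
    fit <- cox_univariate(c(1, 2, 3, 4), rep(1, 4), c(4, 3, 2, 1)),
    "separation")
  expect_true(fit$separated)
  expect_false(fit$converged)
  expect_equal(abs(fit$beta), 15)
})

test_that("single-dose limiting dilution has its closed-form MLE", {
  out <- limiting_dilution_mle(100, 12, 7)
  expect_equal(out$frequency, -log(1 - 7 / 12) / 100, tolerance = 1e-6)
  expect_true(out$ci_low < out$frequency & out$frequency < out$ci_high)
})

test_that("limiting-dilution MLE matches independent oracles", {
  set.seed(20)
  for (i in 1:10) {
    tab <- simulate_limiting_dilution(ld_sim_spec(rng_seed = i))
    if (sum(tab$n_positive) == 0 ||
        all(tab$n_positive == tab$n_injected)) next
    est <- limiting_dilution_mle(tab$dose, tab$n_injected, tab$n_positive)
    # cloglog-binomial GLM with log-dose offset: intercept = log f
    glm_fit <- glm(cbind(n_positive, n_injected - n_positive) ~ 1 +
                     offset(log(dose)),
                   family = binomial("cloglog"), data = tab,
                   control = list(epsilon = 1e-14, maxit = 200))
    expect_equal(est$frequency, exp(unname(coef(glm_fit))),
                 tolerance = 1e-6)
    # dense grid search on the binomial log-likelihood
    grid <- exp(seq(log(1e-5), log(0.5), length.out = 20001))
    ll <- vapply(grid, ld_loglik_oracle, numeric(1), dose = tab$dose,
                 n_injected = tab$n_injected, n_positive = tab$n_positive)
    expect_lt(abs(est$frequency - grid[which.max(ll)]),
              1e-6 + grid[which.max(ll)] * 1e-3)
  }
})

test_that("limiting-dilution boundaries are handled as stated", {
  all_neg <- limiting_dilution_mle(c(10, 100), c(6, 6), c(0, 0))
  expect_equal(all_neg$frequency, 0)
  expect_true(is.finite(all_neg$ci_high) && all_neg$ci_high > 0)
  expect_equal(all_neg$ci_high, -log(0.05) / (6 * 10 + 6 * 100))

  all_pos <- limiting_dilution_mle(c(10, 100), c(6, 6), c(6, 6))
  expect_equal(all_pos$boundary, "all_positive")
  expect_true(all_pos$ci_low > 0 && all_pos$ci_low < 1)

  expect_error(limiting_dilution_mle(10, 6, 7), "n_injected")
})

test_that("profile-likelihood CI brackets the Wald CI sensibly", {
  tab <- data.frame(dose = c(10, 50, 100, 500), n_injected = rep(6, 4),
                    n_positive = c(1, 3, 5, 6))
  wald <- limiting_dilution_mle(tab$dose, tab$n_injected, tab$n_positive)
  prof <- limiting_dilution_mle(tab$dose, tab$n_injected, tab$n_positive,
                                ci = "profile")
  expect_equal(wald$frequency, prof$frequency)
  expect_true(prof$ci_low < wald$frequency &
                wald$frequency < prof$ci_high)
})
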