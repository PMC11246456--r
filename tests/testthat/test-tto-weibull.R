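test_that("TTO is day-level event minus earliest suspect start, full dates only", {
  config <- test_cohort_config()
  cases <- make_cases(
    demo = dplyr::bind_rows(
      demo_row("1", event_dt = "20200110"),
      demo_row("2", event_dt = "20200104"),
      demo_row("3", event_dt = "20200305"),
      demo_row("4", event_dt = "202003"),     # month precision -> excluded
      demo_row("5", event_dt = "20200301")),
    drug = dplyr::bind_rows(lapply(as.character(1:5), drug_row)),
    ther = dplyr::bind_rows(
      ther_row("1", "20200104"),
      ther_row("2", "20200104"),
      ther_row("3", "20200101"), ther_row("3", "20200301"),
      ther_row("4", "20200101"),
      ther_row("5", "202001")))               # partial start -> excluded
  tto <- compute_tto(cases, config)
  expect_equal(tto$tto_days[tto$primaryid == "1"], 6)
  expect_equal(tto$tto_days[tto$primaryid == "2"], 0)   # same-day onset
  expect_equal(tto$tto_days[tto$primaryid == "3"], 64)  # earliest start
  expect_setequal(tto$primaryid, c("1", "2", "3"))
})

test_that("median and quartiles use linear interpolation", {
  s <- median_iqr(c(1, 2, 3, 4, 5))
  expect_equal(s[c("median", "q1", "q3")], list(median = 3, q1 = 2, q3 = 4))
  expect_equal(median_iqr(c(0, 10))$median, 5)
  expect_error(median_iqr(numeric(0)), "empty")
  # quartiles of a big known sample approach the closed form
  set.seed(8)
  x <- rexp(1000, rate = 1 / 50)
  s2 <- median_iqr(x)
  expect_equal(s2$median, 50 * log(2), tolerance = 0.1)
  expect_equal(s2$q1, -50 * log(0.75), tolerance = 0.15)
})

test_that("Weibull MLE recovers exponential data and honors preconditions", {
  set.seed(123)
  x <- rweibull(5000, shape = 1, scale = 40)
  fit <- fit_weibull_mle(x)
  expect_true(fit$beta_ci[1] <= 1 && 1 <= fit$beta_ci[2])
  expect_equal(fit$beta, 1, tolerance = 0.05)
  expect_equal(fit$alpha, 40, tolerance = 2)
  expect_equal(fit$failure_type, "random")
  expect_error(fit_weibull_mle(c(1, 2, 3)), "at least 10")
  expect_error(fit_weibull_mle(rep(5, 20)), "degenerate")
})

test_that("MLE agrees with a grid-search likelihood oracle", {
  loglik <- function(x, a, b) {
    sum(dweibull(x, shape = b, scale = a, log = TRUE))
  }
  set.seed(55)
  for (i in 1:20) {
    x <- rweibull(80, shape = runif(1, 0.4, 2.5), scale = runif(1, 10, 300))
    fit <- fit_weibull_mle(x)
    grid_b <- seq(fit$beta * 0.5, fit$beta * 1.5, length.out = 401)
    grid_a <- seq(fit$alpha * 0.5, fit$alpha * 1.5, length.out = 401)
    ll <- outer(grid_a, grid_b, Vectorize(function(a, b) loglik(x, a, b)))
    best <- arrayInd(which.max(ll), dim(ll))
    expect_equal(grid_a[best[1]], fit$alpha, tolerance = 2e-3)
    expect_equal(grid_b[best[2]], fit$beta, tolerance = 2e-3)
    expect_gte(loglik(x, fit$alpha, fit$beta), max(ll) - 1e-6)
  }
})

test_that("scale equivariance: k*x multiplies alpha by k, beta unchanged", {
  set.seed(9)
  x <- rweibull(200, shape = 0.7, scale = 90)
  f1 <- fit_weibull_mle(x)
  f2 <- fit_weibull_mle(x * 3)
  expect_equal(f2$alpha, 3 * f1$alpha, tolerance = 1e-6)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-8)
})

test_that("Wald CIs reach near-nominal coverage at n = 200", {
  set.seed(777)
  hits <- replicate(1000, {
    x <- rweibull(200, shape = 0.6, scale = 100)
    fit <- fit_weibull_mle(x)
    fit$beta_ci[1] <= 0.6 && 0.6 <= fit$beta_ci[2]
  })
  expect_gte(mean(hits), 0.90)
})

test_that("zero-day onsets are shifted (or dropped) before fitting", {
  set.seed(4)
  x <- c(rep(0, 15), round(rweibull(150, 0.6, 80)) + 1)
  fit_shift <- fit_weibull_mle(x, zero_policy = "shift")
  expect_equal(fit_shift$n_used, length(x))
  expect_equal(fit_shift$n_zero, 15)
  fit_drop <- fit_weibull_mle(x, zero_policy = "drop")
  expect_equal(fit_drop$n_used, length(x) - 15)
  # medians are computed on raw values regardless
  expect_equal(median_iqr(x)$min, 0)
})

test_that("failure-type classification follows the shape CI rule", {
  expect_equal(classify_failure(0.48, c(0.40, 0.55)), "early")
  expect_equal(classify_failure(1.0, c(0.9, 1.1)), "random")
  expect_equal(classify_failure(1.5, c(1.2, 1.8)), "wear_out")
  expect_equal(classify_failure(0.95, c(0.85, 1.02)), "random")
})

test_that("cross-check against an independent parametric survival fit", {
  skip_if_not_installed("survival")
  set.seed(314)
  x <- rweibull(400, shape = 0.48, scale = 100)
  fit <- fit_weibull_mle(x)
  sr <- survival::survreg(survival::Surv(x) ~ 1, dist = "weibull")
  expect_equal(fit$alpha, unname(exp(coef(sr))), tolerance = 1e-4)
  expect_equal(fit$beta, 1 / sr$scale, tolerance = 1e-4)
})

test_that("pooled priority-group TTO table mirrors the two-band structure", {
  config <- test_cohort_config()
  set.seed(21)
  ids <- as.character(1:80)
  tto_days <- c(round(rweibull(40, 0.6, 30)), round(rweibull(40, 0.8, 150)))
  start <- as.Date("2020-01-01")
  demo <- dplyr::bind_rows(lapply(seq_along(ids), function(i) {
    demo_row(ids[i], event_dt = format(start + tto_days[i], "%Y%m%d"))
  }))
  reac <- reac_row(ids, rep(c("Bradycardia", "Atrial fibrillation"),
                            each = 40))
  cases <- make_cases(demo,
                      drug = dplyr::bind_rows(lapply(ids, drug_row)),
                      reac = reac,
                      ther = dplyr::bind_rows(lapply(ids, ther_row,
                                                     start_dt = "20200101")))
  priorities <- tibble::tibble(
    pt = c("BRADYCARDIA", "ATRIAL FIBRILLATION"),
    level = c("moderate", "weak"))
  out <- tto_group_summary(cases, config, priorities)
  expect_equal(out$group, c("moderate", "weak"))
  expect_equal(out$n_cases, c(40L, 40L))
  expect_equal(out$median[1], median(tto_days[1:40]))
  expect_true(all(out$beta_low < out$beta & out$beta < out$beta_high))
  expect_lt(out$beta[1], 1)
})
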