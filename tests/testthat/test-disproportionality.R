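test_that("contingency tables tally the 2x2 cells and conserve margins", {
  drug <- c(X = 10, Y = 90)
  bg <- c(X = 100, Y = 9900)
  tab <- build_pt_contingency(drug, bg, "X")
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 10, b = 90, c = 100, d = 9900))
  absent <- build_pt_contingency(drug, bg, "Z")
  expect_equal(unlist(absent[c("a", "b", "c", "d")]),
               c(a = 0, b = 100, c = 0, d = 10000))
  # margin conservation across every pt of a random tally
  set.seed(1)
  dt <- stats::setNames(rpois(30, 20) + 1, paste0("PT", 1:30))
  bt <- stats::setNames(rpois(30, 200) + 1, paste0("PT", 1:30))
  for (pt in names(dt)) {
    tb <- build_pt_contingency(dt, bt, pt)
    expect_equal(tb$a + tb$b, sum(dt))
    expect_equal(tb$c + tb$d, sum(bt))
  }
})

test_that("ROR and Wald CI match direct formula evaluation", {
  est <- compute_ror(list(a = 10, b = 90, c = 100, d = 9900))
  expect_equal(est$ror, 11)
  expect_equal(est$ci_low, 5.5595, tolerance = 1e-4)
  expect_equal(est$ci_high, 21.7645, tolerance = 1e-4)
  expect_false(est$corrected)
  expect_equal(compute_ror(list(a = 5, b = 5, c = 5, d = 5))$ror, 1)
})

test_that("zero cells trigger the Haldane-Anscombe correction, empty margins error", {
  est <- compute_ror(list(a = 0, b = 10, c = 10, d = 1000))
  expect_true(est$corrected)
  # corrected table (0.5, 10.5, 10.5, 1000.5)
  expect_equal(est$ror, (0.5 * 1000.5) / (10.5 * 10.5))
  expect_error(compute_ror(list(a = 0, b = 0, c = 5, d = 5)), "undefined")
})

test_that("signal rule needs ci_low strictly above 1 and at least 5 events", {
  est <- tibble::tibble(
    n = c(67L, 4L, 100L, 5L, 5L),
    ci_low = c(16.80, 3.0, 1.0, 1.0000001, 0.99))
  out <- evaluate_signal(est)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("ROR is strictly monotone in the a-cell", {
  base <- list(b = 200, c = 40, d = 8000)
  rors <- sapply(1:30, function(a) {
    est <- compute_ror(c(list(a = a), base))
    c(est$ror, est$ci_low)
  })
  expect_true(all(diff(rors[1, ]) > 0))
  expect_true(all(diff(rors[2, ]) > 0))
})

test_that("SOC screen flags the injected signal, pools the a-cell, sorts by ci_low", {
  drug <- c(SIG = 60, NULL1 = 30, NULL2 = 30, OTHER = 880)
  bg <- c(SIG = 60, NULL1 = 300, NULL2 = 300, OTHER = 9340)
  map <- data.frame(pt = c("SIG", "NULL1", "NULL2", "OTHER"),
                    soc_code = c("111", "111", "111", "222"))
  res <- screen_soc(drug, bg, map, "111")
  expect_equal(nrow(res$pt_signals), 3)
  expect_equal(res$pt_signals$significant[res$pt_signals$pt == "SIG"], TRUE)
  expect_false(any(res$pt_signals$significant[res$pt_signals$pt != "SIG"]))
  expect_equal(res$pt_signals$ci_low, sort(res$pt_signals$ci_low,
                                           decreasing = TRUE))
  expect_equal(res$soc_signal$n, 60 + 30 + 30)
  expect_equal(nrow(screen_soc(drug, bg, map, "999")$pt_signals), 0)
})

test_that("synthetic generator's configured RORs are recovered through the pipeline", {
  sim <- big_sim_tallies()
  targets <- sim$truth$expected_ror
  for (pt in names(targets)) {
    est <- compute_ror(build_pt_contingency(sim$drug_tally,
                                            sim$background_tally, pt))
    se <- (log(est$ci_high) - log(est$ci_low)) / (2 * 1.96)
    # every injected signal within 3.3 SE of its target
    expect_lt(abs(log(est$ror / targets[[pt]])), 3.3 * se)
  }
  # the high-count signals at the stated +/-10%
  for (pt in c("BRADYCARDIA", "CARDIAC ARREST", "ATRIAL FIBRILLATION")) {
    est <- compute_ror(build_pt_contingency(sim$drug_tally,
                                            sim$background_tally, pt))
    expect_lt(abs(log(est$ror / targets[[pt]])), log(1.10))
  }
})

test_that("stratified screen isolates a stratum-specific signal", {
  set.seed(7)
  n <- 1200
  mkdemo <- function(ids, sex) {
    dplyr::bind_rows(lapply(seq_along(ids), function(i) {
      demo_row(ids[i], sex = sex[i])
    }))
  }
  ids_d <- paste0("d", 1:n)
  ids_b <- paste0("b", 1:(4 * n))
  sex_d <- rep(c("F", "M"), length.out = n)
  sex_b <- rep(c("F", "M"), length.out = 4 * n)
  # strong signal among female drug cases, background-level among males
  pt_d <- ifelse(runif(n) < ifelse(sex_d == "F", 0.30, 0.05),
                 "Bradycardia", "Nausea")
  pt_b <- ifelse(runif(4 * n) < 0.05, "Bradycardia", "Nausea")
  drug_cases <- make_cases(mkdemo(ids_d, sex_d),
                           reac = reac_row(ids_d, pt_d))
  bg_cases <- make_cases(mkdemo(ids_b, sex_b),
                         reac = reac_row(ids_b, pt_b))
  config <- test_cohort_config()
  out <- stratified_screen(drug_cases, bg_cases, config, strata = "sex")
  f <- out[out$level == "F", ]
  m <- out[out$level == "M", ]
  expect_gt(f$ror, m$ror)
  expect_true(f$significant)
  # case counts: n + nl partition each stratum's drug cases
  expect_equal(f$n + f$nl, n / 2)
  # no missingness here: stratum a-cells add to the pooled a-cell
  dt <- pt_event_tally(drug_cases)
  expect_equal(sum(out$a), unname(dt["BRADYCARDIA"]))
})
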