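test_that("deduplication keeps the latest fda_dt, then the higher primaryid", {
  demo <- dplyr::bind_rows(
    demo_row("11", caseid = "X", fda_dt = "20200101"),
    demo_row("12", caseid = "X", fda_dt = "20210101"),
    demo_row("1001", caseid = "Y", fda_dt = "20200601"),
    demo_row("1002", caseid = "Y", fda_dt = "20200601"))
  out <- deduplicate_cases(make_cases(demo))
  expect_setequal(out$demo$primaryid, c("12", "1002"))
  # ordered by caseid, deterministic
  expect_equal(out$demo$caseid, c("X", "Y"))
})

test_that("deduplication matches a brute-force group-by oracle and is idempotent", {
  set.seed(42)
  n_case <- 50
  demo <- dplyr::bind_rows(lapply(seq_len(n_case), function(i) {
    k <- sample(1:3, 1)
    demo_row(primaryid = as.character(i * 10 + seq_len(k)),
             caseid = sprintf("C%03d", i),
             fda_dt = format(as.Date("2019-01-01") +
                               sample(0:1000, k), "%Y%m%d"))
  }))
  demo <- demo[sample(nrow(demo)), ]
  cases <- make_cases(demo)
  out <- deduplicate_cases(cases)
  # oracle: exhaustive split-apply with explicit max rules
  oracle <- vapply(split(demo, demo$caseid), function(g) {
    g <- g[g$fda_dt == max(g$fda_dt), , drop = FALSE]
    g$primaryid[which.max(as.numeric(g$primaryid))]
  }, character(1))
  expect_setequal(out$demo$primaryid, unname(oracle))
  expect_equal(nrow(out$demo), n_case)
  expect_equal(deduplicate_cases(out)$demo, out$demo)
  # order independence
  cases2 <- make_cases(demo[sample(nrow(demo)), ])
  expect_equal(deduplicate_cases(cases2)$demo, out$demo)
})

test_that("dedup on synthetic data with injected duplicates recovers the truth", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_background_cases = 4000, n_drug_cases = 1000,
                          duplicate_rate = 0.3, n_quarters = 8, seed = 99)
  sim <- simulate_faers(cfg, dir)
  expect_gt(sim$truth$n_duplicates, 1000)
  cases <- suppressMessages(assemble_cases(
    suppressWarnings(read_faers_tables(dir))))
  expect_equal(n_cases(cases), 5000 + sim$truth$n_duplicates)
  out <- deduplicate_cases(cases)
  expect_setequal(out$demo$primaryid, sim$truth$case_primaryids)

  # duplicate_rate = 0 makes dedup a no-op
  dir0 <- withr::local_tempdir()
  cfg0 <- synthetic_config(n_background_cases = 300, n_drug_cases = 100,
                           duplicate_rate = 0, n_quarters = 4, seed = 5)
  simulate_faers(cfg0, dir0)
  cases0 <- suppressMessages(assemble_cases(
    suppressWarnings(read_faers_tables(dir0))))
  expect_equal(deduplicate_cases(cases0)$demo$primaryid,
               sort(cases0$demo$primaryid))
})

test_that("suspect-drug selection matches names as substrings and filters role", {
  config <- test_cohort_config()
  cases <- make_cases(
    demo = dplyr::bind_rows(lapply(as.character(1:4), demo_row)),
    drug = dplyr::bind_rows(
      drug_row("1", drugname = "VIMPAT", role_cod = "PS"),
      drug_row("2", drugname = "OTHERDRUG", prod_ai = "LACOSAMIDE",
               role_cod = "C"),
      drug_row("3", drugname = "lacosamide 50mg tab", prod_ai = "",
               role_cod = "PS"),
      drug_row("4", drugname = "ASPIRIN", prod_ai = "", role_cod = "PS")))
  sel <- select_drug_cases(cases, config)
  expect_setequal(sel$demo$primaryid, c("1", "3"))
  expect_lte(n_cases(sel), n_cases(cases))
  # background excludes the drug in any role (case 2 is role C)
  bg <- select_background_cases(cases, config)
  expect_setequal(bg$demo$primaryid, "4")
})

test_that("exclusions remove PT classes and date-error cases only", {
  config <- test_cohort_config()
  cases <- make_cases(
    demo = dplyr::bind_rows(
      demo_row("1", event_dt = ""),
      demo_row("2", event_dt = "20200101"),   # before start -> dropped
      demo_row("3", event_dt = "20200401"),
      demo_row("4", event_dt = "")),
    drug = dplyr::bind_rows(lapply(as.character(1:4), drug_row)),
    reac = dplyr::bind_rows(
      reac_row("1", "Off label use"), reac_row("1", "Bradycardia"),
      reac_row("2", "Bradycardia"),
      reac_row("3", "Bradycardia"),
      reac_row("4", "Off label use")),        # fully excluded -> dropped
    ther = dplyr::bind_rows(
      ther_row("2", "20200301"), ther_row("3", "20200301")))
  out <- suppressMessages(apply_exclusions(cases, config))
  expect_setequal(out$demo$primaryid, c("1", "3"))
  # excluded PT removed but case 1 kept through its other PT
  expect_equal(out$reac$pt[out$reac$primaryid == "1"], "Bradycardia")
  counts <- attr(out, "exclusion_counts")
  expect_equal(unname(counts["date_errors"]), 1)
  expect_equal(unname(counts["emptied_cases"]), 1)
})

test_that("SOC restriction keeps mapped cases and double-counts PT-level events", {
  config <- test_cohort_config()
  cases <- make_cases(
    demo = dplyr::bind_rows(lapply(as.character(1:3), demo_row)),
    reac = dplyr::bind_rows(
      reac_row("1", "Bradycardia"), reac_row("1", "Nausea"),
      reac_row("2", "Bradycardia"), reac_row("2", "Sinus arrest"),
      reac_row("2", "Cardiac arrest"),
      reac_row("3", "Nausea")))
  res <- restrict_to_soc(cases, config)
  expect_setequal(res$cases$demo$primaryid, c("1", "2"))
  expect_equal(res$n_pt_events, 4)  # 1 + 3, case 2 double-counted
  expect_equal(res$n_cases, 2)

  # unmapped PT excluded from the tally with a warning
  cases2 <- make_cases(demo = demo_row("9"),
                       reac = reac_row("9", "Mystery unmapped term"))
  expect_warning(res2 <- restrict_to_soc(cases2, config), "unmapped")
  expect_equal(res2$n_cases, 0)
})

test_that("age and weight unit conversions follow the fixed table", {
  expect_equal(age_to_years(c(2, 24, 3, 21, 730.5, 8766),
                            c("DEC", "MON", "YR", "WK", "DY", "HR")),
               c(20, 2, 3, 21 / 52.18, 2, 1))
  expect_warning(bad <- age_to_years(5, "LIGHTYEARS"), "unrecognized")
  expect_true(is.na(bad))
  expect_equal(weight_to_kg(c(70, 100), c("KG", "LBS")), c(70, 45.36))
})

test_that("cohort summary bands, medians and available-denominators are correct", {
  demo <- dplyr::bind_rows(
    demo_row("1", age = "10", sex = "F"),
    demo_row("2", age = "30", sex = "M"),
    demo_row("3", age = "70", sex = "F"),
    demo_row("4", age = "24", age_cod = "MON", sex = ""))
  summ <- summarize_cohort(make_cases(demo))
  ageb <- dplyr::filter(summ$categorical, variable == "age_band")
  expect_equal(sum(ageb$n), unique(ageb$available_n))
  expect_equal(ageb$n[match(c("<18", "18-64", ">64"), ageb$level)],
               c(2L, 1L, 1L))  # 24 months = 2 years -> <18
  cont <- dplyr::filter(summ$continuous, variable == "age_years")
  expect_equal(cont$median, median(c(10, 30, 70, 2)))
  sexr <- dplyr::filter(summ$categorical, variable == "sex")
  expect_equal(unique(sexr$available_n), 3L)
  expect_equal(sum(sexr$pct), 100)
})
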