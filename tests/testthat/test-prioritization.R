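calibration <- readr::read_csv(
  faersignal_extdata("calibration_signals.csv"), show_col_types = FALSE,
  na = character())  # "NA" is a literal importance level, not missing

test_that("importance classification gives DME precedence over IME", {
  ime <- readLines(faersignal_extdata("ime_pts.txt"))
  dme <- readLines(faersignal_extdata("dme_pts.txt"))
  expect_equal(classify_importance("Ventricular fibrillation", ime, dme),
               "DME")  # on both lists: DME wins
  expect_equal(classify_importance("Cardio-respiratory arrest", ime, dme),
               "NA")
  expect_equal(classify_importance("Bradycardia", ime, dme), "IME")
  expect_warning(out <- classify_importance("Bradycardia",
                                            character(), character()),
                 "empty")
  expect_equal(out, "NA")
})

test_that("priority bands partition scores 0..10 as weak/moderate/strong", {
  expect_equal(priority_level(0:10),
               c(rep("weak", 5), rep("moderate", 3), rep("strong", 3)))
})

test_that("rubric scoring reproduces reference signals and rejects bad rubrics", {
  rubric <- default_rubric()
  avb <- score_signal(list(n_cases = 67, ror025 = 16.80, n_deaths = 8,
                           importance = "IME", evidence = "++"), rubric)
  expect_equal(avb$score, 7L)
  expect_equal(avb$level, "moderate")
  af <- score_signal(list(n_cases = 67, ror025 = 1.21, n_deaths = 2,
                          importance = "IME", evidence = "+"), rubric)
  expect_equal(af$score, 4L)
  expect_equal(af$level, "weak")
  floor <- score_signal(list(n_cases = 1, ror025 = 1.01, n_deaths = 0,
                             importance = "NA", evidence = "+"), rubric)
  expect_equal(floor$score, 1L)  # evidence contributes its minimum point
  expect_equal(floor$level, "weak")
  expect_error(score_signal(list(n_cases = 10, ror025 = 2, n_deaths = 0,
                                 importance = "IME", evidence = "+++"),
                            rubric), "evidence")
  # rubric whose maxima do not sum to 10 is rejected at load
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_cases: {thresholds: [10], points: [0, 5]}",
               "ror025: {thresholds: [2], points: [0, 2]}",
               "mortality: {thresholds: [0.5], points: [0, 2]}",
               "importance: {'NA': 0, IME: 1, DME: 2}",
               "evidence: {'+': 1, '++': 2}"), bad)
  expect_error(read_rubric(bad), "sum to 10")
})

test_that("scoring is monotone in every feature", {
  rubric <- default_rubric()
  base <- list(n_cases = 30, ror025 = 3, n_deaths = 3,
               importance = "IME", evidence = "+")
  s0 <- score_signal(base, rubric)$score
  bumps <- list(
    list(n_cases = 60, ror025 = 3, n_deaths = 3, importance = "IME",
         evidence = "+"),
    list(n_cases = 30, ror025 = 8, n_deaths = 3, importance = "IME",
         evidence = "+"),
    list(n_cases = 30, ror025 = 3, n_deaths = 20, importance = "IME",
         evidence = "+"),
    list(n_cases = 30, ror025 = 3, n_deaths = 3, importance = "DME",
         evidence = "+"),
    list(n_cases = 30, ror025 = 3, n_deaths = 3, importance = "IME",
         evidence = "++"))
  for (b in bumps) expect_gte(score_signal(b, rubric)$score, s0)
})

test_that("default rubric reproduces the published weak/moderate split", {
  rubric <- default_rubric()
  scored <- purrr::pmap(calibration, function(pt, n, ror025, n_deaths,
                                              importance, evidence, ...) {
    score_signal(list(n_cases = n, ror025 = ror025, n_deaths = n_deaths,
                      importance = importance, evidence = evidence), rubric)
  })
  levels <- purrr::map_chr(scored, "level")
  expect_equal(levels, calibration$published_level)
  expect_equal(sum(levels == "moderate"), 13L)
  expect_equal(sum(levels == "weak"), 4L)
  # exact scores match for all but the one internally inconsistent row
  scores <- purrr::map_int(scored, "score")
  mismatch <- calibration$pt[scores != calibration$published_score]
  expect_equal(mismatch, "ATRIOVENTRICULAR BLOCK SECOND DEGREE")
})

test_that("prioritize_screen derives deaths per distinct case and flags novelty", {
  ids <- as.character(1:40)
  demo <- dplyr::bind_rows(lapply(ids, demo_row))
  reac <- dplyr::bind_rows(reac_row(ids[1:30], "Bradycardia"),
                           reac_row(ids[11:25], "Sinus arrest"))
  # case 1 has a duplicated DE row: must count once
  outc <- dplyr::bind_rows(outc_row(ids[1:5], "DE"), outc_row(ids[1], "DE"),
                           outc_row(ids[6:8], "HO"))
  cases <- make_cases(demo, reac = reac, outc = outc)
  signals <- tibble::tibble(pt = c("Bradycardia", "Sinus arrest"),
                            n = c(30L, 15L), ci_low = c(4.0, 9.0))
  out <- prioritize_screen(
    signals, cases,
    ime_list = readLines(faersignal_extdata("ime_pts.txt")),
    dme_list = readLines(faersignal_extdata("dme_pts.txt")),
    label_pts = readLines(faersignal_extdata("label_pts.txt")))
  expect_equal(nrow(out), 2L)
  expect_equal(out$n, c(30L, 15L))  # sorted by descending n
  # oracle: brute-force scan over cases for death counts
  brady_deaths <- length(unique(
    intersect(ids[1:30], unique(outc$primaryid[outc$outc_cod == "DE"]))))
  expect_equal(out$n_deaths[out$pt == "BRADYCARDIA"], brady_deaths)
  expect_false(out$novel[out$pt == "BRADYCARDIA"])
  expect_true(out$novel[out$pt == "SINUS ARREST"])
})
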