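#' Classify a PT against IME/DME reference lists
#'
#' The EMA maintains Important Medical Events (IME) and Designated
#' Medical Events (DME) lists of inherently serious conditions; here they
#' are supplied as plain-text fixtures (miniature synthetic subsets ship
#' with the package). DME takes precedence over IME; a PT on neither list
#' is `"NA"`.
#'
#' @param pt character vector of Preferred Terms.
#' @param ime_list,dme_list character vectors of reference PTs.
#' @return character vector in `c("DME", "IME", "NA")`.
#' @export
classify_importance <- function(pt, ime_list, dme_list) {
  if (length(ime_list) == 0 && length(dme_list) == 0) {
    warning("empty IME and DME lists: all PTs classified NA")
  }
  key <- norm_text(pt)
  ifelse(key %in% norm_text(dme_list), "DME",
         ifelse(key %in% norm_text(ime_list), "IME", "NA"))
}

#' Default clinical-priority rubric
#'
#' The five-feature semi-quantitative rubric: event count, lower ROR CI
#' bound, mortality proportion, IME/DME importance, and literature
#' evidence grade, each contributing 0--2 points (maximum total 10; 0--4
#' weak, 5--7 moderate, 8--10 strong). The shipped thresholds are a
#' calibrated reconstruction (see the methods vignette), not an official
#' scale: counts score 1 point at >= 10 events and 2 at >= 50; ROR025
#' scores 1 at >= 2 and 2 at >= 5; mortality scores 1 at >= 25% and 2 at
#' >= 50%; IME scores 1 and DME 2; evidence `+` scores 1 and `++` 2.
#'
#' @return a `priority_rubric` list.
#' @export
default_rubric <- function() {
  read_rubric(system.file("extdata", "rubric.yaml", package = "faersignal"))
}

#' Read a clinical-priority rubric from YAML
#'
#' The file defines, per graded feature, ascending `thresholds` and the
#' `points` awarded below the first / between / at-or-above the last
#' threshold, plus categorical point maps for `importance` and
#' `evidence`. Per-feature maxima must sum to 10.
#'
#' @param path YAML rubric path.
#' @return a `priority_rubric` list.
#' @export
read_rubric <- function(path) {
  raw <- yaml::read_yaml(path)
  needed <- c("n_cases", "ror025", "mortality", "importance", "evidence")
  if (!all(needed %in% names(raw))) {
    stop("rubric must define features: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  for (f in c("n_cases", "ror025", "mortality")) {
    th <- raw[[f]]$thresholds
    pts <- raw[[f]]$points
    if (length(pts) != length(th) + 1 || is.unsorted(th) ||
        any(pts < 0) || is.unsorted(pts)) {
      stop("rubric feature ", f, ": points must be nondecreasing, ",
           "nonnegative, one more than thresholds", call. = FALSE)
    }
  }
  maxima <- c(
    max(raw$n_cases$points), max(raw$ror025$points),
    max(raw$mortality$points),
    max(unlist(raw$importance)), max(unlist(raw$evidence))
  )
  if (sum(maxima) != 10) {
    stop("per-feature maxima must sum to 10 (got ", sum(maxima), ")",
         call. = FALSE)
  }
  structure(raw, class = "priority_rubric")
}

step_points <- function(value, feature) {
  idx <- findInterval(value, feature$thresholds) + 1L
  feature$points[idx]
}

#' Score one signal with the priority rubric
#'
#' @param features list or one-row data frame with `n_cases`, `ror025`,
#'   `n_deaths`, `importance` (`"DME"`, `"IME"` or `"NA"`), and
#'   `evidence` (`"+"` or `"++"`).
#' @param rubric a `priority_rubric` (default [default_rubric()]).
#' @return list with integer `score` (0--10) and `level`
#'   (`"weak"`/`"moderate"`/`"strong"`).
#' @export
score_signal <- function(features, rubric = default_rubric()) {
  f <- as.list(features)
  stopifnot(f$n_deaths <= f$n_cases, f$n_cases >= 1)
  imp <- rubric$importance[[as.character(f$importance)]]
  ev <- rubric$evidence[[as.character(f$evidence)]]
  if (is.null(imp)) stop("importance level outside rubric domain: ",
                         f$importance, call. = FALSE)
  if (is.null(ev)) stop("evidence grade outside rubric domain: ",
                        f$evidence, call. = FALSE)
  score <- step_points(f$n_cases, rubric$n_cases) +
    step_points(f$ror025, rubric$ror025) +
    step_points(f$n_deaths / f$n_cases, rubric$mortality) +
    imp + ev
  list(score = as.integer(score), level = priority_level(score))
}

#' Map a priority score to its band
#' @param score integer 0--10.
#' @return `"weak"` (0--4), `"moderate"` (5--7) or `"strong"` (8--10).
#' @export
priority_level <- function(score) {
  ifelse(score <= 4, "weak", ifelse(score <= 7, "moderate", "strong"))
}

#' Prioritize significant disproportionality signals
#'
#' Derives the five rubric features for each significant signal and
#' scores it: death counts are distinct cases with outcome code DE
#' mentioning the PT (never double-counted across duplicate DE rows),
#' importance from the IME/DME lists, evidence from the supplied
#' annotation (a literature-review input, `"+"` by default). Signals
#' whose PT is absent from the drug-label list are flagged novel.
#'
#' @param signals tibble of significant estimates (columns `pt`, `n`,
#'   `ci_low`, as from [screen_soc()], already filtered to
#'   `significant`).
#' @param cases the `faers_cases` cohort the signals came from.
#' @param rubric a `priority_rubric`.
#' @param ime_list,dme_list reference PT vectors.
#' @param label_pts PTs already on the drug label (novelty reference).
#' @param evidence named character vector of `"+"`/`"++"` grades keyed by
#'   PT; unannotated PTs default to `"+"`.
#' @return tibble sorted by descending `n`: `pt`, `n`, `ror025`,
#'   `n_deaths`, `importance`, `evidence`, `score`, `level`, `novel`.
#' @export
prioritize_screen <- function(signals, cases, rubric = default_rubric(),
                              ime_list = character(),
                              dme_list = character(),
                              label_pts = character(),
                              evidence = character()) {
  evidence <- stats::setNames(as.character(evidence),
                              norm_text(names(evidence)))
  if (nrow(signals) == 0) {
    return(tibble(pt = character(), n = integer(), ror025 = numeric(),
                  n_deaths = integer(), importance = character(),
                  evidence = character(), score = integer(),
                  level = character(), novel = logical()))
  }
  death_ids <- unique(cases$outc$primaryid[cases$outc$outc_cod == "DE"])
  reac <- distinct(cases$reac, .data$primaryid, pt = norm_text(.data$pt))
  deaths_per_pt <- reac %>%
    filter(.data$primaryid %in% death_ids) %>%
    count(.data$pt)
  out <- signals %>%
    mutate(pt = norm_text(.data$pt), ror025 = .data$ci_low) %>%
    left_join(rename(deaths_per_pt, n_deaths = "n"), by = "pt") %>%
    mutate(
      n_deaths = ifelse(is.na(.data$n_deaths), 0L, .data$n_deaths),
      importance = classify_importance(.data$pt, ime_list, dme_list),
      evidence = dplyr::coalesce(unname(evidence[.data$pt]), "+"),
      novel = !.data$pt %in% norm_text(label_pts)
    )
  scored <- purrr::pmap(
    select(out, "pt", n_cases = "n", "ror025", "n_deaths", "importance",
           "evidence"),
    function(pt, n_cases, ror025, n_deaths, importance, evidence) {
      score_signal(list(n_cases = n_cases, ror025 = ror025,
                        n_deaths = n_deaths, importance = importance,
                        evidence = evidence), rubric)
    })
  out %>%
    mutate(score = purrr::map_int(scored, "score"),
           level = purrr::map_chr(scored, "level")) %>%
    select("pt", "n", "ror025", "n_deaths", "importance", "evidence",
           "score", "level", "novel") %>%
    arrange(desc(.data$n))
}
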