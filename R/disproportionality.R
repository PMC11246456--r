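#' PT-level event tally
#'
#' Counts distinct (case, PT) pairs per Preferred Term: the event-level
#' counting convention of spontaneous-report disproportionality, in which
#' a case reporting several PTs contributes one count to each.
#'
#' @param cases a `faers_cases` object.
#' @return named integer vector of event counts keyed by normalized PT.
#' @export
pt_event_tally <- function(cases) {
  reac <- distinct(cases$reac, .data$primaryid, pt = norm_text(.data$pt))
  tab <- table(reac$pt)
  stats::setNames(as.integer(tab), names(tab))
}

#' Build the drug-by-event 2x2 contingency table for one PT
#'
#' Cell layout: `a` = target-PT events for the target drug, `b` = all
#' other-PT events for the target drug, `c` = target-PT events for all
#' other drugs, `d` = all other-PT events for all other drugs.
#'
#' @param drug_events named event tally for the target drug (see
#'   [pt_event_tally()]).
#' @param background_events named event tally for all other drugs.
#' @param pt Preferred Term (matched after case/whitespace normalization).
#' @return a `faers_2x2` list with fields `pt`, `a`, `b`, `c`, `d`.
#' @export
build_pt_contingency <- function(drug_events, background_events, pt) {
  key <- norm_text(pt)
  a <- unname(drug_events[key]);  a <- ifelse(is.na(a), 0, a)
  c_ <- unname(background_events[key]); c_ <- ifelse(is.na(c_), 0, c_)
  structure(list(pt = key, a = as.numeric(a),
                 b = as.numeric(sum(drug_events) - a),
                 c = as.numeric(c_),
                 d = as.numeric(sum(background_events) - c_)),
            class = "faers_2x2")
}

#' Reporting odds ratio with Wald 95% confidence interval
#'
#' ROR = (a d)/(b c); the interval is the log-scale normal (Wald)
#' approximation `exp(log ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`, the
#' standard convention for spontaneous-report screens. When any cell is
#' zero the Haldane--Anscombe correction (0.5 added to every cell) is
#' applied and flagged in the `corrected` column.
#'
#' @param table a `faers_2x2` (or any list with fields `a`, `b`, `c`,
#'   `d`, optionally `pt`).
#' @return one-row tibble: `pt`, `n` (the uncorrected a-cell), `ror`,
#'   `ci_low`, `ci_high`, `corrected`.
#' @export
compute_ror <- function(table) {
  a <- table$a; b <- table$b; cc <- table$c; d <- table$d
  if (any(c(a, b, cc, d) < 0)) stop("negative cell count", call. = FALSE)
  if (a + b == 0 || cc + d == 0) {
    stop("ROR undefined: empty drug or background margin", call. = FALSE)
  }
  corrected <- any(c(a, b, cc, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  ror <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  tibble(
    pt = table$pt %||% NA_character_,
    n = as.integer(table$a),
    ror = ror,
    ci_low = exp(log(ror) - 1.96 * se),
    ci_high = exp(log(ror) + 1.96 * se),
    corrected = corrected
  )
}

#' Apply the disproportionality signal rule
#'
#' A PT is a significant signal when the lower 95% CI bound of its ROR
#' exceeds 1 (strictly) AND at least 5 events were reported.
#'
#' @param est tibble of ROR estimates with columns `n` and `ci_low` (as
#'   from [compute_ror()]).
#' @return `est` with a logical `significant` column set.
#' @export
evaluate_signal <- function(est) {
  mutate(est, significant = .data$ci_low > 1 & .data$n >= 5)
}

#' Screen every PT of a System Organ Class
#'
#' Computes one ROR estimate per SOC-member PT observed in either tally,
#' sorted by descending lower CI bound, plus one pooled SOC-level
#' estimate whose a-cell sums all member-PT events.
#'
#' @param drug_events,background_events event tallies ([pt_event_tally()]).
#' @param pt_to_soc data frame mapping `pt` to `soc_code`.
#' @param soc_code the target SOC code.
#' @return list with `pt_signals` (tibble, one row per PT, with
#'   `significant` flags) and `soc_signal` (one-row tibble).
#' @export
screen_soc <- function(drug_events, background_events, pt_to_soc, soc_code) {
  pt_to_soc <- as_tibble(pt_to_soc)
  pt_to_soc$pt <- norm_text(pt_to_soc$pt)
  members <- pt_to_soc$pt[as.character(pt_to_soc$soc_code) ==
                            as.character(soc_code)]
  seen <- union(names(drug_events), names(background_events))
  members <- intersect(members, seen)
  if (length(members) == 0) {
    empty <- evaluate_signal(compute_ror(
      list(pt = NA_character_, a = 0, b = 1, c = 0, d = 1)))[0, ]
    return(list(pt_signals = empty, soc_signal = empty))
  }
  pt_signals <- bind_rows(lapply(members, function(pt) {
    compute_ror(build_pt_contingency(drug_events, background_events, pt))
  })) %>%
    evaluate_signal() %>%
    arrange(desc(.data$ci_low))
  a <- sum(drug_events[intersect(members, names(drug_events))])
  cc <- sum(background_events[intersect(members, names(background_events))])
  soc_signal <- compute_ror(list(
    pt = paste0("SOC:", soc_code), a = a, b = sum(drug_events) - a,
    c = cc, d = sum(background_events) - cc)) %>%
    evaluate_signal()
  list(pt_signals = pt_signals, soc_signal = soc_signal)
}

# Stratum labels derived from the demographic table.
stratum_values <- function(demo, variable) {
  switch(variable,
    sex = ifelse(demo$sex %in% c("F", "M"), demo$sex, NA_character_),
    age_band = band_age(age_to_years(demo$age, demo$age_cod)),
    weight_band = band_weight(weight_to_kg(demo$wt, demo$wt_cod)),
    reporter_class = ifelse(demo$reporter_class %in%
                              c("professional", "consumer"),
                            demo$reporter_class, NA_character_),
    stop("unknown stratum variable: ", variable, call. = FALSE)
  )
}

#' Stratified SOC-level disproportionality screen
#'
#' Recomputes the SOC-level 2x2 within subgroups defined by sex, age
#' band, weight band and/or reporter class. Within each stratum the drug
#' and background event tallies are rebuilt from that stratum's cases
#' (cases missing the stratum variable are excluded from it). Alongside
#' the ROR, the case-level counts `n` (drug cases in the stratum with at
#' least one target-SOC PT) and `nl` (without) are reported.
#'
#' @param cases suspect-drug cohort (`faers_cases`, post-exclusion).
#' @param background_cases background `faers_cases`.
#' @param config a [cohort_config()].
#' @param strata character vector among `"sex"`, `"age_band"`,
#'   `"weight_band"`, `"reporter_class"`.
#' @return tibble with one row per (variable, level): `n`, `nl`, the 2x2
#'   cells, `ror`, `ci_low`, `ci_high`, `significant`, and an `error`
#'   message column for strata with zero drug events.
#' @export
stratified_screen <- function(cases, background_cases, config,
                              strata = c("sex", "age_band", "weight_band",
                                         "reporter_class")) {
  soc_pts <- config$pt_to_soc$pt[config$pt_to_soc$soc_code ==
                                   config$target_soc_code]
  rows <- list()
  for (variable in strata) {
    sv_drug <- stratum_values(cases$demo, variable)
    sv_bg <- stratum_values(background_cases$demo, variable)
    for (level in sort(unique(stats::na.omit(c(sv_drug, sv_bg))))) {
      dsub <- filter_cases(cases, cases$demo$primaryid[
        !is.na(sv_drug) & sv_drug == level])
      bsub <- filter_cases(background_cases, background_cases$demo$primaryid[
        !is.na(sv_bg) & sv_bg == level])
      dt <- pt_event_tally(dsub)
      bt <- pt_event_tally(bsub)
      soc_case_ids <- unique(dsub$reac$primaryid[
        norm_text(dsub$reac$pt) %in% soc_pts])
      a <- sum(dt[intersect(soc_pts, names(dt))])
      cc <- sum(bt[intersect(soc_pts, names(bt))])
      base <- tibble(variable = variable, level = level,
                     n = length(soc_case_ids),
                     nl = n_cases(dsub) - length(soc_case_ids),
                     a = a, b = sum(dt) - a, c = cc, d = sum(bt) - cc)
      if (sum(dt) == 0 || sum(bt) == 0 || a == 0) {
        rows[[length(rows) + 1]] <- mutate(
          base, ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          significant = NA, error = "no drug events in stratum")
        next
      }
      est <- evaluate_signal(compute_ror(list(
        pt = level, a = a, b = base$b, c = cc, d = base$d)))
      rows[[length(rows) + 1]] <- mutate(
        base, ror = est$ror, ci_low = est$ci_low, ci_high = est$ci_high,
        significant = est$significant, error = NA_character_)
    }
  }
  bind_rows(rows)
}
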