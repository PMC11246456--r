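#' Cohort configuration
#'
#' Bundles everything needed to carve a suspect-drug / target-SOC cohort
#' out of assembled FAERS cases: the drug name lists, the suspect role
#' filter, the PT exclusion classes, and the PT-to-SOC map.
#'
#' @param generic_names character vector of active-ingredient names,
#'   matched case-insensitively as substrings of `drugname` and `prod_ai`.
#' @param trade_names character vector of product names, matched in
#'   `drugname` only.
#' @param required_role FAERS role code the matching drug row must carry
#'   (default `"PS"`, primary suspect).
#' @param excluded_pts named list of character vectors: PT exclusion
#'   classes (e.g. off-label use, product issues, medication errors,
#'   indication-disease terms).
#' @param target_soc_code MedDRA System Organ Class numeric code defining
#'   the event cohort (cardiac disorders is 10007541).
#' @param pt_to_soc data frame with columns `pt` and `soc_code` mapping
#'   Preferred Terms to SOC codes.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(generic_names, trade_names,
                          required_role = "PS",
                          excluded_pts = list(),
                          target_soc_code,
                          pt_to_soc) {
  stopifnot(length(generic_names) > 0, length(trade_names) > 0)
  pt_to_soc <- as_tibble(pt_to_soc)
  if (!all(c("pt", "soc_code") %in% names(pt_to_soc))) {
    stop("pt_to_soc needs columns pt and soc_code", call. = FALSE)
  }
  pt_to_soc$pt <- norm_text(pt_to_soc$pt)
  pt_to_soc$soc_code <- as.character(pt_to_soc$soc_code)
  target_soc_code <- as.character(target_soc_code)
  if (!target_soc_code %in% pt_to_soc$soc_code) {
    stop("target_soc_code ", target_soc_code,
         " absent from pt_to_soc map", call. = FALSE)
  }
  structure(list(
    generic_names = norm_text(generic_names),
    trade_names = norm_text(trade_names),
    required_role = toupper(required_role),
    excluded_pts = lapply(excluded_pts, norm_text),
    target_soc_code = target_soc_code,
    pt_to_soc = pt_to_soc
  ), class = "cohort_config")
}

#' Read a cohort configuration from YAML
#'
#' Expects keys `generic_names`, `trade_names`, optional `required_role`,
#' `excluded_pts` (a map of class name to PT list or to a text-file path),
#' `target_soc_code`, and `pt_to_soc` (path to a two-column `pt,soc_code`
#' CSV). Relative paths are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return a [cohort_config()] object.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  excl <- lapply(raw$excluded_pts, function(x) {
    if (length(x) == 1 && file.exists(resolve(x))) readLines(resolve(x)) else x
  })
  cohort_config(
    generic_names = raw$generic_names,
    trade_names = raw$trade_names,
    required_role = raw$required_role %||% "PS",
    excluded_pts = excl,
    target_soc_code = raw$target_soc_code,
    pt_to_soc = readr::read_csv(resolve(raw$pt_to_soc), show_col_types = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deduplicate FAERS case versions
#'
#' A FAERS `caseid` may appear as several report versions (distinct
#' `primaryid`s). Per FDA practice, the version with the largest `fda_dt`
#' survives; at equal `fda_dt` the higher `primaryid` wins (numerically
#' when all ids parse as numbers, otherwise lexicographically with a
#' warning). The result has exactly one case per `caseid`, ordered by
#' `caseid`; the operation is idempotent and order-independent.
#'
#' @param cases a `faers_cases` object whose demo rows carry `caseid` and
#'   `fda_dt`.
#' @return deduplicated `faers_cases`.
#' @export
deduplicate_cases <- function(cases) {
  demo <- cases$demo
  if (any(is.na(demo$caseid))) stop("caseid missing on some cases", call. = FALSE)
  pid_num <- suppressWarnings(as.numeric(demo$primaryid))
  if (any(is.na(pid_num))) {
    warning("non-numeric primaryid; tie-break falls back to lexicographic order")
    pid_rank <- rank(demo$primaryid, ties.method = "first")
  } else {
    pid_rank <- pid_num
  }
  fda <- demo$fda_dt
  fda[is.na(fda)] <- ""
  keep <- demo %>%
    mutate(.fda = fda, .pid_rank = pid_rank) %>%
    group_by(.data$caseid) %>%
    arrange(desc(.data$.fda), desc(.data$.pid_rank), .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.data$caseid) %>%
    pull("primaryid")
  out <- filter_cases(cases, keep)
  out$demo <- arrange(out$demo, .data$caseid)
  out
}

# Drug rows matching the configured names + role, case-insensitive
# substring on drugname/prod_ai (generic) or drugname (trade).
match_suspect_drug_rows <- function(drug, config) {
  dn <- norm_text(drug$drugname)
  ai <- norm_text(drug$prod_ai)
  hit <- rep(FALSE, nrow(drug))
  for (g in config$generic_names) {
    hit <- hit | grepl(g, dn, fixed = TRUE) | grepl(g, ai, fixed = TRUE)
  }
  for (tr in config$trade_names) {
    hit <- hit | grepl(tr, dn, fixed = TRUE)
  }
  hit & !is.na(drug$role_cod) & drug$role_cod == config$required_role
}

# Drug rows naming the target drug in ANY role (used to exclude the
# drug's own reports from the background).
match_any_role_drug_rows <- function(drug, config) {
  dn <- norm_text(drug$drugname)
  ai <- norm_text(drug$prod_ai)
  hit <- rep(FALSE, nrow(drug))
  for (g in config$generic_names) {
    hit <- hit | grepl(g, dn, fixed = TRUE) | grepl(g, ai, fixed = TRUE)
  }
  for (tr in config$trade_names) {
    hit <- hit | grepl(tr, dn, fixed = TRUE)
  }
  hit
}

#' Select suspect-drug cases
#'
#' Retains cases having at least one drug row that names the target drug
#' (generic name in `drugname`/`prod_ai`, or trade name in `drugname`;
#' case-insensitive substring match, so verbatim entries with dose or
#' form suffixes still match) AND carries the required role code.
#'
#' @param cases deduplicated `faers_cases`.
#' @param config a [cohort_config()].
#' @return `faers_cases` restricted to suspect-drug cases.
#' @export
select_drug_cases <- function(cases, config) {
  hit <- match_suspect_drug_rows(cases$drug, config)
  filter_cases(cases, unique(cases$drug$primaryid[hit]))
}

#' Background (comparator) cases
#'
#' All cases where the target drug does not appear in any role; the
#' disproportionality comparator "all other drugs".
#'
#' @inheritParams select_drug_cases
#' @return `faers_cases` with the target drug's reports removed.
#' @export
select_background_cases <- function(cases, config) {
  hit <- match_any_role_drug_rows(cases$drug, config)
  drop <- unique(cases$drug$primaryid[hit])
  filter_cases(cases, setdiff(cases$demo$primaryid, drop))
}

#' Apply PT-class and date-error exclusions
#'
#' Removes from every case's reaction list the PTs belonging to any
#' configured exclusion class (off-label use, product issues, medication
#' errors, indication-disease terms). Drops entirely (a) cases whose
#' `event_dt` and suspect-drug therapy `start_dt` are both full-precision
#' calendar dates with `event_dt < start_dt` (input errors), and (b)
#' cases whose whole PT list was excluded. Partial or missing dates are
#' never treated as date errors.
#'
#' @param cases suspect-drug `faers_cases`.
#' @param config a [cohort_config()].
#' @return filtered `faers_cases`; removal counts are reported via
#'   `message()` and attached as attribute `"exclusion_counts"`.
#' @export
apply_exclusions <- function(cases, config) {
  excluded <- unique(unlist(config$excluded_pts, use.names = FALSE))
  reac <- cases$reac
  drop_pt <- norm_text(reac$pt) %in% excluded
  n_pts_removed <- sum(drop_pt)
  cases$reac <- reac[!drop_pt, , drop = FALSE]

  start <- suspect_start_dates(cases, config)
  demo <- left_join(cases$demo, start, by = "primaryid")
  event <- faers_date_to_date(demo$event_dt)
  date_error <- !is.na(event) & !is.na(demo$start_date) &
    event < demo$start_date
  n_date_errors <- sum(date_error)

  keep <- demo$primaryid[!date_error]
  out <- filter_cases(cases, keep)
  empty <- setdiff(out$demo$primaryid, out$reac$primaryid)
  n_emptied <- length(empty)
  out <- filter_cases(out, setdiff(out$demo$primaryid, empty))
  message("exclusions: ", n_pts_removed, " PT row(s) removed, ",
          n_date_errors, " date-error case(s) dropped, ",
          n_emptied, " case(s) left without PTs dropped")
  attr(out, "exclusion_counts") <- c(pts_removed = n_pts_removed,
                                     date_errors = n_date_errors,
                                     emptied_cases = n_emptied)
  out
}

# Earliest full-precision therapy start date among the suspect drug's
# THER rows, per case.
suspect_start_dates <- function(cases, config) {
  hit <- match_suspect_drug_rows(cases$drug, config)
  suspect <- cases$drug[hit, c("primaryid", "drug_seq")]
  ther <- inner_join(cases$ther, suspect,
                     by = c("primaryid", dsg_drug_seq = "drug_seq"))
  ther$start_date <- faers_date_to_date(ther$start_dt)
  ther %>%
    filter(!is.na(.data$start_date)) %>%
    group_by(.data$primaryid) %>%
    summarise(start_date = min(.data$start_date), .groups = "drop")
}

#' Restrict a cohort to a target System Organ Class
#'
#' Keeps cases having at least one retained PT that maps to the target
#' SOC, and tallies PT-level events: a case with several target-SOC PTs
#' is intentionally double-counted in the event tally (one count per
#' distinct case-PT pair), while contributing a single case. PTs absent
#' from the map are excluded from the tally with a warning.
#'
#' @param cases `faers_cases` after exclusions.
#' @param config a [cohort_config()].
#' @return list with elements `cases` (the SOC cohort), `n_pt_events`
#'   (PT-level event tally), `n_cases`, and `n_unmapped_pts`.
#' @export
restrict_to_soc <- function(cases, config) {
  reac <- distinct(cases$reac, .data$primaryid, pt = norm_text(.data$pt))
  mapped <- left_join(reac, config$pt_to_soc, by = "pt")
  n_unmapped <- sum(is.na(mapped$soc_code))
  if (n_unmapped > 0) {
    warning(n_unmapped, " reaction row(s) with unmapped PT excluded from ",
            "the SOC tally")
  }
  in_soc <- mapped[!is.na(mapped$soc_code) &
                     mapped$soc_code == config$target_soc_code, ]
  soc_cases <- filter_cases(cases, unique(in_soc$primaryid))
  list(cases = soc_cases,
       n_pt_events = nrow(in_soc),
       n_cases = n_cases(soc_cases),
       n_unmapped_pts = n_unmapped)
}

#' Summarize a cohort's clinical characteristics
#'
#' Descriptive table in the shape of a spontaneous-report demographics
#' table: counts and percentages by sex, age band (&lt;18, 18--64, &gt;64
#' years), weight band (&lt;80, 80--100, &gt;100 kg), country, outcome
#' class and codes, reporter class, and reporting year, plus median/IQR
#' for age, weight and (when `config` is given) time-to-onset.
#' Percentages use the available (non-missing) denominator of each
#' variable.
#'
#' @param cases a deduplicated `faers_cases` cohort.
#' @param config optional [cohort_config()] enabling the TTO summary.
#' @return a `cohort_summary` list with tibbles `categorical` (columns
#'   `variable`, `level`, `n`, `available_n`, `pct`) and `continuous`
#'   (columns `variable`, `n`, `median`, `q1`, `q3`).
#' @export
summarize_cohort <- function(cases, config = NULL) {
  demo <- cases$demo %>%
    mutate(
      age_years = age_to_years(.data$age, .data$age_cod),
      weight_kg = weight_to_kg(.data$wt, .data$wt_cod),
      age_band = band_age(.data$age_years),
      weight_band = band_weight(.data$weight_kg),
      year = substr(.data$fda_dt, 1, 4),
      outcome_class = ifelse(.data$serious, "serious", "nonserious")
    )
  cat_var <- function(var) {
    x <- demo[[var]]
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      return(tibble(variable = character(), level = character(),
                    n = integer(), available_n = integer(), pct = numeric()))
    }
    tab <- sort(table(x), decreasing = TRUE)
    tibble(variable = var, level = names(tab), n = as.integer(tab),
           available_n = length(x),
           pct = 100 * as.integer(tab) / length(x))
  }
  categorical <- bind_rows(lapply(
    c("sex", "age_band", "weight_band", "occr_country", "outcome_class",
      "reporter_class", "year"), cat_var))
  # per-outcome-code shares over all cases (codes are not exclusive)
  if (nrow(cases$outc) > 0) {
    oc <- distinct(cases$outc, .data$primaryid, .data$outc_cod) %>%
      count(.data$outc_cod)
    categorical <- bind_rows(categorical, tibble(
      variable = "outcome_code", level = oc$outc_cod, n = oc$n,
      available_n = nrow(demo), pct = 100 * oc$n / nrow(demo)))
  }
  cont_var <- function(var, values) {
    values <- values[!is.na(values)]
    if (length(values) == 0) {
      return(tibble(variable = var, n = 0L, median = NA_real_,
                    q1 = NA_real_, q3 = NA_real_))
    }
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
    tibble(variable = var, n = length(values), median = q[2],
           q1 = q[1], q3 = q[3])
  }
  continuous <- bind_rows(
    cont_var("age_years", demo$age_years),
    cont_var("weight_kg", demo$weight_kg)
  )
  if (!is.null(config)) {
    tto <- compute_tto(cases, config)
    continuous <- bind_rows(continuous, cont_var("tto_days", tto$tto_days))
  }
  structure(list(categorical = categorical, continuous = continuous),
            class = "cohort_summary")
}

band_age <- function(age_years) {
  cut(age_years, breaks = c(-Inf, 18, 64, Inf),
      labels = c("<18", "18-64", ">64"), right = FALSE) |>
    as.character() |>
    (\(x) ifelse(age_years == 64 & !is.na(age_years), "18-64", x))()
}

band_weight <- function(weight_kg) {
  cut(weight_kg, breaks = c(-Inf, 80, 100, Inf),
      labels = c("<80", "80-100", ">100"), right = FALSE) |>
    as.character() |>
    (\(x) ifelse(weight_kg == 100 & !is.na(weight_kg), "80-100", x))()
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$categorical, n = 20)
  print(x$continuous)
  invisible(x)
}
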