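#' Configuration for the synthetic FAERS generator
#'
#' Defines a complete simulated reporting stream: a background cohort of
#' non-target-drug reports, a suspect-drug cohort with configurable
#' drug--event association strengths, Weibull-distributed onset times,
#' serious-outcome and death rates, demographics with missingness,
#' duplicate case versions, and the quarterly reporting window. All
#' randomness is fixed by `seed`.
#'
#' Signals are injected on the odds scale: for a PT with target ROR
#' `rho`, the drug cohort's per-event probability `q` solves
#' `(q/(1-q)) / (p/(1-p)) = rho` where `p` is the background probability,
#' so the expected event-level 2x2 reproduces `rho` exactly; the
#' remaining probability mass is spread over non-signal PTs
#' proportionally to their background rates.
#'
#' @param n_background_cases,n_drug_cases cohort sizes (deduplicated
#'   truth; duplicates are emitted on top).
#' @param pt_catalog tibble with columns `pt`, `soc_code`,
#'   `background_rate` (relative event rates, any positive scale).
#' @param signal_spec named numeric vector: target ROR multiplier per PT
#'   (names must appear in `pt_catalog`).
#' @param serious_prob probability a case is serious (has OUTC rows).
#' @param death_prob_given_serious probability a serious case carries a
#'   DE outcome.
#' @param tto_spec list of onset-time groups; each element is
#'   `list(pts = <character or NULL>, alpha = <days>, beta = <shape>)`.
#'   A case is assigned the first group one of its PTs belongs to; the
#'   element named `"default"` (with `pts = NULL`) catches the rest.
#' @param tto_available fraction of cases with a suspect-drug therapy
#'   start date (full precision).
#' @param event_dt_available fraction of cases with an event date.
#' @param partial_date_frac fraction of available event dates truncated
#'   to month precision (exercises precision handling).
#' @param duplicate_rate fraction of cases emitted with an extra,
#'   superseded case version.
#' @param n_quarters number of quarterly file sets starting 2013 Q1.
#' @param trade_name,generic_name verbatim names for the suspect drug.
#' @param background_drugs drug names used for background reports.
#' @param demographics list with elements `sex_probs` (F/M/missing),
#'   `age_mean`, `age_sd`, `age_missing`, `wt_mean`, `wt_sd`,
#'   `wt_missing`.
#' @param seed integer RNG seed fixing all randomness.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_background_cases = 20000,
                             n_drug_cases = 2000,
                             pt_catalog = default_pt_catalog(),
                             signal_spec = default_signal_spec(),
                             serious_prob = 0.74,
                             death_prob_given_serious = 0.18,
                             tto_spec = default_tto_spec(),
                             tto_available = 0.35,
                             event_dt_available = 0.75,
                             partial_date_frac = 0.05,
                             duplicate_rate = 0.1,
                             n_quarters = 40,
                             trade_name = "VIMPAT",
                             generic_name = "LACOSAMIDE",
                             background_drugs = c(
                               "LEVETIRACETAM", "VALPROIC ACID", "LAMOTRIGINE",
                               "METFORMIN", "ASPIRIN", "LISINOPRIL",
                               "ATORVASTATIN", "OMEPRAZOLE"),
                             demographics = list(
                               sex_probs = c(F = 0.49, M = 0.44, miss = 0.07),
                               age_mean = 52, age_sd = 22, age_missing = 0.25,
                               wt_mean = 70, wt_sd = 18, wt_missing = 0.6),
                             seed = 1L) {
  pt_catalog <- as_tibble(pt_catalog)
  stopifnot(all(c("pt", "soc_code", "background_rate") %in% names(pt_catalog)),
            all(pt_catalog$background_rate > 0),
            n_background_cases > 0, n_drug_cases > 0,
            serious_prob >= 0, serious_prob <= 1,
            death_prob_given_serious >= 0, death_prob_given_serious <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1,
            tto_available >= 0, tto_available <= 1,
            n_quarters >= 1)
  pt_catalog$pt <- norm_text(pt_catalog$pt)
  if (length(signal_spec) > 0) {
    names(signal_spec) <- norm_text(names(signal_spec))
    missing_pts <- setdiff(names(signal_spec), pt_catalog$pt)
    if (length(missing_pts) > 0) {
      stop("signal_spec PTs absent from pt_catalog: ",
           paste(missing_pts, collapse = ", "), call. = FALSE)
    }
    if (any(signal_spec <= 0)) stop("signal ROR multipliers must be > 0",
                                    call. = FALSE)
  }
  p <- pt_catalog$background_rate / sum(pt_catalog$background_rate)
  q <- drug_event_probs(pt_catalog$pt, p, signal_spec)
  if (any(is.na(q)) || any(q < 0)) {
    stop("impossible signal_spec: implied drug event probabilities ",
         "exceed 1", call. = FALSE)
  }
  if ("default" %in% names(tto_spec) == FALSE) {
    stop("tto_spec must contain a 'default' group", call. = FALSE)
  }
  structure(list(
    n_background_cases = as.integer(n_background_cases),
    n_drug_cases = as.integer(n_drug_cases),
    pt_catalog = pt_catalog, signal_spec = signal_spec,
    background_probs = p, drug_probs = q,
    serious_prob = serious_prob,
    death_prob_given_serious = death_prob_given_serious,
    tto_spec = tto_spec, tto_available = tto_available,
    event_dt_available = event_dt_available,
    partial_date_frac = partial_date_frac,
    duplicate_rate = duplicate_rate, n_quarters = as.integer(n_quarters),
    trade_name = trade_name, generic_name = generic_name,
    background_drugs = background_drugs, demographics = demographics,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Odds-scale signal injection (see synthetic_config details).
drug_event_probs <- function(pts, p, signal_spec) {
  q <- rep(NA_real_, length(p))
  names(q) <- pts
  sig <- names(signal_spec)
  for (s in sig) {
    i <- match(s, pts)
    odds <- signal_spec[[s]] * p[i] / (1 - p[i])
    q[i] <- odds / (1 + odds)
  }
  rest <- setdiff(pts, sig)
  mass <- 1 - sum(q[sig])
  if (mass < 0) return(rep(NA_real_, length(p)))
  q[rest] <- mass * p[match(rest, pts)] / sum(p[match(rest, pts)])
  q
}

#' Default miniature PT catalog
#'
#' Cardiac-disorder PTs (SOC 10007541) alongside non-cardiac background
#' terms, with relative background reporting rates loosely shaped like a
#' spontaneous-reporting stream (a long tail of common non-cardiac
#' terms). Ships as a plain-text fixture; a synthetic miniature, not the
#' licensed MedDRA dictionary.
#'
#' @return tibble `pt`, `soc_code`, `background_rate`.
#' @export
default_pt_catalog <- function() {
  path <- system.file("extdata", "pt_catalog.csv", package = "faersignal")
  out <- readr::read_csv(path, show_col_types = FALSE)
  out$pt <- norm_text(out$pt)
  out$soc_code <- as.character(out$soc_code)
  out
}

#' Default injected signal strengths
#'
#' A handful of cardiac PTs with target RORs spanning the strong
#' conduction-disorder signals and the near-null atrial fibrillation
#' style signal, plus one null cardiac PT left at 1 for contrast.
#'
#' @return named numeric vector of target RORs.
#' @export
default_signal_spec <- function() {
  c("BRADYCARDIA" = 6, "ATRIOVENTRICULAR BLOCK" = 15,
    "ATRIOVENTRICULAR BLOCK COMPLETE" = 16, "CARDIAC ARREST" = 2.5,
    "ATRIAL FIBRILLATION" = 1.6, "VENTRICULAR FIBRILLATION" = 3,
    "SINUS ARREST" = 12)
}

#' Default onset-time groups
#'
#' Early-failure Weibull onset profiles for the strong conduction
#' signals (scale ~100 days, shape ~0.5) and a slower profile for the
#' weaker signals, with an intermediate default.
#'
#' @return list of TTO groups (see [synthetic_config()]).
#' @export
default_tto_spec <- function() {
  list(
    moderate = list(pts = c("BRADYCARDIA", "ATRIOVENTRICULAR BLOCK",
                            "ATRIOVENTRICULAR BLOCK COMPLETE",
                            "CARDIAC ARREST", "VENTRICULAR FIBRILLATION",
                            "SINUS ARREST"),
                    alpha = 103, beta = 0.48),
    weak = list(pts = c("ATRIAL FIBRILLATION", "CARDIO-RESPIRATORY ARREST",
                        "ARRHYTHMIA", "CONDUCTION DISORDER"),
                alpha = 174, beta = 0.52),
    default = list(pts = NULL, alpha = 120, beta = 0.7)
  )
}

#' Generate a synthetic FAERS quarterly file set
#'
#' Emits DEMO/DRUG/REAC/OUTC/THER/INDI files per quarter in the FAERS
#' `$`-delimited dialect, together with the ground truth used to create
#' them. Deterministic under a fixed config (the seed is part of the
#' config): regenerating yields byte-identical files.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list: `files` (written paths), `truth` (list with
#'   `expected_ror`, `case_primaryids` of the pre-duplication truth,
#'   `tto` tibble, `serious` tibble, `n_duplicates`).
#' @export
simulate_faers <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  window_start <- as.Date("2013-01-01")
  window_end <- seq(window_start, by = "3 months",
                    length.out = config$n_quarters + 1)[config$n_quarters + 1] - 1

  bg <- make_synthetic_cohort(config, drug_cohort = FALSE,
                              id_offset = 1000000L, window_start, window_end)
  dr <- make_synthetic_cohort(config, drug_cohort = TRUE,
                              id_offset = 2000000L, window_start, window_end)
  tabs <- mapply(bind_rows, bg$tables, dr$tables, SIMPLIFY = FALSE)

  dup <- emit_duplicates(tabs, config$duplicate_rate, window_start)
  tabs <- dup$tables

  files <- write_faers_files(tabs, dir)
  truth <- list(
    expected_ror = config$signal_spec,
    case_primaryids = sort(c(bg$primaryids, dr$primaryids)),
    drug_case_primaryids = sort(dr$primaryids),
    tto = dr$tto,
    serious = bind_rows(bg$serious, dr$serious),
    n_duplicates = dup$n_duplicates
  )
  invisible(list(files = files, truth = truth))
}

# One cohort's worth of linked tables (pre-duplication).
make_synthetic_cohort <- function(config, drug_cohort, id_offset,
                                  window_start, window_end) {
  n <- if (drug_cohort) config$n_drug_cases else config$n_background_cases
  probs <- if (drug_cohort) config$drug_probs else config$background_probs
  dem <- config$demographics
  caseid <- as.character(id_offset + seq_len(n))
  primaryid <- paste0(caseid, "9")  # version suffix; duplicates get lower

  # --- reactions: iid event draws, distinct (case, pt)
  n_pt <- 1L + stats::rpois(n, 0.25)
  ev_case <- rep(seq_len(n), n_pt)
  ev_pt <- sample(config$pt_catalog$pt, sum(n_pt), replace = TRUE,
                  prob = probs)
  reac <- distinct(tibble(case = ev_case, pt = ev_pt))
  pts_by_case <- split(reac$pt, reac$case)

  # --- onset-time group per case: first tto_spec group hit by its PTs
  group_of_case <- function(pts) {
    for (g in names(config$tto_spec)) {
      gp <- config$tto_spec[[g]]$pts
      if (!is.null(gp) && any(pts %in% norm_text(gp))) return(g)
    }
    "default"
  }
  groups <- vapply(pts_by_case[as.character(seq_len(n))],
                   group_of_case, character(1))

  # --- dates
  window_days <- as.numeric(window_end - window_start)
  tto <- vapply(seq_len(n), function(i) {
    g <- config$tto_spec[[groups[i]]]
    min(round(stats::rweibull(1, shape = g$beta, scale = g$alpha)),
        window_days - 120)
  }, numeric(1))
  start_offset <- floor(stats::runif(n) *
                          pmax(1, window_days - 120 - tto))
  start_date <- window_start + start_offset
  event_date <- start_date + tto
  fda_date <- pmin(event_date + sample(3:90, n, replace = TRUE), window_end)

  has_ther <- stats::runif(n) < config$tto_available
  has_event <- stats::runif(n) < config$event_dt_available
  event_partial <- stats::runif(n) < config$partial_date_frac
  event_dt <- ifelse(has_event,
                     ifelse(event_partial, format(event_date, "%Y%m"),
                            format(event_date, "%Y%m%d")),
                     "")

  # --- seriousness
  serious <- stats::runif(n) < config$serious_prob
  death <- serious & stats::runif(n) < config$death_prob_given_serious

  # --- demographics
  sexp <- dem$sex_probs
  sex <- sample(c("F", "M", ""), n, replace = TRUE, prob = sexp)
  age <- round(pmin(pmax(stats::rnorm(n, dem$age_mean, dem$age_sd), 0.5), 95))
  age_miss <- stats::runif(n) < dem$age_missing
  age_cod <- rep("YR", n)
  # a slice of infant ages reported in months, elders in decades
  mon <- !age_miss & age < 2
  age[mon] <- pmax(1, round(age[mon] * 12)); age_cod[mon] <- "MON"
  dec <- !age_miss & !mon & stats::runif(n) < 0.03
  age[dec] <- round(age[dec] / 10); age_cod[dec] <- "DEC"
  wt <- round(pmin(pmax(stats::rnorm(n, dem$wt_mean, dem$wt_sd), 3), 160), 1)
  wt_miss <- stats::runif(n) < dem$wt_missing
  wt_cod <- rep("KG", n)
  lbs <- !wt_miss & stats::runif(n) < 0.1
  wt[lbs] <- round(wt[lbs] / 0.4536, 1); wt_cod[lbs] <- "LBS"
  country <- sample(c("US", "JP", "DE", "FR", "CO", "GB", "IT"), n,
                    replace = TRUE,
                    prob = c(0.45, 0.14, 0.09, 0.09, 0.03, 0.1, 0.1))
  occp <- sample(c("MD", "PH", "HP", "OT", "CN", "LW", ""), n,
                 replace = TRUE,
                 prob = c(0.3, 0.12, 0.1, 0.13, 0.28, 0.02, 0.05))

  demo <- tibble(
    primaryid = primaryid, caseid = caseid,
    fda_dt = format(fda_date, "%Y%m%d"),
    event_dt = event_dt, sex = sex,
    age = ifelse(age_miss, "", as.character(age)),
    age_cod = ifelse(age_miss, "", age_cod),
    wt = ifelse(wt_miss, "", as.character(wt)),
    wt_cod = ifelse(wt_miss, "", wt_cod),
    occr_country = country, occp_cod = occp
  )

  # --- drugs
  if (drug_cohort) {
    dn <- sample(c(config$trade_name, config$generic_name,
                   paste(config$generic_name, "100MG TABLET")),
                 n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    drug <- tibble(primaryid = primaryid, drug_seq = "1", role_cod = "PS",
                   drugname = dn, prod_ai = config$generic_name)
    conco <- stats::runif(n) < 0.3
    drug <- bind_rows(drug, tibble(
      primaryid = primaryid[conco], drug_seq = "2", role_cod = "C",
      drugname = sample(config$background_drugs, sum(conco), replace = TRUE),
      prod_ai = ""))
  } else {
    drug <- tibble(primaryid = primaryid, drug_seq = "1", role_cod = "PS",
                   drugname = sample(config$background_drugs, n,
                                     replace = TRUE),
                   prod_ai = "")
    second <- stats::runif(n) < 0.2
    drug <- bind_rows(drug, tibble(
      primaryid = primaryid[second], drug_seq = "2", role_cod = "SS",
      drugname = sample(config$background_drugs, sum(second), replace = TRUE),
      prod_ai = ""))
  }

  reac_tab <- tibble(primaryid = primaryid[reac$case], pt = reac$pt)

  outc <- tibble(
    primaryid = primaryid[serious],
    outc_cod = sample(c("HO", "OT", "LT", "DS", "RI"), sum(serious),
                      replace = TRUE, prob = c(0.4, 0.35, 0.12, 0.05, 0.08)))
  outc <- bind_rows(outc, tibble(primaryid = primaryid[death],
                                 outc_cod = "DE"))

  ther <- tibble(primaryid = primaryid[has_ther], dsg_drug_seq = "1",
                 start_dt = format(start_date[has_ther], "%Y%m%d"),
                 end_dt = "")

  indi <- tibble(primaryid = primaryid, indi_drug_seq = "1",
                 indi_pt = if (drug_cohort) {
                   sample(c("EPILEPSY", "PARTIAL SEIZURES", "NEURALGIA"),
                          n, replace = TRUE, prob = c(0.6, 0.2, 0.2))
                 } else {
                   sample(c("HYPERTENSION", "DIABETES MELLITUS", "EPILEPSY",
                            "PAIN"), n, replace = TRUE)
                 })

  list(
    tables = list(demo = demo, drug = drug, reac = reac_tab, outc = outc,
                  ther = ther, indi = indi),
    primaryids = primaryid,
    tto = tibble(primaryid = primaryid, tto_days = tto, group = groups,
                 observable = has_ther & has_event & !event_partial),
    serious = tibble(primaryid = primaryid, serious = serious,
                     death = death)
  )
}

# Extra, superseded versions of a fraction of cases: same caseid, lower
# version digit (hence lower primaryid), fda_dt strictly older (70%) or
# equal (30%, exercising the primaryid tie-break).
emit_duplicates <- function(tabs, duplicate_rate, window_start) {
  if (duplicate_rate == 0) return(list(tables = tabs, n_duplicates = 0L))
  demo <- tabs$demo
  pick <- stats::runif(nrow(demo)) < duplicate_rate
  ids <- demo$primaryid[pick]
  if (length(ids) == 0) return(list(tables = tabs, n_duplicates = 0L))
  older <- stats::runif(length(ids)) < 0.7
  dup_demo <- demo[pick, , drop = FALSE]
  orig_fda <- as.Date(dup_demo$fda_dt, "%Y%m%d")
  dup_fda <- orig_fda
  dup_fda[older] <- pmax(orig_fda[older] -
                           sample(30:400, sum(older), replace = TRUE),
                         window_start)
  dup_demo$fda_dt <- format(dup_fda, "%Y%m%d")
  old_id <- dup_demo$primaryid
  new_id <- paste0(dup_demo$caseid, "1")
  dup_demo$primaryid <- new_id
  out <- list(demo = bind_rows(demo, dup_demo))
  for (kind in setdiff(names(tabs), "demo")) {
    tab <- tabs[[kind]]
    dup_rows <- tab[tab$primaryid %in% old_id, , drop = FALSE]
    dup_rows$primaryid <- new_id[match(dup_rows$primaryid, old_id)]
    out[[kind]] <- bind_rows(tab, dup_rows)
  }
  list(tables = out, n_duplicates = length(ids))
}

# Write tables into quarterly $-delimited files keyed by fda_dt quarter.
write_faers_files <- function(tabs, dir) {
  demo <- tabs$demo
  fda <- as.Date(demo$fda_dt, "%Y%m%d")
  qlab <- paste0(format(fda, "%y"), "Q", (as.POSIXlt(fda)$mon %/% 3) + 1)
  files <- character()
  for (q in sort(unique(qlab))) {
    ids <- demo$primaryid[qlab == q]
    for (kind in names(tabs)) {
      tab <- tabs[[kind]][tabs[[kind]]$primaryid %in% ids, , drop = FALSE]
      path <- file.path(dir, paste0(toupper(kind), q, ".txt"))
      lines <- c(paste(names(tab), collapse = "$"),
                 do.call(paste, c(as.list(tab), sep = "$")))
      writeLines(lines, path)
      files <- c(files, path)
    }
  }
  files
}

#' Miniature deterministic fixture data set
#'
#' A ~200-case synthetic file set for tests and examples, with
#' handcrafted edge cases appended: a duplicated caseid tied on
#' `fda_dt` (resolved by the primaryid rule), a zero-day onset, a
#' date-error case (`event_dt` before `start_dt`), a case whose only PT
#' is in an excluded class, and a case carrying a PT absent from the
#' PT-to-SOC map.
#'
#' @param dir output directory.
#' @param seed RNG seed (default fixed, so the fixture is stable).
#' @return invisibly, a list: `files`, `truth`, and `edge` (the
#'   handcrafted primaryids by role).
#' @export
make_fixture_small <- function(dir, seed = 20240713) {
  config <- synthetic_config(
    n_background_cases = 150, n_drug_cases = 60,
    duplicate_rate = 0.15, n_quarters = 8, seed = seed)
  sim <- simulate_faers(config, dir)

  edge <- list(
    tie_dup = "90000011", tie_orig = "90000019",
    zero_tto = "90000029", date_error = "90000039",
    excluded_pt = "90000049", unmapped_pt = "90000059")
  headers <- list(
    DEMO = "primaryid$caseid$fda_dt$event_dt$sex$age$age_cod$wt$wt_cod$occr_country$occp_cod",
    DRUG = "primaryid$drug_seq$role_cod$drugname$prod_ai",
    REAC = "primaryid$pt",
    OUTC = "primaryid$outc_cod",
    THER = "primaryid$dsg_drug_seq$start_dt$end_dt",
    INDI = "primaryid$indi_drug_seq$indi_pt")
  app <- function(file, ...) {
    kind <- toupper(sub("[0-9].*$", "", basename(file)))
    if (!file.exists(file)) writeLines(headers[[kind]], file)
    cat(..., sep = "\n", file = file, append = TRUE)
  }
  # duplicated caseid tied on fda_dt: the higher primaryid must survive
  app(file.path(dir, "DEMO14Q1.txt"),
      "90000019$9000001$20140110$20140105$F$44$YR$60$KG$US$MD",
      "90000011$9000001$20140110$20140105$F$44$YR$60$KG$US$MD",
      "90000029$9000002$20140120$20140112$M$50$YR$$$US$CN",
      "90000039$9000003$20140115$20140101$F$31$YR$$$JP$MD",
      "90000049$9000004$20140116$20140110$M$62$YR$$$US$MD",
      "90000059$9000005$20140117$20140111$F$55$YR$$$US$PH")
  app(file.path(dir, "DRUG14Q1.txt"),
      "90000019$1$PS$VIMPAT$LACOSAMIDE",
      "90000011$1$PS$VIMPAT$LACOSAMIDE",
      "90000029$1$PS$lacosamide 50mg tab$LACOSAMIDE",
      "90000039$1$PS$VIMPAT$LACOSAMIDE",
      "90000049$1$PS$VIMPAT$LACOSAMIDE",
      "90000059$1$PS$VIMPAT$LACOSAMIDE")
  app(file.path(dir, "REAC14Q1.txt"),
      "90000019$Bradycardia",
      "90000011$Bradycardia",
      "90000029$Cardiac arrest",
      "90000039$Bradycardia",
      "90000049$Off label use",
      "90000059$Mystery unmapped term")
  app(file.path(dir, "THER14Q1.txt"),
      "90000019$1$20140102$",
      "90000029$1$20140112$",   # zero-day TTO: event same day
      "90000039$1$20140201$",   # date error: event 20140101 < start
      "90000049$1$20140101$",
      "90000059$1$20140101$")
  app(file.path(dir, "OUTC14Q1.txt"), "90000019$HO", "90000029$DE")
  app(file.path(dir, "INDI14Q1.txt"),
      "90000019$1$Epilepsy", "90000029$1$Epilepsy")
  invisible(list(files = sim$files, truth = sim$truth, edge = edge))
}
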