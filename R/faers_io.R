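#' @importFrom dplyr %>% across all_of anti_join arrange bind_rows count
#'   desc distinct filter first group_by inner_join left_join mutate n
#'   pull rename row_number select semi_join slice summarise ungroup
#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Canonical column sets per FAERS table kind. Readers map by header name
# (case-insensitively), tolerate extra columns, and alias renamed columns
# across quarterly schema revisions (e.g. gndr_cod -> sex).
faers_table_schema <- list(
  demo = list(
    required = "primaryid",
    keep = c("primaryid", "caseid", "fda_dt", "event_dt", "sex", "age",
             "age_cod", "wt", "wt_cod", "occr_country", "occp_cod"),
    aliases = c(gndr_cod = "sex")
  ),
  drug = list(
    required = "primaryid",
    keep = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
    aliases = character()
  ),
  reac = list(
    required = "primaryid",
    keep = c("primaryid", "pt"),
    aliases = character()
  ),
  outc = list(
    required = "primaryid",
    keep = c("primaryid", "outc_cod"),
    aliases = c(outc_code = "outc_cod")
  ),
  ther = list(
    required = "primaryid",
    keep = c("primaryid", "dsg_drug_seq", "start_dt", "end_dt"),
    aliases = character()
  ),
  indi = list(
    required = "primaryid",
    keep = c("primaryid", "indi_drug_seq", "indi_pt"),
    aliases = character()
  ),
  rpsr = list(
    required = "primaryid",
    keep = c("primaryid", "rpsr_cod"),
    aliases = character()
  )
)

outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
drug_role_codes <- c("PS", "SS", "C", "I")

#' Read one FAERS quarterly ASCII table
#'
#' Parses the `$`-delimited dialect of the FAERS Quarterly Data Extract.
#' The first line is the header; fields are mapped by name,
#' case-insensitively, so the reader works across the 2013--2022 quarterly
#' schema revisions and tolerates extra columns. Rows whose field count
#' does not match the header, or whose enum fields carry values outside
#' the FAERS code sets, are skipped with a warning; unparseable dates are
#' retained as missing.
#'
#' @param path path to the ASCII file (e.g. `DEMO13Q1.txt`).
#' @param kind one of `"demo"`, `"drug"`, `"reac"`, `"outc"`, `"ther"`,
#'   `"indi"`, `"rpsr"`.
#' @return A tibble with the canonical columns for `kind` (see Details),
#'   one row per valid data line. The number of skipped malformed lines is
#'   attached as attribute `"n_skipped"`.
#' @export
read_faers_table <- function(path, kind = c("demo", "drug", "reac", "outc",
                                            "ther", "indi", "rpsr")) {
  kind <- match.arg(kind)
  schema <- faers_table_schema[[kind]]
  if (!file.exists(path)) {
    stop("FAERS table file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty file: ", path, call. = FALSE)
  header <- tolower(trimws(strsplit(lines[[1]], "$", fixed = TRUE)[[1]]))
  for (al in names(schema$aliases)) header[header == al] <- schema$aliases[[al]]
  if (!all(schema$required %in% header)) {
    stop("header of ", path, " lacks required column(s): ",
         paste(setdiff(schema$required, header), collapse = ", "),
         call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(body, "$", fixed = TRUE)
  # a trailing empty field is dropped by strsplit; pad to header length
  nf <- lengths(fields)
  pad <- nf == length(header) - 1L & endsWith(body, "$")
  fields[pad] <- lapply(fields[pad], function(f) c(f, ""))
  nf <- lengths(fields)
  ok <- nf == length(header)
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    warning(n_skipped, " malformed line(s) skipped in ", basename(path))
  }
  mat <- do.call(rbind, fields[ok])
  if (is.null(mat)) {
    tab <- as_tibble(stats::setNames(
      rep(list(character(0)), length(schema$keep)), schema$keep))
  } else {
    colnames(mat) <- header
    mat <- mat[, !duplicated(header), drop = FALSE]
    tab <- as_tibble(mat)
    for (col in setdiff(schema$keep, names(tab))) tab[[col]] <- NA_character_
    tab <- tab[schema$keep]
    tab[] <- lapply(tab, function(x) {
      x <- trimws(x)
      x[x == ""] <- NA_character_
      x
    })
  }
  tab <- tab[!is.na(tab$primaryid), , drop = FALSE]
  tab <- validate_faers_table(tab, kind, basename(path))
  attr(tab, "n_skipped") <- n_skipped
  tab
}

# Kind-specific normalization: numeric coercions, enum checks, date
# validity. Invalid enum rows are dropped (counted as malformed); bad
# dates become NA with a warning.
validate_faers_table <- function(tab, kind, label) {
  drop_warn <- function(keep, what) {
    if (any(!keep)) warning(sum(!keep), " row(s) with ", what,
                            " skipped in ", label)
    tab[keep, , drop = FALSE]
  }
  if (kind == "demo") {
    bad_fda <- !is.na(tab$fda_dt) & is.na(faers_date_to_date(tab$fda_dt))
    if (any(bad_fda)) {
      warning(sum(bad_fda), " unparseable fda_dt value(s) set to NA in ", label)
      tab$fda_dt[bad_fda] <- NA_character_
    }
    tab$age <- suppressWarnings(as.numeric(tab$age))
    tab$wt <- suppressWarnings(as.numeric(tab$wt))
    tab$age[!is.na(tab$age) & tab$age < 0] <- NA_real_
    tab$wt[!is.na(tab$wt) & tab$wt < 0] <- NA_real_
    tab$sex <- toupper(tab$sex)
    tab$sex[!tab$sex %in% c("F", "M") & !is.na(tab$sex)] <- NA_character_
  } else if (kind == "drug") {
    tab$role_cod <- toupper(tab$role_cod)
    tab <- drop_warn(is.na(tab$role_cod) | tab$role_cod %in% drug_role_codes,
                     "role_cod outside {PS, SS, C, I}")
    tab$drug_seq <- suppressWarnings(as.integer(tab$drug_seq))
  } else if (kind == "reac") {
    tab <- drop_warn(!is.na(tab$pt) & nzchar(trimws(tab$pt)), "empty pt")
  } else if (kind == "outc") {
    tab$outc_cod <- toupper(tab$outc_cod)
    tab <- drop_warn(tab$outc_cod %in% outcome_codes,
                     "outc_cod outside the seven-code set")
  } else if (kind == "ther") {
    tab$dsg_drug_seq <- suppressWarnings(as.integer(tab$dsg_drug_seq))
  } else if (kind == "indi") {
    tab$indi_drug_seq <- suppressWarnings(as.integer(tab$indi_drug_seq))
  }
  tab
}

#' Read all FAERS quarterly tables under a directory
#'
#' Locates files named like `DEMO13Q1.txt`, `DRUG22Q4.txt`, ... (any case)
#' and row-binds each kind across quarters.
#'
#' @param dir directory containing the quarterly ASCII files.
#' @return named list of tibbles (one per table kind found), suitable for
#'   [assemble_cases()].
#' @export
read_faers_tables <- function(dir) {
  if (!dir.exists(dir)) stop("input directory not found: ", dir, call. = FALSE)
  kinds <- names(faers_table_schema)
  out <- list()
  for (kind in kinds) {
    files <- list.files(dir, pattern = paste0("(?i)^", kind,
                                              "[0-9]{2}Q[1-4]\\.txt$"),
                        full.names = TRUE)
    if (length(files) == 0) next
    out[[kind]] <- bind_rows(lapply(sort(files), read_faers_table, kind = kind))
  }
  if (is.null(out$demo)) stop("no DEMO files found under ", dir, call. = FALSE)
  out
}

#' Assemble case-level reports from FAERS tables
#'
#' Joins the per-kind record tables into a `faers_cases` object: one case
#' per DEMO row, with DRUG/REAC/OUTC/THER/INDI/RPSR children attached by
#' `primaryid` equality. Two derived fields are added to the demographic
#' table: `serious` (`TRUE` iff the case has at least one OUTC row) and
#' `reporter_class` (`"professional"` for occupation codes MD/PH/HP/OT,
#' `"consumer"` for CN/LW, `"unknown"` otherwise). Child records whose
#' `primaryid` is absent from DEMO are dropped and counted as orphans.
#'
#' @param tables named list of tibbles as returned by [read_faers_table()]
#'   or [read_faers_tables()]; `demo` is required, other kinds optional.
#' @return A `faers_cases` object: a list of tibbles (`demo`, `drug`,
#'   `reac`, `outc`, `ther`, `indi`, `rpsr`) with attribute `"orphans"`
#'   giving the per-table dropped-record counts.
#' @export
assemble_cases <- function(tables) {
  if (is.null(tables$demo)) stop("DEMO table is required", call. = FALSE)
  demo <- distinct(tables$demo, .data$primaryid, .keep_all = TRUE)
  ids <- demo$primaryid
  orphans <- integer()
  children <- list()
  for (kind in c("drug", "reac", "outc", "ther", "indi", "rpsr")) {
    tab <- tables[[kind]]
    if (is.null(tab)) {
      tab <- as_tibble(stats::setNames(
        rep(list(character(0)), length(faers_table_schema[[kind]]$keep)),
        faers_table_schema[[kind]]$keep))
      # keep numeric columns consistent with read_faers_table output
      tab <- validate_faers_table(tab, kind, "<empty>")
    }
    keep <- tab$primaryid %in% ids
    orphans[[kind]] <- sum(!keep)
    children[[kind]] <- tab[keep, , drop = FALSE]
  }
  if (sum(orphans) > 0) {
    message(sum(orphans), " orphan child record(s) dropped (no matching DEMO)")
  }
  demo$serious <- demo$primaryid %in% children$outc$primaryid
  demo$reporter_class <- reporter_class(demo$occp_cod)
  out <- c(list(demo = demo), children)
  structure(out, class = "faers_cases", orphans = orphans)
}

# Paper-style two-way reporter split; the code map is the package's
# convention (FAERS documents the codes, not the grouping).
reporter_class <- function(occp_cod) {
  cod <- toupper(trimws(ifelse(is.na(occp_cod), "", occp_cod)))
  ifelse(cod %in% c("MD", "PH", "HP", "OT"), "professional",
         ifelse(cod %in% c("CN", "LW"), "consumer", "unknown"))
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("<faers_cases> ", nrow(x$demo), " cases; ",
      nrow(x$reac), " reaction rows; ",
      sum(x$demo$serious), " serious\n", sep = "")
  invisible(x)
}

#' Number of cases in a `faers_cases` object
#' @param cases a `faers_cases` object.
#' @return integer count of cases.
#' @export
n_cases <- function(cases) nrow(cases$demo)

# Restrict every member table to a set of primaryids.
filter_cases <- function(cases, primaryids) {
  out <- lapply(cases, function(tab) {
    tab[tab$primaryid %in% primaryids, , drop = FALSE]
  })
  structure(out, class = "faers_cases", orphans = attr(cases, "orphans"))
}

#' Export a cohort as a flat PT-level CSV
#'
#' Writes one row per (case, PT) pair with demographics, seriousness,
#' reporter class and the date fields needed for time-to-onset. Dates are
#' exported in ISO-8601 where full-precision, otherwise as the raw partial
#' string in `*_raw` columns. The export round-trips losslessly for the
#' exported columns via [readr::read_csv()].
#'
#' @param cases a `faers_cases` object.
#' @param path output CSV path.
#' @param config optional [cohort_config()]; when supplied, the earliest
#'   full-precision suspect-drug therapy start date and `tto_days` are
#'   included.
#' @return the exported tibble, invisibly.
#' @export
write_cohort <- function(cases, path, config = NULL) {
  demo <- cases$demo
  flat <- demo %>%
    left_join(select(cases$reac, "primaryid", "pt"), by = "primaryid") %>%
    mutate(
      fda_date = faers_date_to_date(.data$fda_dt),
      event_date = faers_date_to_date(.data$event_dt),
      event_dt_raw = .data$event_dt,
      age_years = age_to_years(.data$age, .data$age_cod),
      weight_kg = weight_to_kg(.data$wt, .data$wt_cod)
    ) %>%
    select("primaryid", "caseid", "pt", "serious", "reporter_class",
           "sex", "age_years", "weight_kg", "occr_country",
           "fda_date", "event_date", "event_dt_raw")
  if (!is.null(config)) {
    tto <- compute_tto(cases, config)
    flat <- left_join(flat, tto, by = "primaryid")
  }
  readr::write_csv(flat, path, na = "")
  invisible(flat)
}
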