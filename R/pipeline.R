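#' Validate a pipeline configuration
#'
#' Loads a YAML pipeline configuration (or checks an equivalent list) and
#' verifies every cross-reference before anything runs: input directory,
#' PT-to-SOC map, rubric (including the 10-point maxima invariant), and
#' reference list files. Errors are aggregated into a single message so
#' one pass reports every problem.
#'
#' @param config path to a YAML file, or a named list with the same
#'   structure: `input_dir`, `output_dir`, `cohort` (see
#'   [read_cohort_config()] keys), and optional `rubric`, `ime_list`,
#'   `dme_list`, `label_pts`, `stages`, `zero_policy`.
#' @return a validated `pipeline_config` list.
#' @export
validate_config <- function(config) {
  base <- "."
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    base <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
  }
  resolve <- function(p) {
    if (is.null(p) || file.exists(p)) p else file.path(base, p)
  }
  errors <- character()
  need <- function(cond, msg) if (!cond) errors <<- c(errors, msg)

  need(!is.null(config$input_dir), "input_dir is required")
  if (!is.null(config$input_dir)) {
    config$input_dir <- resolve(config$input_dir)
    need(dir.exists(config$input_dir),
         paste0("input_dir not found: ", config$input_dir))
  }
  need(!is.null(config$output_dir), "output_dir is required")

  if (inherits(config$cohort, "cohort_config")) {
    # already built programmatically
  } else if (is.list(config$cohort)) {
    co <- config$cohort
    need(!is.null(co$generic_names), "cohort.generic_names is required")
    need(!is.null(co$trade_names), "cohort.trade_names is required")
    need(!is.null(co$target_soc_code), "cohort.target_soc_code is required")
    need(!is.null(co$pt_to_soc), "cohort.pt_to_soc path is required")
    if (!is.null(co$pt_to_soc)) {
      pts_path <- resolve(co$pt_to_soc)
      need(file.exists(pts_path),
           paste0("pt_to_soc file not found: ", co$pt_to_soc))
      if (file.exists(pts_path)) co$pt_to_soc <- pts_path
    }
    excl <- co$excluded_pts
    if (!is.null(excl)) {
      co$excluded_pts <- lapply(excl, function(x) {
        if (length(x) == 1 && is.character(x) &&
            file.exists(resolve(x))) readLines(resolve(x)) else x
      })
    }
    if (length(errors) == 0) {
      config$cohort <- cohort_config(
        generic_names = co$generic_names, trade_names = co$trade_names,
        required_role = co$required_role %||% "PS",
        excluded_pts = co$excluded_pts %||% list(),
        target_soc_code = co$target_soc_code,
        pt_to_soc = readr::read_csv(co$pt_to_soc, show_col_types = FALSE))
    }
  } else {
    need(FALSE, "cohort section is required")
  }

  if (!is.null(config$rubric) && !inherits(config$rubric, "priority_rubric")) {
    rp <- resolve(config$rubric)
    if (!file.exists(rp)) {
      need(FALSE, paste0("rubric file not found: ", config$rubric))
    } else {
      config$rubric <- tryCatch(read_rubric(rp), error = function(e) {
        need(FALSE, conditionMessage(e)); NULL
      })
    }
  }
  for (lst in c("ime_list", "dme_list", "label_pts")) {
    val <- config[[lst]]
    if (is.null(val)) next
    if (length(val) == 1 && is.character(val) && !file.exists(val) &&
        file.exists(resolve(val))) val <- resolve(val)
    if (length(val) == 1 && is.character(val) && file.exists(val)) {
      config[[lst]] <- readLines(val)
    }
  }
  all_stages <- c("summary", "screen", "severity", "prioritize", "tto")
  config$stages <- config$stages %||% all_stages
  need(all(config$stages %in% all_stages),
       paste0("unknown stage(s): ",
              paste(setdiff(config$stages, all_stages), collapse = ", ")))
  if (length(errors) > 0) {
    stop("invalid pipeline config:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  structure(config, class = "pipeline_config")
}

#' Run the signal-detection pipeline end to end
#'
#' Ingest, deduplicate, cohort selection, exclusions, SOC restriction,
#' then (per requested stage) the descriptive summary, PT/SOC
#' disproportionality screen with stratified subgroups, serious vs
#' nonserious comparison, clinical prioritization and pooled
#' time-to-onset Weibull analysis. Writes schema-stable CSVs plus a JSON
#' run manifest recording the case count surviving each filter step (the
#' counts are monotonically non-increasing along the pipeline), the
#' package version and the config hash. On a stage failure the partial
#' outputs are preserved and the manifest marks the failed stage before
#' the error is re-raised.
#'
#' @param config a `pipeline_config` (or YAML path / list accepted by
#'   [validate_config()]).
#' @return invisibly, a list with the in-memory results (`summary`,
#'   `signals`, `stratified`, `severity`, `priorities`, `tto`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  cohort_cfg <- config$cohort
  manifest <- list(
    package_version = as.character(utils::packageVersion("faersignal")),
    r_version = as.character(getRversion()),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed %||% NA,
    stages = config$stages,
    counts = list(), outputs = character(), failed_stage = NULL
  )
  results <- list()
  out_path <- function(name) file.path(config$output_dir, name)
  finish <- function() {
    jsonlite::write_json(manifest, out_path("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  stage <- "ingest"
  tryCatch({
    tables <- read_faers_tables(config$input_dir)
    manifest$counts$raw_reports <- nrow(tables$demo)
    cases <- assemble_cases(tables)
    manifest$counts$assembled_cases <- n_cases(cases)

    stage <- "deduplicate"
    cases <- deduplicate_cases(cases)
    manifest$counts$deduplicated_cases <- n_cases(cases)

    stage <- "cohort"
    drug_cases <- select_drug_cases(cases, cohort_cfg)
    manifest$counts$suspect_drug_cases <- n_cases(drug_cases)
    background <- select_background_cases(cases, cohort_cfg)
    manifest$counts$background_cases <- n_cases(background)
    drug_cases <- apply_exclusions(drug_cases, cohort_cfg)
    manifest$counts$after_exclusions <- n_cases(drug_cases)
    soc <- restrict_to_soc(drug_cases, cohort_cfg)
    manifest$counts$soc_cases <- soc$n_cases
    manifest$counts$soc_pt_events <- soc$n_pt_events

    if ("summary" %in% config$stages) {
      stage <- "summary"
      results$summary <- summarize_cohort(soc$cases, cohort_cfg)
      summary_csv <- bind_rows(
        results$summary$categorical,
        mutate(results$summary$continuous, level = "median_iqr",
               available_n = .data$n, pct = NA_real_))
      readr::write_csv(summary_csv, out_path("cohort_summary.csv"), na = "")
      manifest$outputs <- c(manifest$outputs, "cohort_summary.csv")
    }

    need_screen <- any(c("screen", "prioritize", "tto") %in% config$stages)
    if (need_screen) {
      stage <- "screen"
      drug_tally <- pt_event_tally(drug_cases)
      bg_tally <- pt_event_tally(background)
      screen <- screen_soc(drug_tally, bg_tally, cohort_cfg$pt_to_soc,
                           cohort_cfg$target_soc_code)
      results$signals <- bind_rows(screen$pt_signals, screen$soc_signal)
      manifest$counts$screened_pts <- nrow(screen$pt_signals)
      manifest$counts$significant_signals <-
        sum(screen$pt_signals$significant)
      if ("screen" %in% config$stages) {
        readr::write_csv(results$signals, out_path("signals.csv"), na = "")
        results$stratified <- stratified_screen(drug_cases, background,
                                                cohort_cfg)
        readr::write_csv(results$stratified, out_path("stratified.csv"),
                         na = "")
        manifest$outputs <- c(manifest$outputs, "signals.csv",
                              "stratified.csv")
      }
    }

    if ("severity" %in% config$stages) {
      stage <- "severity"
      sev <- build_severity_table(soc$cases)
      results$severity <- sev
      readr::write_csv(sev$ae_rows, out_path("severity.csv"), na = "")
      readr::write_csv(sev$demographic_rows,
                       out_path("severity_demographics.csv"), na = "")
      manifest$outputs <- c(manifest$outputs, "severity.csv",
                            "severity_demographics.csv")
    }

    if (any(c("prioritize", "tto") %in% config$stages)) {
      stage <- "prioritize"
      sig <- filter(screen$pt_signals, .data$significant)
      results$priorities <- prioritize_screen(
        sig, drug_cases,
        rubric = config$rubric %||% default_rubric(),
        ime_list = config$ime_list %||% character(),
        dme_list = config$dme_list %||% character(),
        label_pts = config$label_pts %||% character())
      if ("prioritize" %in% config$stages) {
        readr::write_csv(results$priorities, out_path("priorities.csv"),
                         na = "")
        manifest$outputs <- c(manifest$outputs, "priorities.csv")
      }
    }

    if ("tto" %in% config$stages) {
      stage <- "tto"
      results$tto <- tto_group_summary(
        drug_cases, cohort_cfg, results$priorities,
        zero_policy = config$zero_policy %||% "shift")
      readr::write_csv(results$tto, out_path("tto.csv"), na = "")
      manifest$outputs <- c(manifest$outputs, "tto.csv")
    }
  }, error = function(e) {
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    finish()
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  results$manifest <- manifest
  finish()
  invisible(results)
}

#' Paths to the shipped reference fixtures
#'
#' Miniature plain-text stand-ins for the licensed reference data a
#' production run would use: a PT-to-SOC map, PT exclusion classes,
#' IME/DME lists, a drug-label PT list and the default rubric. All are
#' synthetic subsets assembled for this package.
#'
#' @param file fixture file name; with no argument, lists them all.
#' @return a file path (or vector of available fixture names).
#' @export
faersignal_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "faersignal")))
  }
  path <- system.file("extdata", file, package = "faersignal")
  if (path == "") stop("no such fixture: ", file, call. = FALSE)
  path
}

#' Example cohort configuration (lacosamide-style, synthetic fixtures)
#'
#' A ready-made [cohort_config()] wired to the shipped fixtures: generic
#' and trade names for the suspect drug, the four PT exclusion classes,
#' and the cardiac-disorders SOC target over the miniature PT-to-SOC
#' map. Intended for the synthetic data sets produced by
#' [simulate_faers()] and for examples.
#'
#' @return a `cohort_config`.
#' @export
example_cohort_config <- function() {
  excl <- readr::read_csv(faersignal_extdata("excluded_pts.csv"),
                          show_col_types = FALSE)
  cohort_config(
    generic_names = "LACOSAMIDE",
    trade_names = "VIMPAT",
    excluded_pts = split(excl$pt, excl$class),
    target_soc_code = "10007541",
    pt_to_soc = readr::read_csv(faersignal_extdata("pt_to_soc.csv"),
                                show_col_types = FALSE)
  )
}
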