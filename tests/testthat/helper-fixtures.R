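# Shared builders for in-memory FAERS tables and cached simulations.

demo_row <- function(primaryid, caseid = primaryid, fda_dt = "20200601",
                     event_dt = "", sex = "F", age = "40", age_cod = "YR",
                     wt = "", wt_cod = "", country = "US", occp = "MD") {
  tibble::tibble(primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
                 event_dt = ifelse(event_dt == "", NA, event_dt),
                 sex = ifelse(sex == "", NA, sex),
                 age = as.numeric(age), age_cod = age_cod,
                 wt = suppressWarnings(as.numeric(wt)), wt_cod = wt_cod,
                 occr_country = country, occp_cod = occp)
}

drug_row <- function(primaryid, drugname = "VIMPAT", role_cod = "PS",
                     drug_seq = 1L, prod_ai = "LACOSAMIDE") {
  tibble::tibble(primaryid = primaryid, drug_seq = as.integer(drug_seq),
                 role_cod = role_cod, drugname = drugname, prod_ai = prod_ai)
}

reac_row <- function(primaryid, pt) {
  tibble::tibble(primaryid = primaryid, pt = pt)
}

outc_row <- function(primaryid, outc_cod = "HO") {
  tibble::tibble(primaryid = primaryid, outc_cod = outc_cod)
}

ther_row <- function(primaryid, start_dt, drug_seq = 1L, end_dt = NA) {
  tibble::tibble(primaryid = primaryid, dsg_drug_seq = as.integer(drug_seq),
                 start_dt = start_dt, end_dt = end_dt)
}

# Quietly assemble a faers_cases object from row builders.
make_cases <- function(demo, drug = NULL, reac = NULL, outc = NULL,
                       ther = NULL, indi = NULL) {
  suppressMessages(assemble_cases(list(
    demo = demo, drug = drug, reac = reac, outc = outc, ther = ther,
    indi = indi)))
}

test_cohort_config <- function() example_cohort_config()

# Write a $-delimited FAERS file from a character matrix of rows.
write_faers_fixture <- function(path, header, rows) {
  writeLines(c(header, rows), path)
  path
}

# Large simulation shared across test files (computed once per run).
.sim_cache <- new.env(parent = emptyenv())

big_sim_tallies <- function() {
  if (is.null(.sim_cache$big)) {
    dir <- file.path(tempdir(), "faersignal-big-sim")
    cfg <- synthetic_config(n_background_cases = 150000,
                            n_drug_cases = 40000,
                            duplicate_rate = 0, n_quarters = 4,
                            seed = 424242)
    sim <- simulate_faers(cfg, dir)
    tabs <- suppressWarnings(read_faers_tables(dir))
    cases <- suppressMessages(assemble_cases(tabs))
    co <- example_cohort_config()
    drug <- select_drug_cases(cases, co)
    bg <- select_background_cases(cases, co)
    .sim_cache$big <- list(
      config = cfg, truth = sim$truth,
      drug_tally = pt_event_tally(drug),
      background_tally = pt_event_tally(bg))
  }
  .sim_cache$big
}
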