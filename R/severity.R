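#' Yates-corrected chi-squared test for a 2x2 table
#'
#' Continuity-corrected Pearson chi-squared statistic
#' `N (|ad - bc| - N/2)^2 / (R1 R2 C1 C2)` with the correction clamped at
#' zero when `|ad - bc| < N/2`, and its p-value on 1 degree of freedom
#' (delegated to [stats::chisq.test()] with `correct = TRUE`, which
#' implements exactly this statistic).
#'
#' @param a,b,c,d cell counts, rows = attribute levels, columns =
#'   serious/nonserious.
#' @return one-row tibble `test`, `statistic`, `p_value`; a zero marginal
#'   yields an `NA` row with the error message in `error`.
#' @export
yates_chi2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(tibble(test = "pearson_yates", statistic = NA_real_,
                  p_value = NA_real_, error = "zero marginal"))
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
  tibble(test = "pearson_yates", statistic = unname(res$statistic),
         p_value = res$p.value, error = NA_character_)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities, at
#' the observed margins, of all tables no more probable than the observed
#' one (the point-probability rule of [stats::fisher.test()]).
#'
#' @inheritParams yates_chi2
#' @return one-row tibble `test`, `statistic` (`NA`; Fisher reports no
#'   statistic), `p_value`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  res <- stats::fisher.test(m)
  tibble(test = "fisher", statistic = NA_real_, p_value = res$p.value,
         error = NA_character_)
}

#' Compare a continuous variable between serious and nonserious cases
#'
#' Returns both the pooled-variance two-sample t statistic and the
#' two-sided Mann--Whitney p-value (exact for small tie-free samples,
#' otherwise the tie-corrected normal approximation of
#' [stats::wilcox.test()]).
#'
#' @param x_serious,x_nonserious numeric vectors (each of length >= 2
#'   after NA removal).
#' @return two-row tibble (`t_test`, `mann_whitney`) with `statistic` and
#'   `p_value`.
#' @export
compare_continuous <- function(x_serious, x_nonserious) {
  x <- x_serious[!is.na(x_serious)]
  y <- x_nonserious[!is.na(x_nonserious)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 non-missing values", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  exact <- (length(x) + length(y)) <= 20 && !any(duplicated(c(x, y)))
  mw <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = FALSE))
  bind_rows(
    tibble(test = "t_test", statistic = unname(tt$statistic),
           p_value = tt$p.value),
    tibble(test = "mann_whitney", statistic = unname(mw$statistic),
           p_value = mw$p.value)
  )
}

#' Serious vs nonserious comparison table
#'
#' For each PT: counts of serious and nonserious cases mentioning it, and
#' a test of the PT-by-seriousness 2x2 against the rest of the cohort.
#' The test is Fisher's exact when any expected cell is below 5,
#' otherwise the Yates-corrected chi-squared. Demographic comparisons
#' (sex 2x2 by the same rule; age and weight via
#' [compare_continuous()]) are returned alongside.
#'
#' @param cases `faers_cases` cohort with serious flags.
#' @param pt_list optional character vector restricting/ordering the PT
#'   rows; defaults to every PT in the cohort, by descending total count.
#' @return list with tibbles `ae_rows` (`pt`, `n_serious`,
#'   `n_nonserious`, `test`, `statistic`, `p_value`) and
#'   `demographic_rows` (`variable`, `test`, `statistic`, `p_value`).
#' @export
build_severity_table <- function(cases, pt_list = NULL) {
  demo <- cases$demo
  n_serious_total <- sum(demo$serious)
  n_nonserious_total <- sum(!demo$serious)
  reac <- distinct(cases$reac, .data$primaryid, pt = norm_text(.data$pt)) %>%
    left_join(select(demo, "primaryid", "serious"), by = "primaryid")
  if (is.null(pt_list)) {
    pt_list <- reac %>% count(.data$pt, sort = TRUE) %>% pull("pt")
  } else {
    pt_list <- intersect(norm_text(pt_list), unique(reac$pt))
  }
  ae_rows <- bind_rows(lapply(pt_list, function(pt) {
    sub <- reac[reac$pt == pt, ]
    ns <- sum(sub$serious)
    nn <- sum(!sub$serious)
    res <- select_2x2_test(ns, nn, n_serious_total - ns,
                           n_nonserious_total - nn)
    tibble(pt = pt, n_serious = ns, n_nonserious = nn,
           test = res$test, statistic = res$statistic,
           p_value = res$p_value)
  }))

  sex_counts <- table(factor(demo$sex, levels = c("F", "M")),
                      factor(demo$serious, levels = c(TRUE, FALSE)))
  sex_res <- select_2x2_test(sex_counts[1, 1], sex_counts[1, 2],
                             sex_counts[2, 1], sex_counts[2, 2])
  age <- age_to_years(demo$age, demo$age_cod)
  wt <- weight_to_kg(demo$wt, demo$wt_cod)
  demographic_rows <- bind_rows(
    tibble(variable = "sex", test = sex_res$test,
           statistic = sex_res$statistic, p_value = sex_res$p_value),
    mutate(try_compare(age[demo$serious], age[!demo$serious]),
           variable = "age_years", .before = 1),
    mutate(try_compare(wt[demo$serious], wt[!demo$serious]),
           variable = "weight_kg", .before = 1)
  )
  list(ae_rows = ae_rows, demographic_rows = demographic_rows)
}

try_compare <- function(x, y) {
  tryCatch(compare_continuous(x, y), error = function(e) {
    tibble(test = c("t_test", "mann_whitney"), statistic = NA_real_,
           p_value = NA_real_)
  })
}

# Standard selection rule: Fisher when any expected cell < 5, else
# Yates-corrected chi-squared.
select_2x2_test <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  n <- sum(m)
  if (n == 0 || any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(fisher_exact_2x2(a, b, c, d))
  }
  expected <- outer(rowSums(m), colSums(m)) / n
  if (any(expected < 5)) fisher_exact_2x2(a, b, c, d)
  else yates_chi2(a, b, c, d)
}
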