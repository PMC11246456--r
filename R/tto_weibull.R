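#' Compute time-to-onset for a suspect-drug cohort
#'
#' TTO is the number of whole days between the adverse-event onset date
#' (`event_dt`, DEMO) and the start of the suspect drug's therapy
#' (`start_dt`, THER). Both dates must be full-precision calendar dates;
#' when several therapy rows exist for the suspect drug, the earliest
#' start is used. A TTO of 0 means the event occurred on the first day
#' of therapy. Negative values (date errors) are expected to have been
#' dropped by [apply_exclusions()]; any survivors are removed here with
#' a warning.
#'
#' @param cases `faers_cases` cohort.
#' @param config a [cohort_config()] identifying the suspect drug.
#' @return tibble with columns `primaryid` and `tto_days` (one row per
#'   case with computable TTO).
#' @export
compute_tto <- function(cases, config) {
  start <- suspect_start_dates(cases, config)
  out <- cases$demo %>%
    select("primaryid", "event_dt") %>%
    inner_join(start, by = "primaryid") %>%
    mutate(event_date = faers_date_to_date(.data$event_dt),
           tto_days = as.numeric(.data$event_date - .data$start_date)) %>%
    filter(!is.na(.data$tto_days))
  if (any(out$tto_days < 0)) {
    warning(sum(out$tto_days < 0),
            " negative TTO value(s) dropped (date errors)")
    out <- out[out$tto_days >= 0, , drop = FALSE]
  }
  select(out, "primaryid", "tto_days")
}

#' Median and quartiles of a TTO sample
#'
#' Quartiles use the linear-interpolation convention
#' ([stats::quantile()] type 7); min and max are exact.
#'
#' @param x numeric vector of onset delays in days.
#' @return list with `median`, `q1`, `q3`, `min`, `max`, `n`.
#' @export
median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("empty TTO sample", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], min = min(x), max = max(x),
       n = length(x))
}

#' Fit a two-parameter Weibull to time-to-onset data by maximum likelihood
#'
#' The shape parameter solves the profile score equation
#' `1/beta + mean(log x) - sum(x^beta log x)/sum(x^beta) = 0` on a
#' bracketed root (tolerance 1e-8); the scale then has the closed form
#' `alpha = (mean(x^beta))^(1/beta)`. 95% confidence intervals are Wald
#' intervals on the log-parameter scale from the observed information
#' (numerical Hessian of the log-likelihood at the MLE), back-
#' transformed. Zero-day onsets are incompatible with the Weibull
#' density; by default they are shifted to 0.5 days for fitting
#' (`zero_policy = "shift"`), or dropped (`"drop"`). Raw values should
#' always be used for medians/IQRs.
#'
#' @param x numeric vector of onset delays in days (>= 0).
#' @param zero_policy how to handle zero-day values before fitting.
#' @param shift replacement value for zeros under `"shift"` (days).
#' @param conf_level confidence level for the Wald intervals.
#' @return a `weibull_fit` list: `alpha`, `alpha_ci`, `beta`, `beta_ci`,
#'   `failure_type`, `n_used`, `n_zero`, `loglik`.
#' @export
fit_weibull_mle <- function(x, zero_policy = c("shift", "drop"),
                            shift = 0.5, conf_level = 0.95) {
  zero_policy <- match.arg(zero_policy)
  x <- x[!is.na(x)]
  if (any(x < 0)) stop("negative TTO values", call. = FALSE)
  n_zero <- sum(x == 0)
  x <- switch(zero_policy,
              shift = ifelse(x == 0, shift, x),
              drop = x[x > 0])
  if (length(x) < 10) {
    stop("need at least 10 positive TTO values to fit (got ",
         length(x), ")", call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("degenerate sample: all TTO values equal", call. = FALSE)
  }
  lx <- log(x)
  mean_lx <- mean(lx)
  score <- function(beta) {
    xb <- x^beta
    1 / beta + mean_lx - sum(xb * lx) / sum(xb)
  }
  # score is strictly decreasing in beta; expand a bracket then solve
  lo <- 1e-3; hi <- 1
  while (score(hi) > 0 && hi < 1e4) hi <- hi * 2
  if (score(lo) < 0 || score(hi) > 0) {
    stop("Weibull shape root not bracketed in [", lo, ", ", hi,
         "]; score(lo)=", signif(score(lo), 3),
         ", score(hi)=", signif(score(hi), 3), call. = FALSE)
  }
  beta <- stats::uniroot(score, c(lo, hi), tol = 1e-10)$root
  alpha <- mean(x^beta)^(1 / beta)

  n <- length(x)
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -(n * log(b) - n * b * log(a) + (b - 1) * sum(lx) - sum((x / a)^b))
  }
  hess <- stats::optimHess(c(log(alpha), log(beta)), nll)
  vc <- tryCatch(solve(hess), error = function(e) NULL)
  if (is.null(vc) || any(diag(vc) <= 0)) {
    stop("observed information not positive definite; fit diagnostics: ",
         "alpha=", signif(alpha, 4), " beta=", signif(beta, 4),
         call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(diag(vc))
  alpha_ci <- exp(log(alpha) + c(-1, 1) * z * se[1])
  beta_ci <- exp(log(beta) + c(-1, 1) * z * se[2])
  fit <- structure(list(
    alpha = alpha, alpha_ci = alpha_ci,
    beta = beta, beta_ci = beta_ci,
    n_used = n, n_zero = n_zero,
    loglik = -nll(c(log(alpha), log(beta))),
    conf_level = conf_level
  ), class = "weibull_fit")
  fit$failure_type <- classify_failure(fit)
  fit
}

#' Classify the hazard trend from a Weibull shape parameter
#'
#' The Weibull shape-parameter (WSP) test: `"early"` failure (hazard
#' decreasing over time) when beta < 1 and the CI upper bound < 1;
#' `"wear_out"` (hazard increasing) when beta > 1 and the CI lower bound
#' > 1; `"random"` (roughly constant hazard) when the CI includes 1.
#'
#' @param fit a `weibull_fit`, or a numeric shape estimate (then `ci`
#'   must be given).
#' @param ci length-2 numeric CI for the shape, when `fit` is numeric.
#' @return `"early"`, `"random"` or `"wear_out"`.
#' @export
classify_failure <- function(fit, ci = NULL) {
  if (inherits(fit, "weibull_fit")) {
    beta <- fit$beta; ci <- fit$beta_ci
  } else {
    beta <- fit
    if (is.null(ci)) stop("ci required when fit is numeric", call. = FALSE)
  }
  if (beta < 1 && ci[2] < 1) "early"
  else if (beta > 1 && ci[1] > 1) "wear_out"
  else "random"
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "<weibull_fit> n=%d  alpha=%.2f (%.2f-%.2f)  beta=%.3f (%.3f-%.3f)  %s\n",
    x$n_used, x$alpha, x$alpha_ci[1], x$alpha_ci[2],
    x$beta, x$beta_ci[1], x$beta_ci[2], x$failure_type))
  invisible(x)
}

#' Pooled TTO summary and Weibull fit per priority band
#'
#' Mirrors the two-row moderate/weak TTO table: for each priority level
#' present among the scored signals, pools the TTO values of all distinct
#' cohort cases mentioning any PT of that level (a case is counted once
#' per level even when it carries several of its PTs), then summarizes
#' with median/IQR on the raw values and fits the Weibull.
#'
#' @param cases `faers_cases` cohort.
#' @param config a [cohort_config()].
#' @param priorities output of [prioritize_screen()].
#' @param ... passed to [fit_weibull_mle()].
#' @return tibble with one row per priority level: `group`, `n_pts`,
#'   `n_cases`, `median`, `q1`, `q3`, `min`, `max`, `alpha`,
#'   `alpha_low`, `alpha_high`, `beta`, `beta_low`, `beta_high`,
#'   `failure_type` (fit columns `NA` when too few values).
#' @export
tto_group_summary <- function(cases, config, priorities, ...) {
  tto <- compute_tto(cases, config)
  reac <- distinct(cases$reac, .data$primaryid, pt = norm_text(.data$pt))
  rows <- lapply(intersect(c("strong", "moderate", "weak"),
                           unique(priorities$level)), function(lev) {
    pts <- priorities$pt[priorities$level == lev]
    ids <- unique(reac$primaryid[reac$pt %in% pts])
    vals <- tto$tto_days[tto$primaryid %in% ids]
    base <- tibble(group = lev, n_pts = length(pts), n_cases = length(vals))
    if (length(vals) == 0) {
      return(mutate(base, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                    min = NA_real_, max = NA_real_, alpha = NA_real_,
                    alpha_low = NA_real_, alpha_high = NA_real_,
                    beta = NA_real_, beta_low = NA_real_,
                    beta_high = NA_real_, failure_type = NA_character_))
    }
    s <- median_iqr(vals)
    fit <- tryCatch(fit_weibull_mle(vals, ...), error = function(e) NULL)
    mutate(base,
           median = s$median, q1 = s$q1, q3 = s$q3, min = s$min, max = s$max,
           alpha = if (is.null(fit)) NA_real_ else fit$alpha,
           alpha_low = if (is.null(fit)) NA_real_ else fit$alpha_ci[1],
           alpha_high = if (is.null(fit)) NA_real_ else fit$alpha_ci[2],
           beta = if (is.null(fit)) NA_real_ else fit$beta,
           beta_low = if (is.null(fit)) NA_real_ else fit$beta_ci[1],
           beta_high = if (is.null(fit)) NA_real_ else fit$beta_ci[2],
           failure_type = if (is.null(fit)) NA_character_
                          else fit$failure_type)
  })
  bind_rows(rows)
}
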