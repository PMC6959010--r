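#' Two-group log-rank test
#'
#' Standard two-group log-rank comparison via [survival::survdiff()].
#'
#' @param time positive follow-up times.
#' @param event event indicator (0 = censored, 1 = event).
#' @param group two-level group per subject.
#' @return list with `statistic` (chi-square, 1 df) and `p_value`.
#' @export
logrank <- function(time, event, group) {
  assert_that(all(time > 0), "times must be positive")
  assert_that(all(event %in% c(0, 1)), "event must be 0/1")
  group <- as.factor(group)
  assert_that(nlevels(droplevels(group)) == 2, "need exactly two non-empty groups")
  if (sum(event) == 0) {
    stop_cncl("cncl_validation_error", "no events: log-rank test undefined")
  }
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(statistic = unname(sd_fit$chisq),
       p_value = pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE))
}

#' Multiple-cutoff log-rank scan over a continuous score
#'
#' Dichotomizes a continuous biomarker (the stemness score `delta_r`) at a
#' grid of candidate cutoffs — score percentiles by default — and runs a
#' two-group log-rank test at each cutoff where both groups retain at least
#' `min_group_frac` of the cohort. The best cutoff is the one with the
#' smallest p-value. Because minimizing p over cutoffs is a multiple-testing
#' procedure, an optional permutation adjustment is provided: scores are
#' permuted against (time, event) and the minimum p recomputed, giving
#' `adjusted_p = (1 + #(perm min p <= observed)) / (1 + permutations)`.
#'
#' @param records data.frame with columns `time`, `event`, `delta_r`.
#' @param probs percentile grid for candidate cutoffs (default 10th-90th in
#'   steps of 5).
#' @param min_group_frac minimum fraction of the cohort required in each
#'   group at an admissible cutoff (default 0.1).
#' @param permutations permutation replicates for the adjusted p (0 = skip).
#' @param seed RNG seed for the permutations.
#' @return list of class `cncl_lrmc`: `table` (per-cutoff data.frame with
#'   `cutoff`, `n_high`, `n_low`, `statistic`, `p_value`), `best_cutoff`,
#'   `best_p`, `adjusted_p` (or `NA` when `permutations = 0`).
#' @export
lrmc_scan <- function(records, probs = seq(0.10, 0.90, by = 0.05),
                      min_group_frac = 0.1, permutations = 0, seed = 1L) {
  assert_that(all(c("time", "event", "delta_r") %in% names(records)),
              "records needs columns time, event, delta_r")
  assert_that(length(unique(records$delta_r)) >= 2,
              "need >= 2 distinct delta_r values")
  n <- nrow(records)

  scan_min_p <- function(delta_r, return_table = FALSE) {
    cutoffs <- unique(as.numeric(quantile(delta_r, probs = probs, type = 7)))
    rows <- lapply(cutoffs, function(ct) {
      high <- delta_r > ct
      n_high <- sum(high)
      n_low <- n - n_high
      if (min(n_high, n_low) < min_group_frac * n) return(NULL)
      if (sum(records$event) == 0) return(NULL)
      lr <- tryCatch(
        logrank(records$time, records$event,
                ifelse(high, "high", "low")),
        cncl_error = function(e) NULL
      )
      if (is.null(lr)) return(NULL)
      data.frame(cutoff = ct, n_high = n_high, n_low = n_low,
                 statistic = lr$statistic, p_value = lr$p_value)
    })
    tab <- do.call(rbind, Filter(Negate(is.null), rows))
    if (return_table) return(tab)
    if (is.null(tab)) NA_real_ else min(tab$p_value)
  }

  tab <- scan_min_p(records$delta_r, return_table = TRUE)
  if (is.null(tab)) {
    stop_cncl("cncl_validation_error",
              "no candidate cutoff satisfies the group-size constraint")
  }
  best <- which.min(tab$p_value)
  adjusted_p <- NA_real_
  if (permutations > 0) {
    obs <- tab$p_value[best]
    perm_min <- with_seed(seed, vapply(seq_len(permutations), function(i) {
      scan_min_p(sample(records$delta_r))
    }, numeric(1)))
    perm_min <- perm_min[!is.na(perm_min)]
    adjusted_p <- (1 + sum(perm_min <= obs)) / (1 + length(perm_min))
  }
  structure(
    list(table = tab, best_cutoff = tab$cutoff[best], best_p = tab$p_value[best],
         adjusted_p = adjusted_p, probs = probs,
         min_group_frac = min_group_frac),
    class = "cncl_lrmc"
  )
}

#' @export
print.cncl_lrmc <- function(x, ...) {
  cat("Multiple-cutoff log-rank scan\n")
  cat("  candidate cutoffs:", nrow(x$table), "\n")
  cat("  best cutoff:      ", format(x$best_cutoff, digits = 4), "\n")
  cat("  best (naive) p:   ", format(x$best_p, digits = 4), "\n")
  if (!is.na(x$adjusted_p)) {
    cat("  permutation p:    ", format(x$adjusted_p, digits = 4), "\n")
  }
  invisible(x)
}

#' Multivariate Cox proportional-hazards regression
#'
#' Fits [survival::coxph()] for the supplied right-hand-side covariates
#' (typically the score-derived phenotype group plus clinical parameters)
#' and returns per-covariate hazard ratios with confidence intervals.
#'
#' @param records data.frame with `time`, `event` and covariate columns.
#' @param covariates character vector of covariate column names, or a
#'   one-sided formula (e.g. `~ group + stage`).
#' @param conf_level confidence level for the hazard-ratio CIs.
#' @return data.frame with `term`, `hr`, `ci_lower`, `ci_upper`, `p_value`.
#' @export
cox_multivariate <- function(records, covariates, conf_level = 0.95) {
  assert_that(all(c("time", "event") %in% names(records)),
              "records needs columns time and event")
  if (inherits(covariates, "formula")) {
    rhs <- attr(stats::terms(covariates), "term.labels")
  } else {
    rhs <- covariates
  }
  assert_that(length(rhs) >= 1, "need at least one covariate")
  missing_cov <- setdiff(unique(unlist(lapply(rhs, function(x) all.vars(str2lang(x))))),
                         names(records))
  assert_that(length(missing_cov) == 0, "covariate column(s) not found: %s",
              paste(missing_cov, collapse = ", "))
  n_events <- sum(records$event)
  if (n_events == 0) {
    stop_cncl("cncl_validation_error", "no events: Cox model undefined")
  }
  assert_that(n_events >= length(rhs),
              "fewer events (%d) than covariates (%d)", n_events, length(rhs))
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(rhs, collapse = " + ")))
  fit <- withCallingHandlers(
    tryCatch(survival::coxph(f, data = records),
             error = function(e) {
               stop_cncl("cncl_fit_failure_error",
                         "Cox model failed: %s", conditionMessage(e))
             }),
    warning = function(w) {
      if (grepl("did not converge|infinite|Loglik converged", conditionMessage(w))) {
        stop_cncl("cncl_fit_failure_error",
                  "Cox model did not converge cleanly: %s", conditionMessage(w))
      }
      invokeRestart("muffleWarning")
    }
  )
  s <- summary(fit, conf.int = conf_level)
  coefs <- s$coefficients
  ci <- s$conf.int
  data.frame(
    term = rownames(coefs),
    hr = unname(coefs[, "exp(coef)"]),
    ci_lower = unname(ci[, 3]),
    ci_upper = unname(ci[, 4]),
    p_value = unname(coefs[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
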