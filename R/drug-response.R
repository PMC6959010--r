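# Six-model logistic dose-response ensemble.
#
# Every model is the four-parameter logistic
#   v(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)
# with constraints per model id. The "3 parameter" family fixes hill = 1
# (so "3 parameter Top 100" has two free parameters, etc.); the model set is
# configurable. The curve midpoint ic50 is fitted on the log10 scale.

DR_MODELS <- list(
  "3P"          = list(hill_fixed = TRUE,  top_fixed = FALSE, bottom_fixed = FALSE),
  "3P_top100"   = list(hill_fixed = TRUE,  top_fixed = TRUE,  bottom_fixed = FALSE),
  "3P_bottom0"  = list(hill_fixed = TRUE,  top_fixed = FALSE, bottom_fixed = TRUE),
  "4P"          = list(hill_fixed = FALSE, top_fixed = FALSE, bottom_fixed = FALSE),
  "4P_top100"   = list(hill_fixed = FALSE, top_fixed = TRUE,  bottom_fixed = FALSE),
  "4P_bottom0"  = list(hill_fixed = FALSE, top_fixed = FALSE, bottom_fixed = TRUE)
)

dr_n_free <- function(spec) {
  1L + (!spec$hill_fixed) + (!spec$top_fixed) + (!spec$bottom_fixed)
}

# Fit one constrained logistic model by Levenberg-Marquardt least squares.
# Returns NULL when the fit does not converge.
fit_one_model <- function(model_id, dose, v, hill_starts = c(0.5, 1, 2)) {
  spec <- DR_MODELS[[model_id]]
  n <- length(v)
  p <- dr_n_free(spec)
  if (n <= p) return(NULL)
  bottom0 <- if (spec$bottom_fixed) 0 else min(v)
  top0 <- if (spec$top_fixed) 100 else max(v)
  half <- (top0 + bottom0) / 2
  lic0 <- log10(dose[which.min(abs(v - half))])
  if (spec$hill_fixed) hill_starts <- 1

  make_pred <- function(par) {
    bottom <- if (spec$bottom_fixed) 0 else par[["bottom"]]
    top <- if (spec$top_fixed) 100 else par[["top"]]
    hill <- if (spec$hill_fixed) 1 else exp(par[["lhill"]])
    logistic4(dose, bottom, top, 10^par[["lic50"]], hill)
  }
  best <- NULL
  for (h0 in hill_starts) {
    start <- c(lic50 = lic0)
    if (!spec$bottom_fixed) start <- c(start, bottom = bottom0)
    if (!spec$top_fixed) start <- c(start, top = top0)
    if (!spec$hill_fixed) start <- c(start, lhill = log(h0))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = function(par) v - make_pred(par),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(NULL)
  par <- best$fit$par
  bottom <- if (spec$bottom_fixed) 0 else par[["bottom"]]
  top <- if (spec$top_fixed) 100 else par[["top"]]
  hill <- if (spec$hill_fixed) 1 else exp(par[["lhill"]])
  ic50 <- 10^par[["lic50"]]
  if (!all(is.finite(c(bottom, top, hill, ic50)))) return(NULL)
  list(
    model_id = model_id,
    params = c(bottom = bottom, top = top, ic50 = ic50, hill = hill),
    rss = best$rss,
    residual_se = sqrt(best$rss / (n - p)),
    n = n, n_free = p, converged = TRUE
  )
}

#' Fit a dose-response curve with the six-model logistic ensemble
#'
#' Fits each model of the ensemble (by default all six: hill free or fixed at
#' 1, crossed with unconstrained / top fixed at 100% / bottom fixed at 0%) by
#' nonlinear least squares with the midpoint on the log10-dose scale, and
#' selects the converged model with the lowest residual standard error
#' `sqrt(RSS / (n - p))`; that model supplies the IC50 (the fitted curve
#' midpoint, i.e. relative IC50) and is returned alongside all fits. A fitted
#' IC50 beyond the highest tested dose is flagged as right-censored
#' (`ic50_censored`), reported as "> max dose". If no model converges but the
#' data show no inhibition below 50% viability, a flat non-converged fit with
#' a censored IC50 is returned instead of an error.
#'
#' @param dose positive concentrations (uM), replicated entries allowed;
#'   at least 4 distinct doses.
#' @param viability_pct percent viability, same length as `dose`.
#' @param models subset of
#'   `c("3P","3P_top100","3P_bottom0","4P","4P_top100","4P_bottom0")`.
#' @return list of class `cncl_dose_fit`: `model_id`, `params` (bottom, top,
#'   ic50, hill), `residual_se`, `ic50`, `ic50_censored`, `activity_area`
#'   (from the observed viabilities, see [activity_area()]), `converged`, and
#'   `all_fits` (per-model results).
#' @export
fit_dose_response <- function(dose, viability_pct, models = names(DR_MODELS)) {
  assert_that(length(dose) == length(viability_pct),
              "dose and viability_pct lengths differ")
  assert_that(all(dose > 0), "doses must be positive")
  assert_that(length(unique(dose)) >= 4, "need >= 4 distinct doses")
  assert_that(all(is.finite(viability_pct)), "viability values must be finite")
  assert_that(all(models %in% names(DR_MODELS)),
              "unknown model id(s): %s",
              paste(setdiff(models, names(DR_MODELS)), collapse = ", "))
  fits <- lapply(models, fit_one_model, dose = dose, v = viability_pct)
  names(fits) <- models
  fits <- Filter(Negate(is.null), fits)
  max_dose <- max(dose)
  aa <- activity_area(data.frame(dose_uM = dose, viability_pct = viability_pct))
  if (length(fits) == 0) {
    if (min(tapply(viability_pct, dose, mean)) > 50) {
      # no inhibition reaching the midpoint: report a flat curve, IC50 censored
      return(structure(
        list(model_id = NA_character_,
             params = c(bottom = mean(viability_pct), top = mean(viability_pct),
                        ic50 = Inf, hill = 1),
             residual_se = sd(viability_pct), ic50 = Inf, ic50_censored = TRUE,
             ic50_label = sprintf("> %g", max_dose),
             activity_area = aa, converged = FALSE, all_fits = list()),
        class = "cncl_dose_fit"
      ))
    }
    stop_cncl("cncl_fit_failure_error", "no dose-response model converged")
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "residual_se"))]]
  ic50 <- unname(best$params[["ic50"]])
  # a near-zero span between asymptotes means the midpoint is unidentified
  flat <- abs(best$params[["top"]] - best$params[["bottom"]]) < 1e-3
  if (flat) ic50 <- Inf
  censored <- ic50 > max_dose
  structure(
    list(model_id = best$model_id, params = best$params,
         residual_se = best$residual_se, ic50 = ic50,
         ic50_censored = censored,
         ic50_label = if (censored) sprintf("> %g", max_dose) else
           format(ic50, digits = 6),
         activity_area = aa, converged = TRUE, all_fits = fits),
    class = "cncl_dose_fit"
  )
}

#' @export
print.cncl_dose_fit <- function(x, ...) {
  cat("Dose-response fit\n")
  cat("  model:       ", x$model_id, "\n")
  cat("  IC50 (uM):   ", x$ic50_label, if (x$ic50_censored) " (censored)", "\n",
      sep = "")
  cat("  activity area:", format(x$activity_area, digits = 4), "\n")
  cat("  residual SE: ", format(x$residual_se, digits = 4), "\n")
  invisible(x)
}

#' Activity area of a dose-viability profile
#'
#' Summarizes overall drug activity across the tested dose range as the mean
#' per-dose inhibition, `AA = (1/n) * sum(max(0, 1 - viability/100))` over
#' the distinct doses (replicates averaged per dose first), in `[0, 1]`; 0
#' means no inhibition anywhere, 1 complete kill everywhere. The
#' `"trapezoid"` method instead integrates inhibition over log10 dose
#' (trapezoidal rule) normalized by the log-dose range.
#'
#' @param x data.frame with columns `dose_uM` and `viability_pct` (a
#'   `generate_dose_response()` table works directly), or a numeric viability
#'   vector with `doses` supplied.
#' @param doses doses matching `x` when `x` is a plain vector.
#' @param method `"mean"` (default) or `"trapezoid"`.
#' @return activity area in `[0, 1]`.
#' @export
activity_area <- function(x, doses = NULL, method = c("mean", "trapezoid")) {
  method <- match.arg(method)
  if (is.data.frame(x)) {
    assert_that(all(c("dose_uM", "viability_pct") %in% names(x)),
                "data.frame input needs columns dose_uM and viability_pct")
    doses <- x$dose_uM
    v <- x$viability_pct
  } else {
    v <- x
    assert_that(!is.null(doses) && length(doses) == length(v),
                "doses must accompany a viability vector")
  }
  mean_v <- tapply(v, doses, mean)
  d <- as.numeric(names(mean_v))
  ord <- order(d)
  d <- d[ord]
  inhib <- pmax(0, 1 - as.numeric(mean_v)[ord] / 100)
  if (method == "mean") return(mean(inhib))
  ld <- log10(d)
  sum(diff(ld) * (head(inhib, -1) + inhib[-1]) / 2) / (max(ld) - min(ld))
}

#' Screen drugs for phenotype-differential cytotoxicity
#'
#' For every drug, compares a per-cell-line sensitivity metric (activity area
#' or IC50) between CS/M and NS/E cell lines with a Welch t-test, and reports
#' which phenotype is more sensitive. For activity area higher values mean
#' more sensitive; for IC50 lower values do — set `higher_is_sensitive`
#' accordingly.
#'
#' @param sensitivity long data.frame with columns `drug`, `cell_line`, and
#'   the metric column named by `metric`.
#' @param calls phenotype calls: data.frame with `sample_id` and `label`
#'   (cell-line ids matching `cell_line`), e.g. from [classify_phenotype()].
#' @param metric name of the metric column (default `"activity_area"`).
#' @param higher_is_sensitive `TRUE` for activity-area-like metrics (default),
#'   `FALSE` for IC50-like metrics.
#' @param alpha significance level used for the `significant` flag.
#' @return data.frame ordered by p-value with `drug`, `n_csm`, `n_nse`,
#'   `mean_csm`, `mean_nse`, `statistic`, `p_value`, `more_sensitive`
#'   (`"CS/M"` or `"NS/E"`), `significant`.
#' @export
screen_differential_drugs <- function(sensitivity, calls,
                                      metric = "activity_area",
                                      higher_is_sensitive = TRUE,
                                      alpha = 0.05) {
  assert_that(all(c("drug", "cell_line", metric) %in% names(sensitivity)),
              "sensitivity table needs columns drug, cell_line, %s", metric)
  labels <- setNames(calls$label, calls$sample_id)
  rows <- lapply(split(sensitivity, sensitivity$drug), function(tbl) {
    lab <- labels[tbl$cell_line]
    val <- tbl[[metric]]
    ok <- !is.na(val) & lab %in% c("CS/M", "NS/E")
    a <- val[ok & lab == "CS/M"]
    b <- val[ok & lab == "NS/E"]
    if (length(a) < 2 || length(b) < 2) {
      warning(sprintf("drug '%s' skipped: < 2 cell lines per phenotype",
                      tbl$drug[1]), call. = FALSE)
      return(NULL)
    }
    w <- welch_t_test(a, b)
    d <- mean(a) - mean(b)
    sens <- if (xor(d > 0, !higher_is_sensitive)) "CS/M" else "NS/E"
    data.frame(drug = tbl$drug[1], n_csm = length(a), n_nse = length(b),
               mean_csm = mean(a), mean_nse = mean(b),
               statistic = w$statistic, p_value = w$p_value,
               more_sensitive = if (d == 0) NA_character_ else sens,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    stop_cncl("cncl_validation_error",
              "no drug had >= 2 cell lines per phenotype")
  }
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}
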