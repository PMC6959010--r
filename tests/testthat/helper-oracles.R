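# Independent oracles used to cross-check the implementation. These are
# deliberately naive (enumeration, textbook formulas, grid search) and share
# no code with the package internals they validate.

# --- complete-linkage agglomeration by exhaustive pair search -----------------
# Returns merge heights and the partition (list of index sets) after each
# merge; partition with k clusters is partitions[[n - k]].
oracle_complete_linkage <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in 2:length(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- max(dm[clusters[[i]], clusters[[j]]])
        if (is.null(best) || h < best$h) best <- list(i = i, j = j, h = h)
      }
    }
    merged <- c(clusters[[best$j]], clusters[[best$i]])
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
    heights <- c(heights, best$h)
    partitions[[length(partitions) + 1]] <- clusters
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition for label-free comparison
canonical_partition <- function(x) {
  if (!is.list(x)) x <- unname(split(seq_along(x), x))
  sets <- lapply(x, sort)
  sets[order(vapply(sets, `[[`, numeric(1), 1L))]
}

# --- textbook Pearson correlation --------------------------------------------
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# --- median by explicit sorting ----------------------------------------------
oracle_median <- function(x) {
  s <- unname(sort(x))
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# --- Welch t-test from first principles --------------------------------------
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(statistic = t_stat, p_value = 2 * pt(-abs(t_stat), df))
}

# --- two-group log-rank from the O-E / variance sums -------------------------
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  event_times <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (tt in event_times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & g == 1)
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- U^2 / V
  list(statistic = chisq, p_value = pchisq(chisq, df = 1, lower.tail = FALSE))
}

# --- dose-response ensemble by grid search + Nelder-Mead polish --------------
# Refits the same six constrained logistic models independently: coarse grid
# over (log10 ic50, hill) with the linear parameters (bottom/top) solved in
# closed form, then a derivative-free polish. Returns the per-model residual
# standard errors.
oracle_dose_ensemble <- function(dose, v) {
  specs <- list(
    "3P"         = c(hill = TRUE,  top = FALSE, bottom = FALSE),
    "3P_top100"  = c(hill = TRUE,  top = TRUE,  bottom = FALSE),
    "3P_bottom0" = c(hill = TRUE,  top = FALSE, bottom = TRUE),
    "4P"         = c(hill = FALSE, top = FALSE, bottom = FALSE),
    "4P_top100"  = c(hill = FALSE, top = TRUE,  bottom = FALSE),
    "4P_bottom0" = c(hill = FALSE, top = FALSE, bottom = TRUE)
  )
  n <- length(v)
  fit_spec <- function(hill_fixed, top_fixed, bottom_fixed) {
    p <- 1L + (!hill_fixed) + (!top_fixed) + (!bottom_fixed)
    rss_given <- function(lic50, hill) {
      f <- 1 / (1 + (dose / 10^lic50)^hill)
      if (!top_fixed && !bottom_fixed) {
        X <- cbind(1 - f, f); y <- v
      } else if (top_fixed && !bottom_fixed) {
        X <- cbind(1 - f); y <- v - 100 * f
      } else {
        X <- cbind(f); y <- v   # bottom fixed at 0
      }
      beta <- tryCatch(qr.solve(crossprod(X), crossprod(X, y)),
                       error = function(e) NULL)
      if (is.null(beta)) return(Inf)
      sum((y - X %*% beta)^2)
    }
    grid_l <- seq(log10(min(dose)) - 1, log10(max(dose)) + 1, length.out = 80)
    grid_h <- if (hill_fixed) 1 else c(0.25, 0.5, 1, 2, 4)
    best <- list(rss = Inf)
    for (h in grid_h) {
      for (l in grid_l) {
        r <- rss_given(l, h)
        if (r < best$rss) best <- list(rss = r, l = l, h = h)
      }
    }
    if (hill_fixed) {
      opt <- optim(best$l, function(par) rss_given(par[1], 1),
                   method = "Brent",
                   lower = min(grid_l) - 2, upper = max(grid_l) + 2)
    } else {
      opt <- optim(c(best$l, log(best$h)),
                   function(par) rss_given(par[1], exp(par[2])),
                   method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12))
    }
    sqrt(opt$value / (n - p))
  }
  vapply(specs, function(s) fit_spec(s[["hill"]], s[["top"]], s[["bottom"]]),
         numeric(1))
}
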