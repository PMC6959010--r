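#' Welch's unequal-variance two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] with explicit conventions for the
#' degenerate zero-variance cases that arise when screening thousands of
#' genes: two identical constant groups give `t = 0, p = 1`; constant groups
#' with different means give an infinite statistic and the smallest
#' representable positive p.
#'
#' @param group_a,group_b numeric vectors with at least 2 values each.
#' @return list with elements `statistic` (t) and `p_value` (two-sided).
#' @export
welch_t_test <- function(group_a, group_b) {
  assert_that(length(group_a) >= 2 && length(group_b) >= 2,
              "each group needs >= 2 values")
  va <- var(group_a)
  vb <- var(group_b)
  if (va == 0 && vb == 0) {
    d <- mean(group_a) - mean(group_b)
    if (d == 0) return(list(statistic = 0, p_value = 1))
    return(list(statistic = sign(d) * Inf,
                p_value = .Machine$double.xmin))
  }
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Rank differentially expressed genes between two phenotype groups
#'
#' Per-gene Welch t-tests of CS/M versus NS/E on log2-scale data. Genes with
#' `p < initial_p` are ordered by the configured key (p ascending by default,
#' absolute fold descending as an alternative) and truncated to `top_n`.
#' Fold change is computed on the anti-logged group means
#' (`2^|mean difference|`, geometric-mean fold), with the sign of the
#' difference carried as a direction flag.
#'
#' @param mat log2-scale matrix, genes x samples.
#' @param labels phenotype per sample (`"CS/M"`/`"NS/E"`), vector or named
#'   vector.
#' @param top_n maximum number of genes returned (0 gives an empty table).
#' @param initial_p p-value screen applied before ranking.
#' @param order_by `"p"` (default) or `"fold"`.
#' @return data.frame with `feature_id`, `direction`, `log2_diff`, `fold`,
#'   `p_value`, ordered by the ranking key.
#' @export
rank_de_genes <- function(mat, labels, top_n = 200, initial_p = 0.05,
                          order_by = c("p", "fold")) {
  order_by <- match.arg(order_by)
  assert_that(is_count(top_n + 1), "top_n must be a non-negative integer")
  labels <- check_labels(labels, colnames(mat))
  a <- mat[, labels == "CS/M", drop = FALSE]
  b <- mat[, labels == "NS/E", drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) {
    stop_cncl("cncl_validation_error",
              "each phenotype group needs >= 2 samples (CS/M: %d, NS/E: %d)",
              ncol(a), ncol(b))
  }
  res <- t(vapply(seq_len(nrow(mat)), function(i) {
    w <- welch_t_test(a[i, ], b[i, ])
    d <- mean(a[i, ]) - mean(b[i, ])
    c(d, w$p_value)
  }, numeric(2)))
  df <- data.frame(
    feature_id = rownames(mat),
    direction = ifelse(res[, 1] >= 0, "up_in_CS/M", "up_in_NS/E"),
    log2_diff = res[, 1],
    fold = 2^abs(res[, 1]),
    p_value = res[, 2],
    stringsAsFactors = FALSE
  )
  df <- df[df$p_value < initial_p, , drop = FALSE]
  ord <- if (order_by == "p") order(df$p_value, df$feature_id)
         else order(-df$fold, df$feature_id)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  head(df, top_n)
}

#' Parameters for signature derivation
#'
#' Defaults reproduce the published construction: the 200 most differentially
#' expressed genes at p < 0.05 per dataset, then a minimum 3-fold change and
#' p < 0.0002 in both datasets, then a within-arm inter-gene correlation
#' screen (mean absolute pairwise Pearson r >= `min_intercorr`).
#'
#' @param top_n genes retained per dataset after the initial screen.
#' @param initial_p p-value screen before ranking.
#' @param min_fold minimum linear fold change (>= 1) required in both datasets.
#' @param max_p maximum p-value required in both datasets.
#' @param min_intercorr minimum mean absolute pairwise Pearson correlation with
#'   same-direction candidates, required in both datasets; 0 disables.
#' @return a `derivation_params` list.
#' @export
derivation_params <- function(top_n = 200, initial_p = 0.05,
                              min_fold = 3, max_p = 2e-4,
                              min_intercorr = 0.5) {
  assert_that(is_count(top_n + 1), "top_n must be a non-negative integer")
  assert_that(is_number(initial_p) && initial_p > 0 && initial_p <= 1,
              "initial_p must be in (0, 1]")
  assert_that(is_number(max_p) && max_p > 0 && max_p <= initial_p,
              "max_p must satisfy 0 < max_p <= initial_p")
  assert_that(is_number(min_fold) && min_fold >= 1, "min_fold must be >= 1")
  assert_that(is_number(min_intercorr) && min_intercorr >= 0 &&
                min_intercorr <= 1, "min_intercorr must be in [0, 1]")
  structure(list(top_n = as.integer(top_n), initial_p = initial_p,
                 min_fold = min_fold, max_p = max_p,
                 min_intercorr = min_intercorr),
            class = "derivation_params")
}

# Mean absolute pairwise Pearson r of each candidate with the other
# same-direction candidates, within one dataset. Single-gene arms pass
# vacuously (no pairs to be inconsistent with).
arm_intercorr <- function(mat, genes) {
  if (length(genes) < 2) return(setNames(rep(1, length(genes)), genes))
  cm <- abs(cor(t(mat[genes, , drop = FALSE])))
  diag(cm) <- NA
  rowMeans(cm, na.rm = TRUE)
}

#' Derive a directional signature gene list from two labeled datasets
#'
#' Reproduces the CS/M-vs-NS/E signature construction: per dataset, rank the
#' most differentially expressed genes ([rank_de_genes()]); intersect the two
#' lists keeping only features with concordant direction; filter to features
#' with fold change >= `min_fold` and p < `max_p` in both datasets; finally
#' retain features whose mean absolute pairwise correlation with the other
#' retained same-direction features reaches `min_intercorr` in both datasets.
#'
#' @param dataset_a,dataset_b log2-scale matrices sharing a feature id space.
#' @param labels_a,labels_b phenotype labels per sample for each dataset.
#' @param params a [derivation_params()] object.
#' @return data.frame of class `cncl_signature` with columns `feature_id`,
#'   `direction`, `fold_a`, `p_a`, `fold_b`, `p_b`; derivation provenance is
#'   attached as the `provenance` attribute.
#' @export
derive_signature <- function(dataset_a, labels_a, dataset_b, labels_b,
                             params = derivation_params()) {
  assert_that(inherits(params, "derivation_params"),
              "params must come from derivation_params()")
  de_a <- rank_de_genes(dataset_a, labels_a, params$top_n, params$initial_p)
  de_b <- rank_de_genes(dataset_b, labels_b, params$top_n, params$initial_p)

  common <- merge(de_a, de_b, by = "feature_id", suffixes = c("_a", "_b"))
  common <- common[common$direction_a == common$direction_b, , drop = FALSE]
  if (nrow(common) == 0) {
    stop_cncl("cncl_empty_signature_error",
              "no features shared with concordant direction between datasets")
  }
  keep <- common$fold_a >= params$min_fold & common$fold_b >= params$min_fold &
    common$p_value_a < params$max_p & common$p_value_b < params$max_p
  common <- common[keep, , drop = FALSE]
  if (nrow(common) == 0) {
    stop_cncl("cncl_empty_signature_error",
              "no shared features pass the fold/p filters in both datasets")
  }
  if (params$min_intercorr > 0) {
    keep_corr <- rep(TRUE, nrow(common))
    for (dir in unique(common$direction_a)) {
      genes <- common$feature_id[common$direction_a == dir]
      ra <- arm_intercorr(dataset_a, genes)
      rb <- arm_intercorr(dataset_b, genes)
      ok <- ra >= params$min_intercorr & rb >= params$min_intercorr
      keep_corr[match(genes[!ok], common$feature_id)] <- FALSE
    }
    common <- common[keep_corr, , drop = FALSE]
    if (nrow(common) == 0) {
      stop_cncl("cncl_empty_signature_error",
                "no shared features pass the inter-gene correlation screen")
    }
  }
  out <- data.frame(
    feature_id = common$feature_id,
    direction = common$direction_a,
    fold_a = common$fold_a, p_a = common$p_value_a,
    fold_b = common$fold_b, p_b = common$p_value_b,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$direction, out$p_a, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- list(
    params = params,
    n_samples_a = ncol(dataset_a), n_samples_b = ncol(dataset_b)
  )
  class(out) <- c("cncl_signature", "data.frame")
  out
}

#' Combine two enrichment rankings by rank sum
#'
#' Each name's combined score is the sum of its ranks in the two input
#' rankings; output is sorted by rank sum ascending, ties broken
#' lexicographically by name. Used to identify gene sets commonly enriched in
#' two independent enrichment analyses.
#'
#' @param ranking_a,ranking_b numeric rank vectors named by gene-set (or
#'   gene) name; the two name sets must match.
#' @return data.frame with `name`, `rank_a`, `rank_b`, `ranksum`, ordered by
#'   `ranksum` then `name`.
#' @export
rank_sum_combine <- function(ranking_a, ranking_b) {
  assert_that(!is.null(names(ranking_a)) && !is.null(names(ranking_b)),
              "rankings must be named numeric vectors")
  only_a <- setdiff(names(ranking_a), names(ranking_b))
  only_b <- setdiff(names(ranking_b), names(ranking_a))
  if (length(only_a) > 0 || length(only_b) > 0) {
    stop_cncl("cncl_validation_error",
              "rankings cover different names; only in a: {%s}; only in b: {%s}",
              paste(only_a, collapse = ", "), paste(only_b, collapse = ", "))
  }
  nm <- names(ranking_a)
  out <- data.frame(
    name = nm,
    rank_a = as.numeric(ranking_a),
    rank_b = as.numeric(ranking_b[nm]),
    stringsAsFactors = FALSE
  )
  out$ranksum <- out$rank_a + out$rank_b
  out <- out[order(out$ranksum, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
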