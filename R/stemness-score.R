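#' Build median phenotype centroids from a labeled reference dataset
#'
#' For each signature gene, standardizes expression across all reference
#' samples (z-score by default; `center_only = TRUE` gives mean-centering
#' without scaling) and takes the per-group median, yielding one centroid
#' vector for CS/M and one for NS/E. These are the reference "matrices" a new
#' sample's standardized signature profile is correlated against.
#'
#' @param mat log2-scale matrix, genes x samples (reference cohort).
#' @param labels phenotype per sample (`"CS/M"`/`"NS/E"`); other labels are
#'   ignored when taking group medians.
#' @param signature signature gene ids or a `cncl_signature`.
#' @param center_only passed to [standardize_genes()].
#' @return data.frame of class `cncl_centroids` with `gene`, `csm_median`,
#'   `nse_median`; reference group sizes attached as the `source` attribute.
#' @export
build_centroids <- function(mat, labels, signature, center_only = FALSE) {
  genes <- signature_genes(signature)
  sub <- check_signature_present(mat, genes)
  labels <- check_labels(labels, colnames(sub))
  n_csm <- sum(labels == "CS/M")
  n_nse <- sum(labels == "NS/E")
  assert_that(n_csm >= 1 && n_nse >= 1,
              "both reference groups must be non-empty (CS/M: %d, NS/E: %d)",
              n_csm, n_nse)
  z <- standardize_genes(sub, center_only = center_only)
  out <- data.frame(
    gene = genes,
    csm_median = apply(z[, labels == "CS/M", drop = FALSE], 1L, median),
    nse_median = apply(z[, labels == "NS/E", drop = FALSE], 1L, median),
    stringsAsFactors = FALSE
  )
  assert_that(all(is.finite(out$csm_median)) && all(is.finite(out$nse_median)),
              "centroids must be finite")
  rownames(out) <- NULL
  attr(out, "source") <- list(n_csm = n_csm, n_nse = n_nse)
  class(out) <- c("cncl_centroids", "data.frame")
  out
}

#' Categorical call from a stemness score
#'
#' `delta_r > cutoff + band` gives CS/M, `delta_r <= cutoff - band` gives
#' NS/E, values inside the open band give I. With `band_halfwidth = 0` the
#' boundary value itself is called NS/E (scores must exceed the cutoff to be
#' called CS/M). Vectorized over `delta_r`.
#'
#' @param delta_r stemness score(s), the difference CS/M(r) - NS/E(r);
#'   negative values indicate a more NS/E phenotype.
#' @param cutoff decision threshold (default 0).
#' @param band_halfwidth half-width (>= 0) of an indeterminate band around
#'   the cutoff producing I calls.
#' @return character vector of `"CS/M"`, `"NS/E"`, `"I"`.
#' @export
call_from_score <- function(delta_r, cutoff = 0, band_halfwidth = 0) {
  assert_that(is_number(cutoff), "cutoff must be a finite number")
  assert_that(is_number(band_halfwidth) && band_halfwidth >= 0,
              "band_halfwidth must be >= 0")
  ifelse(delta_r > cutoff + band_halfwidth, "CS/M",
         ifelse(delta_r <= cutoff - band_halfwidth, "NS/E", "I"))
}

#' Score one sample against the phenotype centroids
#'
#' Correlates a sample's standardized signature-gene vector with the CS/M and
#' NS/E median centroids (Pearson, across genes), giving `csm_r` and `nse_r`;
#' the stemness score is their difference `delta_r = csm_r - nse_r`, bounded
#' in `[-2, 2]`.
#'
#' @param x named numeric vector of standardized expression over the
#'   signature genes.
#' @param centroids a `cncl_centroids` data.frame.
#' @param cutoff,band_halfwidth passed to [call_from_score()].
#' @return list with `csm_r`, `nse_r`, `delta_r`, `call`.
#' @export
score_sample <- function(x, centroids, cutoff = 0, band_halfwidth = 0) {
  assert_that(inherits(centroids, "cncl_centroids"),
              "centroids must come from build_centroids()")
  assert_that(nrow(centroids) >= 3, "need >= 3 signature genes to correlate")
  assert_that(!is.null(names(x)) && all(centroids$gene %in% names(x)),
              "sample vector must be named by the signature genes")
  x <- x[centroids$gene]
  if (sd(x) == 0) {
    stop_cncl("cncl_degenerate_input_error",
              "constant sample vector: Pearson correlation undefined")
  }
  if (sd(centroids$csm_median) == 0 || sd(centroids$nse_median) == 0) {
    stop_cncl("cncl_configuration_error",
              "constant centroid: Pearson correlation undefined")
  }
  csm_r <- cor(x, centroids$csm_median)
  nse_r <- cor(x, centroids$nse_median)
  delta_r <- csm_r - nse_r
  stopifnot(delta_r >= -2 - 1e-12, delta_r <= 2 + 1e-12)
  list(csm_r = csm_r, nse_r = nse_r, delta_r = delta_r,
       call = call_from_score(delta_r, cutoff, band_halfwidth))
}

#' Score all samples of a cohort against the phenotype centroids
#'
#' Standardizes the cohort's signature submatrix per gene (self-standardized,
#' i.e. against the cohort's own means/sds) and applies [score_sample()] to
#' every sample.
#'
#' @param mat log2-scale matrix, genes x samples.
#' @param centroids a `cncl_centroids` data.frame.
#' @param cutoff,band_halfwidth passed to [call_from_score()].
#' @param standardize z-score the signature submatrix first (set `FALSE` if
#'   `mat` is already standardized).
#' @param center_only passed to [standardize_genes()].
#' @return data.frame of class `cncl_scores` with `sample_id`, `csm_r`,
#'   `nse_r`, `delta_r`, `call`.
#' @export
score_samples <- function(mat, centroids, cutoff = 0, band_halfwidth = 0,
                          standardize = TRUE, center_only = FALSE) {
  assert_that(inherits(centroids, "cncl_centroids"),
              "centroids must come from build_centroids()")
  sub <- check_signature_present(mat, centroids$gene)
  if (standardize) sub <- standardize_genes(sub, center_only = center_only)
  rows <- lapply(colnames(sub), function(s) {
    sc <- score_sample(sub[, s], centroids, cutoff, band_halfwidth)
    data.frame(sample_id = s, csm_r = sc$csm_r, nse_r = sc$nse_r,
               delta_r = sc$delta_r, call = sc$call,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cncl_scores", "data.frame")
  out
}

#' Trace phenotype plasticity across paired conditions
#'
#' Joins pre- and post-condition score tables by a pairing (defaulting to
#' shared sample ids) and flags samples whose categorical call changed. By
#' default pairs where either call is I are excluded from the switch flag
#' (`switched = NA`), since an indeterminate call cannot evidence a switch.
#'
#' @param pre_scores,post_scores `cncl_scores` data.frames (from
#'   [score_samples()]).
#' @param pairing optional data.frame with columns `pre_id`, `post_id`; by
#'   default samples are paired by identical `sample_id`.
#' @param exclude_intermediate if `TRUE` (default), pairs with an I call get
#'   `switched = NA`.
#' @return data.frame with `pre_id`, `post_id`, `pre_call`, `post_call`,
#'   `switched`, `delta_delta_r` (post minus pre score); transition counts
#'   are attached as the `summary` attribute (a table of pre by post call).
#' @export
trace_plasticity <- function(pre_scores, post_scores, pairing = NULL,
                             exclude_intermediate = TRUE) {
  if (is.null(pairing)) {
    pairing <- data.frame(pre_id = pre_scores$sample_id,
                          post_id = pre_scores$sample_id,
                          stringsAsFactors = FALSE)
  }
  assert_that(all(c("pre_id", "post_id") %in% names(pairing)),
              "pairing needs columns pre_id and post_id")
  miss_pre <- setdiff(pairing$pre_id, pre_scores$sample_id)
  miss_post <- setdiff(pairing$post_id, post_scores$sample_id)
  if (length(miss_pre) > 0 || length(miss_post) > 0) {
    stop_cncl("cncl_validation_error",
              "unmatched pair member(s): %s",
              paste(c(miss_pre, miss_post), collapse = ", "))
  }
  i_pre <- match(pairing$pre_id, pre_scores$sample_id)
  i_post <- match(pairing$post_id, post_scores$sample_id)
  out <- data.frame(
    pre_id = pairing$pre_id, post_id = pairing$post_id,
    pre_call = pre_scores$call[i_pre], post_call = post_scores$call[i_post],
    delta_delta_r = post_scores$delta_r[i_post] - pre_scores$delta_r[i_pre],
    stringsAsFactors = FALSE
  )
  out$switched <- out$pre_call != out$post_call
  if (exclude_intermediate) {
    out$switched[out$pre_call == "I" | out$post_call == "I"] <- NA
  }
  out <- out[, c("pre_id", "post_id", "pre_call", "post_call", "switched",
                 "delta_delta_r")]
  attr(out, "summary") <- table(pre = out$pre_call, post = out$post_call)
  out
}
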