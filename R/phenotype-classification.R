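#' Hierarchically cluster samples on the signature genes
#'
#' Restricts the matrix to the signature genes, standardizes each gene
#' (z-score across samples, the convention behind two-block expression
#' heatmaps; disable with `standardize = FALSE`), computes Euclidean
#' distances between samples and applies complete-linkage agglomerative
#' clustering, cut into `k` flat clusters.
#'
#' @param mat log2-scale matrix, genes x samples.
#' @param signature signature gene ids (character) or a `cncl_signature`.
#' @param k number of flat clusters (default 2).
#' @param standardize z-score genes before clustering.
#' @return list of class `cncl_clustering`: `cluster` (integer vector named
#'   by sample), `hclust` (the [stats::hclust()] tree), `k`, `metric`
#'   (`"euclidean"`), `linkage` (`"complete"`).
#' @export
hcluster <- function(mat, signature, k = 2, standardize = TRUE) {
  genes <- signature_genes(signature)
  sub <- check_signature_present(mat, genes)
  assert_that(is_count(k) && k <= ncol(sub),
              "k must be a positive integer <= number of samples (%d)", ncol(sub))
  if (standardize) sub <- standardize_genes(sub)
  hc <- hclust(dist(t(sub), method = "euclidean"), method = "complete")
  structure(
    list(cluster = cutree(hc, k = k), hclust = hc, k = as.integer(k),
         metric = "euclidean", linkage = "complete"),
    class = "cncl_clustering"
  )
}

# Per-sample polarity score: mean standardized expression of the up_in_CS/M
# genes minus that of the up_in_NS/E genes. Positive = more CS/M-like.
polarity_scores <- function(mat, signature, standardize = TRUE) {
  sig <- signature_directions(signature)
  sub <- check_signature_present(mat, sig$feature_id)
  if (standardize) sub <- standardize_genes(sub)
  up <- sig$feature_id[sig$direction == "up_in_CS/M"]
  dn <- sig$feature_id[sig$direction == "up_in_NS/E"]
  up_m <- if (length(up)) colMeans(sub[up, , drop = FALSE]) else 0
  dn_m <- if (length(dn)) colMeans(sub[dn, , drop = FALSE]) else 0
  up_m - dn_m
}

#' Assign phenotype labels to clusters
#'
#' Orders clusters by their mean polarity score (mean standardized expression
#' of up-in-CS/M genes minus up-in-NS/E genes): the highest-scoring cluster
#' is labeled CS/M and the lowest NS/E; with `k = 3` the middle cluster is
#' labeled I (intermediary). Exactly tied cluster means indicate degenerate
#' input and raise an error.
#'
#' @param clustering a `cncl_clustering` from [hcluster()] with k in `{2, 3}`.
#' @param mat the matrix the clustering was computed on.
#' @param signature a directional `cncl_signature`.
#' @param standardize z-score genes before scoring (match [hcluster()]).
#' @return data.frame of class `cncl_calls` with `sample_id`, `label`
#'   (`"CS/M"`, `"NS/E"` or `"I"`), `basis = "clustering"`.
#' @export
label_clusters <- function(clustering, mat, signature, standardize = TRUE) {
  assert_that(inherits(clustering, "cncl_clustering"),
              "clustering must come from hcluster()")
  assert_that(clustering$k %in% c(2L, 3L),
              "phenotype labeling needs k = 2 (or 3 with an intermediary cluster)")
  scores <- polarity_scores(mat, signature, standardize = standardize)
  cl <- clustering$cluster[names(scores)]
  means <- tapply(scores, cl, mean)
  if (anyDuplicated(means)) {
    stop_cncl("cncl_degenerate_input_error",
              "tied cluster mean polarity scores; input is degenerate")
  }
  ord <- order(means, decreasing = TRUE)  # CS/M first
  labels_by_rank <- if (clustering$k == 2L) c("CS/M", "NS/E") else c("CS/M", "I", "NS/E")
  cluster_label <- setNames(labels_by_rank, names(means)[ord])
  out <- data.frame(
    sample_id = names(scores),
    label = unname(cluster_label[as.character(cl)]),
    basis = "clustering",
    stringsAsFactors = FALSE
  )
  class(out) <- c("cncl_calls", "data.frame")
  out
}

#' Classify samples by clustering on the signature
#'
#' Convenience wrapper: [hcluster()] then [label_clusters()].
#'
#' @inheritParams hcluster
#' @param signature a directional `cncl_signature`.
#' @return a `cncl_calls` data.frame (see [label_clusters()]).
#' @export
classify_phenotype <- function(mat, signature, k = 2, standardize = TRUE) {
  cl <- hcluster(mat, signature, k = k, standardize = standardize)
  label_clusters(cl, mat, signature, standardize = standardize)
}

#' Audit phenotype-call consistency across datasets
#'
#' Samples profiled in two or more datasets should receive the same phenotype
#' call everywhere. An assignment is each (sample, dataset) call for samples
#' appearing in at least two of the supplied datasets; a sample is
#' inconsistent when its non-I labels disagree across datasets (each
#' inconsistent sample is reported once, while all of its assignments count
#' toward the total).
#'
#' @param calls_by_dataset named list of `cncl_calls` data.frames (or any
#'   data.frame with `sample_id` and `label`).
#' @return list with `n_assignments`, `n_inconsistent`,
#'   `inconsistent_samples` (character vector).
#' @export
cross_dataset_consistency <- function(calls_by_dataset) {
  assert_that(is.list(calls_by_dataset) && length(calls_by_dataset) >= 2,
              "need calls from >= 2 datasets")
  long <- do.call(rbind, lapply(names(calls_by_dataset), function(ds) {
    calls <- calls_by_dataset[[ds]]
    data.frame(dataset = ds, sample_id = calls$sample_id,
               label = calls$label, stringsAsFactors = FALSE)
  }))
  n_datasets <- tapply(long$dataset, long$sample_id,
                       function(d) length(unique(d)))
  shared <- names(n_datasets)[n_datasets >= 2]
  if (length(shared) == 0) {
    stop_cncl("cncl_validation_error", "no samples shared between datasets")
  }
  long <- long[long$sample_id %in% shared, , drop = FALSE]
  inconsistent <- vapply(split(long$label, long$sample_id), function(lab) {
    lab <- lab[lab != "I"]
    length(unique(lab)) > 1
  }, logical(1))
  list(
    n_assignments = nrow(long),
    n_inconsistent = sum(inconsistent),
    inconsistent_samples = sort(names(inconsistent)[inconsistent])
  )
}
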