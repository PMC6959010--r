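#' Read an expression matrix from a delimited text file
#'
#' Expects a header row of sample ids and a first column of feature
#' (probeset/gene) ids. Every cell is validated: ragged rows, duplicated
#' sample or feature ids and non-numeric cells raise errors naming the
#' offending row/column, since silent coercion would corrupt downstream
#' correlation-based scoring.
#'
#' @param path file path.
#' @param sep field separator; `"\t"` (default) for TSV, `","` for CSV.
#' @param scale_tag `"log2"` (default) or `"fpkm"`. FPKM inputs can be put on
#'   a log2 scale with `fpkm_to_log2`.
#' @param fpkm_to_log2 if `TRUE` and `scale_tag == "fpkm"`, values are
#'   transformed to `log2(FPKM + 1)` and the tag becomes `"log2"`.
#' @return numeric matrix (features x samples) with a `scale_tag` attribute.
#' @export
read_expression <- function(path, sep = "\t", scale_tag = c("log2", "fpkm"),
                            fpkm_to_log2 = FALSE) {
  scale_tag <- match.arg(scale_tag)
  assert_that(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  assert_that(length(lines) >= 2, "file %s has no data rows", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1]]
  n_col <- length(header)
  sample_ids <- header[-1]
  assert_that(length(sample_ids) >= 1, "no sample columns in %s", path)
  if (anyDuplicated(sample_ids)) {
    stop_cncl("cncl_parse_error", "duplicated sample id(s) in header: %s",
              paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  body <- fields[-1]
  n_fields <- lengths(body)
  if (any(n_fields != n_col)) {
    i <- which(n_fields != n_col)[1]
    stop_cncl("cncl_parse_error",
              "ragged row %d: %d field(s), expected %d", i + 1L,
              n_fields[i], n_col)
  }
  feature_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(feature_ids)) {
    stop_cncl("cncl_parse_error", "duplicated feature id(s): %s",
              paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(n_col - 1L))
  )
  # vapply gives samples x features; transpose to features x samples
  mat <- t(matrix(vals, nrow = n_col - 1L))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop_cncl("cncl_parse_error",
              "non-numeric cell at feature '%s', sample '%s'",
              feature_ids[bad[1]], sample_ids[bad[2]])
  }
  dimnames(mat) <- list(feature_ids, sample_ids)
  if (scale_tag == "fpkm" && fpkm_to_log2) {
    mat <- log2(mat + 1)
    scale_tag <- "log2"
  }
  attr(mat, "scale_tag") <- scale_tag
  mat
}

#' Write an expression matrix to a delimited text file
#'
#' Emits the same dialect [read_expression()] consumes: header of sample ids
#' preceded by a `feature_id` column.
#'
#' @param mat numeric matrix with feature rownames and sample colnames.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, sep = "\t") {
  assert_that(is.matrix(mat) && !is.null(rownames(mat)) && !is.null(colnames(mat)),
              "matrix must have feature rownames and sample colnames")
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probeset-level rows to gene symbols
#'
#' Microarray matrices carry multiple probesets per gene; for gene-level
#' analyses one row per gene is needed. The default rule keeps, for each
#' symbol, the probeset with maximal variance across samples (the most
#' informative measurement); `"mean"` averages all probesets of a symbol.
#'
#' @param mat numeric matrix, features x samples.
#' @param mapping data.frame with columns `feature_id`, `symbol`.
#' @param rule `"max_variance"` (default) or `"mean"`.
#' @return matrix with one row per mapped gene symbol.
#' @export
collapse_to_genes <- function(mat, mapping, rule = c("max_variance", "mean")) {
  rule <- match.arg(rule)
  assert_that(is.data.frame(mapping) &&
                all(c("feature_id", "symbol") %in% names(mapping)),
              "mapping needs columns feature_id and symbol")
  mapping <- mapping[mapping$feature_id %in% rownames(mat), , drop = FALSE]
  if (nrow(mapping) == 0) {
    stop_cncl("cncl_mapping_error",
              "no overlap between mapping feature ids and matrix rows")
  }
  sub <- mat[mapping$feature_id, , drop = FALSE]
  by_symbol <- split(seq_len(nrow(mapping)), mapping$symbol)
  rows <- lapply(by_symbol, function(idx) {
    block <- sub[idx, , drop = FALSE]
    if (rule == "mean" && nrow(block) > 1) {
      colMeans(block)
    } else {
      block[which.max(apply(block, 1L, var)), ]
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(by_symbol)
  attr(out, "scale_tag") <- attr(mat, "scale_tag")
  out
}

#' qPCR relative expression by the delta-delta-Ct method
#'
#' Computes `2^-ddCT` with `ddCT = (ct_target - ct_reference) -
#' (calibrator_ct_target - calibrator_ct_reference)`, i.e. fold change of the
#' target gene relative to an endogenous reference (e.g. GAPDH) and a
#' calibrator sample. Vectorized over inputs.
#'
#' @param ct_target Ct of the target gene in the test sample.
#' @param ct_reference Ct of the reference gene in the test sample.
#' @param calibrator_ct_target,calibrator_ct_reference Ct values in the
#'   calibrator sample.
#' @return relative expression fold (numeric).
#' @examples
#' delta_delta_ct(19, 15, 20, 15) # 2-fold up
#' @export
delta_delta_ct <- function(ct_target, ct_reference,
                           calibrator_ct_target, calibrator_ct_reference) {
  vals <- c(ct_target, ct_reference, calibrator_ct_target,
            calibrator_ct_reference)
  assert_that(all(is.finite(vals)), "all Ct values must be finite")
  ddct <- (ct_target - ct_reference) -
    (calibrator_ct_target - calibrator_ct_reference)
  2^(-ddct)
}
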