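# Internal helpers shared across modules.

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

stop_cncl <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "cncl_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

assert_that <- function(ok, msg, ...) {
  if (!isTRUE(ok)) stop_cncl("cncl_validation_error", msg, ...)
  invisible(TRUE)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

is_number <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)

#' Standardize each gene (row) of an expression matrix
#'
#' Centers every row at its mean and, unless `center_only = TRUE`, scales it to
#' unit standard deviation (z-score). Gene-wise standardization puts genes with
#' different dynamic ranges on a comparable scale before clustering or
#' correlation-based scoring.
#'
#' @param mat numeric matrix, features x samples.
#' @param center_only if `TRUE`, only subtract the row mean (no scaling).
#' @return matrix of the same shape.
#' @export
standardize_genes <- function(mat, center_only = FALSE) {
  assert_that(is.matrix(mat) && is.numeric(mat), "expected a numeric matrix")
  mu <- rowMeans(mat)
  out <- mat - mu
  if (!center_only) {
    s <- apply(mat, 1L, sd)
    zero <- s == 0 | !is.finite(s)
    if (any(zero)) {
      stop_cncl(
        "cncl_constant_gene_error",
        "cannot standardize constant gene(s): %s",
        paste(rownames(mat)[zero], collapse = ", ")
      )
    }
    out <- out / s
  }
  out
}

# Resolve a signature argument to a character vector of gene ids, and (if
# directions are needed) to a data.frame with feature_id + direction.
signature_genes <- function(signature) {
  if (is.character(signature)) return(signature)
  if (is.data.frame(signature) && "feature_id" %in% names(signature)) {
    return(as.character(signature$feature_id))
  }
  stop_cncl("cncl_validation_error",
            "signature must be a character vector or a signature data.frame")
}

signature_directions <- function(signature) {
  assert_that(
    is.data.frame(signature) &&
      all(c("feature_id", "direction") %in% names(signature)),
    "a directional signature (feature_id + direction columns) is required"
  )
  assert_that(
    all(signature$direction %in% c("up_in_CS/M", "up_in_NS/E")),
    "direction must be 'up_in_CS/M' or 'up_in_NS/E'"
  )
  signature
}

check_signature_present <- function(mat, genes) {
  missing <- setdiff(genes, rownames(mat))
  if (length(missing) > 0) {
    stop_cncl("cncl_missing_genes_error",
              "signature gene(s) absent from matrix: %s",
              paste(missing, collapse = ", "))
  }
  sub <- mat[genes, , drop = FALSE]
  if (anyNA(sub)) {
    stop_cncl("cncl_missing_values_error",
              "missing values in the signature submatrix are not allowed")
  }
  sub
}

# Normalize phenotype labels to a character vector named by sample id.
check_labels <- function(labels, sample_ids) {
  labels <- as.character(labels)
  if (!is.null(names(labels))) {
    assert_that(all(sample_ids %in% names(labels)),
                "labels missing for some samples")
    labels <- labels[sample_ids]
  } else {
    assert_that(length(labels) == length(sample_ids),
                "labels length (%d) != number of samples (%d)",
                length(labels), length(sample_ids))
    names(labels) <- sample_ids
  }
  labels
}
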