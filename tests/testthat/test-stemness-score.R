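make_centroids <- function(csm, nse, genes = paste0("g", seq_along(csm))) {
  out <- data.frame(gene = genes, csm_median = csm, nse_median = nse)
  class(out) <- c("cncl_centroids", "data.frame")
  out
}

test_that("build_centroids takes per-group medians of standardized genes", {
  set.seed(501)
  mat <- matrix(rnorm(15 * 40), nrow = 15,
                dimnames = list(paste0("g", 1:15), paste0("s", 1:40)))
  labels <- setNames(rep(c("CS/M", "NS/E"), each = 20), colnames(mat))
  cen <- build_centroids(mat, labels, paste0("g", 1:15))
  z <- standardize_genes(mat)
  for (i in 1:15) {
    expect_equal(cen$csm_median[i], oracle_median(z[i, 1:20]),
                 tolerance = 1e-12)
    expect_equal(cen$nse_median[i], oracle_median(z[i, 21:40]),
                 tolerance = 1e-12)
  }
  # a one-sample group's centroid is that sample's standardized vector
  one <- setNames(c("CS/M", rep("NS/E", 39)), colnames(mat))
  cen1 <- build_centroids(mat, one, paste0("g", 1:15))
  expect_equal(cen1$csm_median, unname(z[, 1]), tolerance = 1e-12)
  # mirror-image groups give opposite centroids after centering
  sym <- cbind(mat[, 1:20], 2 * rowMeans(mat[, 1:20]) - mat[, 1:20])
  colnames(sym) <- paste0("s", 1:40)
  cen_sym <- build_centroids(sym, labels, paste0("g", 1:15))
  expect_equal(cen_sym$nse_median, -cen_sym$csm_median, tolerance = 1e-10)
})

test_that("score_sample matches the textbook Pearson formula", {
  set.seed(502)
  for (i in 1:20) {
    cen <- make_centroids(rnorm(15), rnorm(15))
    x <- setNames(rnorm(15), cen$gene)
    sc <- score_sample(x, cen)
    expect_equal(sc$csm_r, oracle_pearson(x, cen$csm_median),
                 tolerance = 1e-12)
    expect_equal(sc$nse_r, oracle_pearson(x, cen$nse_median),
                 tolerance = 1e-12)
    expect_equal(sc$delta_r, sc$csm_r - sc$nse_r, tolerance = 1e-12)
  }
})

test_that("score algebra identities hold", {
  set.seed(503)
  cen <- make_centroids(rnorm(15), rnorm(15))
  rho <- cor(cen$csm_median, cen$nse_median)
  # sample identical to the CS/M centroid
  x <- setNames(cen$csm_median, cen$gene)
  sc <- score_sample(x, cen)
  expect_equal(sc$csm_r, 1, tolerance = 1e-12)
  expect_equal(sc$nse_r, rho, tolerance = 1e-12)
  expect_equal(sc$delta_r, 1 - rho, tolerance = 1e-12)
  # antipodal centroids: delta_r reaches its bound of 2
  anti <- make_centroids(cen$csm_median, -cen$csm_median)
  expect_equal(score_sample(x, anti)$delta_r, 2, tolerance = 1e-12)
  # degenerate inputs are refused
  expect_error(score_sample(setNames(rep(1, 15), cen$gene), cen),
               class = "cncl_degenerate_input_error")
  flat <- make_centroids(rep(0.5, 15), rnorm(15))
  expect_error(score_sample(x, flat), class = "cncl_configuration_error")
})

test_that("delta_r is affine-invariant, bounded, and antisymmetric in centroids", {
  set.seed(504)
  for (i in 1:15) {
    cen <- make_centroids(rnorm(15), rnorm(15))
    x <- setNames(rnorm(15), cen$gene)
    sc <- score_sample(x, cen)
    expect_gte(sc$delta_r, -2)
    expect_lte(sc$delta_r, 2)
    # positive affine transform of the sample leaves the score unchanged
    a <- runif(1, 0.1, 5); b <- runif(1, -3, 3)
    sc_aff <- score_sample(a * x + b, cen)
    expect_equal(sc_aff$delta_r, sc$delta_r, tolerance = 1e-12)
    # swapping the centroids negates the score exactly
    swapped <- make_centroids(cen$nse_median, cen$csm_median)
    expect_equal(score_sample(x, swapped)$delta_r, -sc$delta_r,
                 tolerance = 1e-12)
  }
})

test_that("categorical calls follow the cutoff/band rule", {
  expect_identical(call_from_score(0.7, cutoff = 0.6459), "CS/M")
  expect_identical(call_from_score(0.6, cutoff = 0.6459), "NS/E")
  # boundary value goes to NS/E by convention
  expect_identical(call_from_score(0, cutoff = 0, band_halfwidth = 0), "NS/E")
  expect_identical(call_from_score(0.05, cutoff = 0, band_halfwidth = 0.1),
                   "I")
  expect_identical(call_from_score(c(-0.5, 0.02, 0.5), 0, 0.1),
                   c("NS/E", "I", "CS/M"))
})

test_that("score-based calls agree with clustering-based labels", {
  for (seed in c(61, 62)) {
    sim <- generate_expression(expression_sim_config(
      n_genes = 100, log2_effect = 2, noise_sd = 0.5, seed = seed))
    cen <- build_centroids(sim$matrix, sim$labels, sim$signature$feature_id)
    scores <- score_samples(sim$matrix, cen)
    cluster_calls <- classify_phenotype(sim$matrix, sim$signature)
    agree <- mean(scores$call ==
                    cluster_calls$label[match(scores$sample_id,
                                              cluster_calls$sample_id)])
    expect_gte(agree, 0.95)
    expect_true(all(abs(scores$delta_r) <= 2))
  }
})

test_that("trace_plasticity flags switched pairs and errors on bad pairing", {
  sim <- generate_expression(expression_sim_config(n_genes = 80, seed = 71))
  cen <- build_centroids(sim$matrix, sim$labels, sim$signature$feature_id)
  sc <- score_samples(sim$matrix, cen)
  none <- trace_plasticity(sc, sc)
  expect_true(all(!none$switched))
  expect_true(all(none$delta_delta_r == 0))

  bad_pairing <- data.frame(pre_id = "S001", post_id = "NOPE")
  expect_error(trace_plasticity(sc, sc, bad_pairing),
               class = "cncl_validation_error")

  # full switch: every call flips
  flipped <- generate_paired_switch(expression_sim_config(n_genes = 80,
                                                          seed = 72), 1)
  cen2 <- build_centroids(flipped$pre, flipped$labels_pre,
                          sim$signature$feature_id)
  pre_sc <- score_samples(flipped$pre, cen2)
  post_sc <- score_samples(flipped$post, cen2)
  tr <- trace_plasticity(pre_sc, post_sc)
  expect_true(all(tr$switched))
  expect_identical(dim(attr(tr, "summary")), c(2L, 2L))
})
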