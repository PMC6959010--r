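test_that("welch_t_test matches the textbook Welch formula", {
  set.seed(301)
  for (i in 1:20) {
    a <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
    got <- welch_t_test(a, b)
    ref <- oracle_welch(a, b)
    expect_equal(got$statistic, ref$statistic, tolerance = 1e-10)
    expect_equal(got$p_value, ref$p_value, tolerance = 1e-10)
  }
})

test_that("welch_t_test handles degenerate zero-variance groups by convention", {
  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3))$statistic,
               0, tolerance = 1e-12)
  same <- welch_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p_value, 1)
  diffc <- welch_t_test(c(0, 0, 0), c(1, 1, 1))
  expect_lt(diffc$p_value, 1e-300)
  expect_true(is.infinite(diffc$statistic) && diffc$statistic < 0)
  expect_error(welch_t_test(1, c(1, 2)), class = "cncl_validation_error")
})

test_that("rank_de_genes recovers planted genes and behaves at the null", {
  sim <- generate_expression(expression_sim_config(n_genes = 200, seed = 9))
  top <- rank_de_genes(sim$matrix, sim$labels, top_n = 15)
  expect_setequal(top$feature_id, sim$signature$feature_id)
  expect_identical(
    top$direction[match(sim$signature$feature_id, top$feature_id)],
    sim$signature$direction
  )
  expect_true(all(diff(top$p_value) >= 0))
  expect_true(all(top$fold >= 1))

  # null data: directions of the reported genes are roughly balanced
  null_sim <- generate_expression(expression_sim_config(
    n_genes = 400, log2_effect = 0, seed = 10))
  null_top <- rank_de_genes(null_sim$matrix, null_sim$labels, top_n = 200,
                            initial_p = 1)
  frac_up <- mean(null_top$direction == "up_in_CS/M")
  expect_gt(frac_up, 0.35)
  expect_lt(frac_up, 0.65)

  expect_equal(nrow(rank_de_genes(sim$matrix, sim$labels, top_n = 0)), 0L)
  one_each <- setNames(rep(c("CS/M", "NS/E"), c(1, 39)), colnames(sim$matrix))
  expect_error(rank_de_genes(sim$matrix, one_each, 10),
               class = "cncl_validation_error")
})

test_that("derive_signature recovers a planted 8-up/7-down signature exactly", {
  simA <- generate_expression(expression_sim_config(seed = 11))
  simB <- generate_expression(expression_sim_config(seed = 22))
  sig <- derive_signature(simA$matrix, simA$labels, simB$matrix, simB$labels)
  expect_s3_class(sig, "cncl_signature")
  expect_equal(nrow(sig), 15L)
  expect_setequal(sig$feature_id, simA$signature$feature_id)
  expect_identical(
    sig$direction[match(simA$signature$feature_id, sig$feature_id)],
    simA$signature$direction
  )
  expect_equal(sum(sig$direction == "up_in_CS/M"), 8L)
  expect_equal(sum(sig$direction == "up_in_NS/E"), 7L)

  # every retained entry satisfies all filters in both datasets
  p <- derivation_params()
  expect_true(all(sig$fold_a >= p$min_fold & sig$fold_b >= p$min_fold))
  expect_true(all(sig$p_a < p$max_p & sig$p_b < p$max_p))

  # symmetric in dataset order up to the per-dataset columns
  swapped <- derive_signature(simB$matrix, simB$labels, simA$matrix, simA$labels)
  expect_setequal(swapped$feature_id, sig$feature_id)
  expect_equal(swapped$fold_a[match(sig$feature_id, swapped$feature_id)],
               sig$fold_b)
})

test_that("derive_signature errors on empty intersections, not silently", {
  simA <- generate_expression(expression_sim_config(n_genes = 50, seed = 1))
  simB <- generate_expression(expression_sim_config(n_genes = 50, seed = 2))
  disjoint <- simB$matrix
  rownames(disjoint) <- paste0("OTHER_", seq_len(nrow(disjoint)))
  expect_error(
    derive_signature(simA$matrix, simA$labels, disjoint, simB$labels),
    class = "cncl_empty_signature_error"
  )
})

test_that("with filters disabled the signature is the concordant intersection", {
  simA <- generate_expression(expression_sim_config(n_genes = 100, seed = 31))
  simB <- generate_expression(expression_sim_config(n_genes = 100, seed = 32))
  params <- derivation_params(top_n = 40, initial_p = 1, min_fold = 1,
                              max_p = 1, min_intercorr = 0)
  sig <- derive_signature(simA$matrix, simA$labels, simB$matrix, simB$labels,
                          params)
  de_a <- rank_de_genes(simA$matrix, simA$labels, 40, 1)
  de_b <- rank_de_genes(simB$matrix, simB$labels, 40, 1)
  both <- intersect(de_a$feature_id, de_b$feature_id)
  concordant <- both[de_a$direction[match(both, de_a$feature_id)] ==
                       de_b$direction[match(both, de_b$feature_id)]]
  expect_setequal(sig$feature_id, concordant)
})

test_that("rank_sum_combine orders by combined rank with lexicographic ties", {
  r1 <- c(A = 1, B = 2, C = 3)
  expect_identical(rank_sum_combine(r1, r1)$name, c("A", "B", "C"))
  # exactly reversed rankings force an all-way tie, broken lexicographically
  rev3 <- c(A = 3, B = 2, C = 1)
  tied <- rank_sum_combine(r1, rev3)
  expect_true(all(tied$ranksum == 4))
  expect_identical(tied$name, c("A", "B", "C"))
  # hand-computed case: B(3) < A(4) = C(5) -> B, A, C
  out <- rank_sum_combine(c(A = 1, B = 2, C = 3), c(A = 3, B = 1, C = 2))
  expect_identical(out$name, c("B", "A", "C"))
  expect_equal(out$ranksum, c(3, 4, 5))
  expect_error(rank_sum_combine(c(A = 1, B = 2), c(A = 1, D = 2)),
               "only in a: \\{B\\}; only in b: \\{D\\}")
})
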