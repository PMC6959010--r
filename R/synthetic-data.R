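#' Configuration for synthetic two-phenotype expression data
#'
#' Describes a log2-scale expression matrix with two sample groups (CS/M and
#' NS/E) and a planted directional signature: `n_signature_up` genes elevated
#' in CS/M and `n_signature_down` genes elevated in NS/E, each shifted by
#' `log2_effect` between the group means. Genes in the same signature arm
#' co-vary through a shared per-sample latent factor with weight
#' `within_arm_corr` (pairwise gene-gene correlation within an arm is
#' `within_arm_corr^2`); all other variation is i.i.d. Gaussian with standard
#' deviation `noise_sd` on the log2 scale.
#'
#' The defaults mirror the structure of the real signature the pipeline was
#' built around: 8 genes up and 7 down in CS/M at a large (8-fold, i.e. 3 on
#' the log2 scale) effect, which sits comfortably above the 3-fold linear
#' filter used at derivation time.
#'
#' @param n_genes total number of genes.
#' @param n_signature_up genes elevated in CS/M samples.
#' @param n_signature_down genes elevated in NS/E samples.
#' @param n_csm_samples,n_nse_samples samples per group.
#' @param log2_effect mean log2 difference between groups for signature genes
#'   (>= 0).
#' @param noise_sd Gaussian noise standard deviation on the log2 scale (> 0).
#' @param within_arm_corr latent-factor weight in `[0, 1]` making same-arm
#'   signature genes co-vary.
#' @param seed integer RNG seed; the same config and seed give bit-identical
#'   output.
#' @return an `expression_sim_config` list.
#' @export
expression_sim_config <- function(n_genes = 1000,
                                  n_signature_up = 8,
                                  n_signature_down = 7,
                                  n_csm_samples = 20,
                                  n_nse_samples = 20,
                                  log2_effect = 3,
                                  noise_sd = 0.25,
                                  within_arm_corr = 0.7,
                                  seed = 1L) {
  assert_that(is_count(n_genes), "n_genes must be a positive integer")
  assert_that(is_count(n_signature_up), "n_signature_up must be a positive integer")
  assert_that(is_count(n_signature_down), "n_signature_down must be a positive integer")
  assert_that(is_count(n_csm_samples), "n_csm_samples must be a positive integer")
  assert_that(is_count(n_nse_samples), "n_nse_samples must be a positive integer")
  assert_that(n_signature_up + n_signature_down <= n_genes,
              "n_signature_up + n_signature_down (%d) exceeds n_genes (%d)",
              n_signature_up + n_signature_down, n_genes)
  assert_that(is_number(log2_effect) && log2_effect >= 0,
              "log2_effect must be a finite number >= 0")
  assert_that(is_number(noise_sd) && noise_sd > 0, "noise_sd must be > 0")
  assert_that(is_number(within_arm_corr) && within_arm_corr >= 0 &&
                within_arm_corr <= 1, "within_arm_corr must be in [0, 1]")
  assert_that(is_count(abs(seed) + 1), "seed must be an integer")
  structure(
    list(n_genes = as.integer(n_genes),
         n_signature_up = as.integer(n_signature_up),
         n_signature_down = as.integer(n_signature_down),
         n_csm_samples = as.integer(n_csm_samples),
         n_nse_samples = as.integer(n_nse_samples),
         log2_effect = log2_effect, noise_sd = noise_sd,
         within_arm_corr = within_arm_corr, seed = as.integer(seed)),
    class = "expression_sim_config"
  )
}

# Per-gene baseline log2 means (typical RMA intensities), drawn once per config.
sim_baseline <- function(config) {
  rnorm(config$n_genes, mean = 8, sd = 1.5)
}

sim_gene_ids <- function(config) {
  n_sig <- config$n_signature_up + config$n_signature_down
  ids <- sprintf("GENE_%04d", seq_len(config$n_genes))
  ids[seq_len(config$n_signature_up)] <-
    sprintf("SIGUP_%02d", seq_len(config$n_signature_up))
  ids[config$n_signature_up + seq_len(config$n_signature_down)] <-
    sprintf("SIGDN_%02d", seq_len(config$n_signature_down))
  ids
}

# Draw one matrix given per-sample group assignments ("CS/M"/"NS/E") and a
# fixed per-gene baseline. RNG state is the caller's responsibility.
sim_expression_matrix <- function(config, groups, baseline, sample_ids) {
  g <- config$n_genes
  n <- length(groups)
  up <- seq_len(config$n_signature_up)
  dn <- config$n_signature_up + seq_len(config$n_signature_down)
  half <- config$log2_effect / 2
  shift <- matrix(0, g, n)
  csm <- groups == "CS/M"
  shift[up, csm] <- half
  shift[up, !csm] <- -half
  shift[dn, csm] <- -half
  shift[dn, !csm] <- half

  w <- config$within_arm_corr
  eps <- matrix(rnorm(g * n), g, n)
  z_up <- rnorm(n)
  z_dn <- rnorm(n)
  resid_w <- sqrt(1 - w^2)
  eps[up, ] <- w * matrix(z_up, length(up), n, byrow = TRUE) + resid_w * eps[up, , drop = FALSE]
  eps[dn, ] <- w * matrix(z_dn, length(dn), n, byrow = TRUE) + resid_w * eps[dn, , drop = FALSE]

  mat <- baseline + shift + config$noise_sd * eps
  dimnames(mat) <- list(sim_gene_ids(config), sample_ids)
  attr(mat, "scale_tag") <- "log2"
  mat
}

sim_true_signature <- function(config) {
  ids <- sim_gene_ids(config)
  data.frame(
    feature_id = ids[seq_len(config$n_signature_up + config$n_signature_down)],
    direction = c(rep("up_in_CS/M", config$n_signature_up),
                  rep("up_in_NS/E", config$n_signature_down)),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic labeled expression matrix with a planted signature
#'
#' Simulates a log2-scale expression matrix under [expression_sim_config()]:
#' signature genes differ between the CS/M and NS/E groups by `log2_effect` in
#' expectation (signed by arm direction), non-signature genes have zero
#' expected difference, and same-arm signature genes share a latent factor.
#'
#' @param config an [expression_sim_config()].
#' @return a list with `matrix` (genes x samples, log2 scale), `labels`
#'   (character vector named by sample id, values `"CS/M"`/`"NS/E"`), and
#'   `signature` (data.frame of planted genes with `feature_id`, `direction`).
#' @examples
#' sim <- generate_expression(expression_sim_config(n_genes = 50, seed = 7))
#' dim(sim$matrix)
#' table(sim$labels)
#' @export
generate_expression <- function(config) {
  assert_that(inherits(config, "expression_sim_config"),
              "config must come from expression_sim_config()")
  n <- config$n_csm_samples + config$n_nse_samples
  sample_ids <- sprintf("S%03d", seq_len(n))
  groups <- c(rep("CS/M", config$n_csm_samples),
              rep("NS/E", config$n_nse_samples))
  mat <- with_seed(config$seed, {
    baseline <- sim_baseline(config)
    sim_expression_matrix(config, groups, baseline, sample_ids)
  })
  list(matrix = mat,
       labels = setNames(groups, sample_ids),
       signature = sim_true_signature(config))
}

#' Generate paired pre/post expression matrices with phenotype switching
#'
#' Emulates a paired design (e.g. tumor tissue sampled before and after
#' therapy): pre-treatment samples are drawn per `config`; each sample then
#' independently switches phenotype with probability `switch_fraction`, and
#' its post-treatment profile is redrawn from the generative model of its
#' post-switch group (non-switched samples are redrawn from their own group,
#' modeling biological/technical resampling noise between timepoints).
#'
#' @param config an [expression_sim_config()].
#' @param switch_fraction probability in `[0, 1]` that a sample switches
#'   phenotype between timepoints.
#' @return list with `pre`, `post` (matrices), `labels_pre`, `labels_post`
#'   (named character vectors), and `switched` (named logical vector).
#' @export
generate_paired_switch <- function(config, switch_fraction) {
  assert_that(inherits(config, "expression_sim_config"),
              "config must come from expression_sim_config()")
  assert_that(is_number(switch_fraction) && switch_fraction >= 0 &&
                switch_fraction <= 1, "switch_fraction must be in [0, 1]")
  n <- config$n_csm_samples + config$n_nse_samples
  sample_ids <- sprintf("S%03d", seq_len(n))
  groups_pre <- c(rep("CS/M", config$n_csm_samples),
                  rep("NS/E", config$n_nse_samples))
  out <- with_seed(config$seed, {
    baseline <- sim_baseline(config)
    pre <- sim_expression_matrix(config, groups_pre, baseline, sample_ids)
    switched <- runif(n) < switch_fraction
    groups_post <- ifelse(switched,
                          ifelse(groups_pre == "CS/M", "NS/E", "CS/M"),
                          groups_pre)
    post <- sim_expression_matrix(config, groups_post, baseline, sample_ids)
    list(pre = pre, post = post, groups_post = groups_post,
         switched = switched)
  })
  list(pre = out$pre, post = out$post,
       labels_pre = setNames(groups_pre, sample_ids),
       labels_post = setNames(out$groups_post, sample_ids),
       switched = setNames(out$switched, sample_ids))
}

#' Configuration for synthetic dose-viability data
#'
#' A four-parameter logistic (4PL) viability curve sampled at a fixed dose
#' series with replicate wells and additive Gaussian noise. The default dose
#' series is 10 half-log-spaced concentrations spanning 0.001-50 uM, matching
#' the kind of 10-dose cytotoxicity series used for drugs such as Lapatinib.
#' Replicates default to 4 (quadruplicate wells). Noisy viabilities are
#' truncated to `[-10, 130]`% to mimic plate-assay artifacts.
#'
#' @param doses strictly increasing positive concentrations (uM).
#' @param bottom,top viability asymptotes (%), `bottom < top`.
#' @param ic50 curve midpoint concentration (uM, > 0).
#' @param hill Hill slope (> 0).
#' @param noise_sd Gaussian noise sd in viability percent (>= 0).
#' @param replicates wells per dose (positive integer).
#' @param seed integer RNG seed.
#' @return a `dose_response_sim_config` list.
#' @export
dose_response_sim_config <- function(doses = 10^seq(-3, log10(50), length.out = 10),
                                     bottom = 0, top = 100,
                                     ic50 = 1, hill = 1,
                                     noise_sd = 5, replicates = 4,
                                     seed = 1L) {
  assert_that(is.numeric(doses) && length(doses) >= 2 && all(doses > 0) &&
                all(diff(doses) > 0), "doses must be strictly increasing and positive")
  assert_that(is_number(bottom) && is_number(top) && bottom < top,
              "bottom must be < top")
  assert_that(is_number(ic50) && ic50 > 0, "ic50 must be > 0")
  assert_that(is_number(hill) && hill > 0, "hill must be > 0")
  assert_that(is_number(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(is_count(replicates), "replicates must be a positive integer")
  structure(
    list(doses = as.numeric(doses), bottom = bottom, top = top,
         ic50 = ic50, hill = hill, noise_sd = noise_sd,
         replicates = as.integer(replicates), seed = as.integer(seed)),
    class = "dose_response_sim_config"
  )
}

# 4PL viability at dose d (percent).
logistic4 <- function(d, bottom, top, ic50, hill) {
  bottom + (top - bottom) / (1 + (d / ic50)^hill)
}

#' Generate a synthetic dose-viability table
#'
#' Samples `viability = bottom + (top - bottom) / (1 + (dose/ic50)^hill) +
#' noise` at each configured dose and replicate; noisy values are truncated to
#' `[-10, 130]`%.
#'
#' @param config a [dose_response_sim_config()].
#' @return data.frame with columns `dose_uM`, `replicate`, `viability_pct`.
#' @export
generate_dose_response <- function(config) {
  assert_that(inherits(config, "dose_response_sim_config"),
              "config must come from dose_response_sim_config()")
  with_seed(config$seed, {
    grid <- expand.grid(replicate = seq_len(config$replicates),
                        dose_uM = config$doses)
    mu <- logistic4(grid$dose_uM, config$bottom, config$top,
                    config$ic50, config$hill)
    v <- mu + rnorm(nrow(grid), sd = config$noise_sd)
    if (config$noise_sd > 0) v <- pmin(pmax(v, -10), 130)
    data.frame(dose_uM = grid$dose_uM, replicate = grid$replicate,
               viability_pct = v)
  })
}

#' Configuration for synthetic two-group survival data
#'
#' Exponential event times with proportional hazards between the CS/M and
#' NS/E groups and independent exponential censoring.
#'
#' @param n_per_group samples per phenotype group.
#' @param hazard_ratio CS/M hazard relative to NS/E (> 0).
#' @param baseline_rate NS/E event rate per time unit (> 0).
#' @param censor_rate censoring rate per time unit (> 0).
#' @param seed integer RNG seed.
#' @return a `survival_sim_config` list.
#' @export
survival_sim_config <- function(n_per_group = 100,
                                hazard_ratio = 3,
                                baseline_rate = 0.1,
                                censor_rate = 0.02,
                                seed = 1L) {
  assert_that(is_count(n_per_group), "n_per_group must be a positive integer")
  assert_that(is_number(hazard_ratio) && hazard_ratio > 0,
              "hazard_ratio must be > 0")
  assert_that(is_number(baseline_rate) && baseline_rate > 0,
              "baseline_rate must be > 0")
  assert_that(is_number(censor_rate) && censor_rate > 0,
              "censor_rate must be > 0")
  structure(
    list(n_per_group = as.integer(n_per_group), hazard_ratio = hazard_ratio,
         baseline_rate = baseline_rate, censor_rate = censor_rate,
         seed = as.integer(seed)),
    class = "survival_sim_config"
  )
}

#' Generate a synthetic survival table
#'
#' Event times are exponential with rate `baseline_rate` for NS/E and
#' `baseline_rate * hazard_ratio` for CS/M; censoring times are exponential
#' with rate `censor_rate`; the observed time is the minimum and `event`
#' flags whether the event preceded censoring.
#'
#' @param config a [survival_sim_config()].
#' @return data.frame with columns `sample_id`, `time`, `event` (0/1),
#'   `group` (`"CS/M"`/`"NS/E"`).
#' @export
generate_survival <- function(config) {
  assert_that(inherits(config, "survival_sim_config"),
              "config must come from survival_sim_config()")
  n <- config$n_per_group
  group <- c(rep("CS/M", n), rep("NS/E", n))
  rate <- ifelse(group == "CS/M",
                 config$baseline_rate * config$hazard_ratio,
                 config$baseline_rate)
  with_seed(config$seed, {
    t_event <- rexp(2 * n, rate = rate)
    t_cens <- rexp(2 * n, rate = config$censor_rate)
    data.frame(
      sample_id = sprintf("P%03d", seq_len(2 * n)),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      group = group
    )
  })
}
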