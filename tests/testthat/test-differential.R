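# Small labelled study used across differential tests.
diff_fixture <- function(n_per_cohort = c(6, 6, 6), seed = 30) {
  man <- tiny_manifest(n_per_cohort = n_per_cohort, n_pools = 2, seed = seed)
  man
}

test_that("MS GEE with one profile per subject equals OLS", {
  man <- diff_fixture()
  set.seed(31)
  n <- nrow(man)
  profiles <- data.frame(run_id = "P1_R1", pool_id = man$pool_id, replicate = 1,
                         channel = man$channel, subject_id = man$subject_id,
                         profile_id = paste0("pr", seq_len(n)))
  vals <- matrix(rnorm(5 * n, 10, 1), 5, n,
                 dimnames = list(paste0("PR", 1:5), profiles$profile_id))
  vals[1, man$cohort == "control"] <- vals[1, man$cohort == "control"] + 1
  res <- fit_ms_differential(vals, profiles, man)
  d <- data.frame(y = vals[1, ],
                  cohort = factor(man$cohort, c("centenarian", "offspring", "control")),
                  year = man$year_of_collection, gender = man$gender)
  ols <- lm(y ~ cohort + year + gender, d)
  expect_equal(res$beta_control[1], unname(coef(ols)["cohortcontrol"]),
               tolerance = 1e-6)
  expect_equal(res$beta_offspring[1], unname(coef(ols)["cohortoffspring"]),
               tolerance = 1e-6)
})

test_that("MS GEE type-I error and effect recovery on triplicate data", {
  # directly constructed protein x profile matrix: subject-level noise shared
  # across the triplicate, replicate-level technical noise on top
  man <- simulate_manifest(sim_config(seed = 32))
  set.seed(32)
  n_sub <- nrow(man)
  profiles <- data.frame(
    run_id = rep(paste0("r", 1:3), each = n_sub),
    pool_id = rep(man$pool_id, 3), replicate = rep(1:3, each = n_sub),
    channel = rep(man$channel, 3), subject_id = rep(man$subject_id, 3),
    profile_id = paste0(rep(man$subject_id, 3), "_", rep(1:3, each = n_sub)))
  G <- 500
  vals <- matrix(rnorm(G * n_sub, 0, 0.5), G, n_sub)[, rep(seq_len(n_sub), 3)] +
    matrix(rnorm(G * 3 * n_sub, 0, 0.2), G, 3 * n_sub)
  rownames(vals) <- paste0("PR", seq_len(G)); colnames(vals) <- profiles$profile_id
  res <- fit_ms_differential(vals, profiles, man)
  rej <- mean(res$global_p < 0.05, na.rm = TRUE)
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)

  cfg2 <- sim_config(n_proteins = 150, effect_size = 1, frac_conserved = 1,
                     frac_ms_effect_only = 0, frac_soma_effect_only = 0,
                     batch_sd = 0, missingness_params = c(intercept = -Inf, slope = 0),
                     run_dropout_prob = 0, seed = 33)
  man2 <- simulate_manifest(cfg2)
  tr2 <- simulate_ground_truth(cfg2)
  pep2 <- simulate_peptide_data(man2, cfg2, tr2)
  pre2 <- suppressMessages(run_ms_preprocess(pep2, man2, depleted = NULL, qc = FALSE))
  res2 <- fit_ms_differential(pre2$values, pre2$profiles, man2)
  est <- res2$beta_control * sign(tr2$ms_beta_control[
    match(res2$feature_id, tr2$protein_accession)])
  expect_lt(abs(median(est, na.rm = TRUE) - 1), 0.1)
})

test_that("aptamer OLS uses F(2, n - 5) and matches the GEE stage on single replicates", {
  set.seed(34)
  man <- simulate_manifest(sim_config(seed = 35))   # 50 subjects
  samples <- man[, c("subject_id", "cohort", "gender", "year_of_collection")]
  vals <- matrix(rnorm(20 * 50, 8, 1), 20, 50,
                 dimnames = list(paste0("apt", 1:20), man$subject_id))
  res <- fit_soma_differential(vals, samples)
  expect_true(all(res$df_den == 45))               # n=50, 5 mean parameters
  # same single-replicate data through the MS stage gives matching estimates
  profiles <- data.frame(run_id = "r1", pool_id = man$pool_id, replicate = 1,
                         channel = man$channel, subject_id = man$subject_id,
                         profile_id = man$subject_id)
  res_ms <- fit_ms_differential(vals, profiles, man)
  expect_equal(res_ms$beta_control, res$beta_control, tolerance = 1e-6)
  expect_equal(res_ms$beta_offspring, res$beta_offspring, tolerance = 1e-6)
  # duplicated aptamer row gives identical results
  res2 <- fit_soma_differential(vals[c(1, 1), ], samples)
  expect_equal(res2$global_p[1], res2$global_p[2])
  expect_equal(res2$global_p[1], res$global_p[1])
})

test_that("aptamer stage is uniform under a permutation null and NA-robust", {
  set.seed(36)
  man <- simulate_manifest(sim_config(seed = 37))
  samples <- man[, c("subject_id", "cohort", "gender", "year_of_collection")]
  samples$cohort <- sample(samples$cohort)         # break any structure
  vals <- matrix(rnorm(1000 * 50, 8, 1), 1000, 50,
                 dimnames = list(paste0("apt", 1:1000), man$subject_id))
  res <- fit_soma_differential(vals, samples)
  expect_gt(stats::ks.test(res$global_p, "punif")$p.value, 0.01)
  # masked values are dropped per aptamer; too few observations -> NA
  vals[1, 1:45] <- NA
  res2 <- fit_soma_differential(vals, samples)
  expect_true(is.na(res2$global_p[1]))
  expect_false(is.na(res2$fdr[2]))
})
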