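test_that("remove_depleted drops exactly the listed proteins' peptides", {
  man <- tiny_manifest()
  M <- matrix(100, 10, nrow(man) * 3)
  tab <- peptides_from_matrix(M, man,
                              protein = rep(c("P1", "P2"), each = 5),
                              gene = rep(c("ALBU", "OTHER"), each = 5))
  out <- remove_depleted(tab, "ALBU")
  expect_equal(sort(unique(out$gene_symbol)), "OTHER")
  expect_equal(length(unique(out$peptide_id)), 5)
  expect_equal(attr(out, "n_removed"), 5)
  # disjoint list: identity plus warning
  expect_warning(out2 <- remove_depleted(tab, c("OTHER", "NOPE")), "NOPE")
  expect_equal(nrow(out2), 5 * nrow(man) * 3)
  # default list carries the 12 depletion-column symbols
  expect_length(default_depleted_proteins(), 12)
  expect_true(all(c("ALBU", "TRFE", "IGH") %in% default_depleted_proteins()))
})

test_that("filter_missingness applies the three 20% rules at their boundaries", {
  fx <- filter_fixture()
  out <- suppressMessages(filter_missingness(fx$table, fx$manifest))
  expect_setequal(unique(out$peptide_id), fx$expected_retained)
  rep <- attr(out, "filter_report")
  expect_equal(rep$n_removed, length(fx$expected_removed))
  expect_equal(unname(rep$thresholds), c(30, 3, 1))
  # idempotence: filtering a filtered table removes nothing
  out2 <- suppressMessages(filter_missingness(out, fx$manifest))
  expect_setequal(unique(out2$peptide_id), unique(out$peptide_id))
})

test_that("imputation bounds, aggregation mass and determinism", {
  man <- tiny_manifest(n_per_cohort = c(2, 2, 2), n_pools = 1)
  # two peptides of one protein; peptide 2 missing in some profiles
  M <- rbind(rep(200, 18), rep(300, 18))
  M[2, c(1, 5, 9)] <- NA
  M[1, 2] <- 100                                 # run minimum
  tab <- peptides_from_matrix(M, man)
  agg <- impute_and_aggregate(tab, man, seed = 21)
  expect_equal(dim(agg$values), c(1L, 18L))
  # no-missing profile: protein = sum of peptides
  expect_equal(unname(agg$values[1, 3]), 500)
  # imputed values bounded by the run minimum
  run1 <- agg$profiles$run_id == agg$profiles$run_id[1]
  imput <- agg$peptide_values[2, c(1, 5, 9)]
  mins <- tapply(tab$intensity, tab$run_id, min)
  expect_true(all(imput > 0 & imput < mins[agg$profiles$run_id[c(1, 5, 9)]]))
  # aggregation conserves peptide mass everywhere (raw scale, exact)
  expect_equal(unname(agg$values[1, ]), unname(colSums(agg$peptide_values)))
  # deterministic given seed
  expect_identical(agg$values, impute_and_aggregate(tab, man, seed = 21)$values)
  expect_false(identical(agg$values, impute_and_aggregate(tab, man, seed = 22)$values))
})

test_that("impute_and_aggregate errors when a run has no observed value", {
  man <- tiny_manifest(n_per_cohort = c(2, 2, 2), n_pools = 1)
  M <- matrix(100, 2, 18)
  M[, 1:6] <- NA                                 # entire first run missing
  tab <- peptides_from_matrix(M, man)
  expect_error(impute_and_aggregate(tab, man), "no observed intensities")
})

test_that("normalize_log2 follows the trimmed-mean definition and is scale invariant", {
  m <- cbind(a = c(1:10), b = rep(4, 10))
  out <- normalize_log2(m, trim = 0.1)
  expect_equal(unname(out[1, "a"]), log2(1 / 5.5)) # trimmed mean of 1..10 is 5.5
  expect_equal(unname(out[, "b"]), rep(0, 10))   # constant profile -> all zero
  # multiplying a profile by c > 0 changes nothing
  m2 <- m; m2[, "a"] <- m2[, "a"] * 4
  expect_equal(normalize_log2(m2), out)
  expect_error(normalize_log2(cbind(c(-5, rep(1, 9)), rep(1, 10)) - 1), "trimmed mean")
})

test_that("missingness_qc flags constructed informative missingness only", {
  man <- tiny_manifest(n_per_cohort = c(9, 17, 24), n_pools = 5, seed = 31)
  set.seed(77)
  n_prof <- 150
  M <- matrix(100, 30, n_prof)
  prof_cohort <- rep(man$cohort[order(man$pool_id, man$channel)], times = 3)
  # profile order in peptides_from_matrix is run-major; rebuild it
  prof <- expand.grid(replicate = 1:3, i = seq_len(nrow(man)))
  prof$run_id <- paste0(man$pool_id[prof$i], "_R", prof$replicate)
  prof$channel <- man$channel[prof$i]
  ord <- order(prof$run_id, prof$channel)
  coh <- man$cohort[prof$i][ord]
  # peptides 1-27: missing completely at random at 10%
  for (p in 1:27) M[p, sample.int(n_prof, 15)] <- NA
  # peptide 28: missing in every centenarian profile and nowhere else.
  # This is perfect separation: the logistic GEE cannot estimate it and the
  # peptide must come back untestable rather than flagged or crashed.
  M[28, coh == "centenarian"] <- NA
  # peptide 29: near-complete cohort-driven missingness, still estimable
  cent <- which(coh == "centenarian")
  M[29, cent[-(1:2)]] <- NA
  M[29, which(coh != "centenarian")[c(5, 40, 80, 100, 110, 120)]] <- NA
  # peptide 30: present everywhere -> skipped
  tab <- peptides_from_matrix(M, man, protein = sprintf("PR%02d", 1:30),
                              gene = sprintf("GN%02d", 1:30))
  qc <- suppressMessages(missingness_qc(tab, man))
  expect_false(qc$testable[qc$peptide_id == "PEP28"])
  expect_false(qc$flagged[qc$peptide_id == "PEP28"])
  tested <- qc[qc$testable, ]
  expect_equal(tested$peptide_id[which.min(tested$p)], "PEP29")
  expect_true(qc$flagged[qc$peptide_id == "PEP29"])
  # MCAR peptides are not flagged at the Bonferroni level
  expect_false(any(qc$flagged[qc$peptide_id != "PEP29"]))
})

test_that("correct_batches removes run shifts while keeping cohort signal", {
  cfg <- sim_config(n_proteins = 60, batch_sd = 0.6, effect_size = 1,
                    frac_conserved = 0.3, frac_ms_effect_only = 0,
                    frac_soma_effect_only = 0, seed = 13)
  man <- simulate_manifest(cfg)
  tr <- simulate_ground_truth(cfg)
  pep <- simulate_peptide_data(man, cfg, tr)
  res <- suppressMessages(run_ms_preprocess(pep, man, depleted = NULL, qc = FALSE))
  # run-level mean differences mostly gone
  run_means <- apply(res$values, 2, mean)
  by_run <- tapply(run_means, res$profiles$run_id, mean)
  expect_lt(max(by_run) - min(by_run), 0.12)
  # effect magnitude recovered within +/- 0.15 for conserved proteins
  # (sign-aligned: ratio normalization can add a small common shift to all
  # features when many proteins carry effects, which cancels in the
  # pair-of-cohorts comparisons of interest)
  diffres <- fit_ms_differential(res$values, res$profiles, man)
  cons <- tr[tr$conserved & tr$protein_accession %in% diffres$feature_id, ]
  est <- diffres$beta_control[match(cons$protein_accession, diffres$feature_id)]
  expect_lt(abs(median(est * sign(cons$ms_beta_control)) - 1), 0.15)
})
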