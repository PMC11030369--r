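mk_diff <- function(ids, p = 0.5, bc = 1, bo = 1) {
  data.frame(feature_id = ids, beta_control = bc, beta_offspring = bo,
             se_control = 0.1, se_offspring = 0.1, global_p = p,
             fdr = p, stringsAsFactors = FALSE)
}

test_that("pair_shared_features intersects platforms and partitions the rest", {
  ms <- mk_diff(c("A", "B"))
  soma <- mk_diff(c("a1", "a2", "a3"))
  annot <- data.frame(aptamer_id = c("a1", "a2", "a3"),
                      protein_accession = c("A", "A", "C"),
                      gene_symbol = c("gA", "gA", "gC"))
  out <- pair_shared_features(ms, soma, annot)
  expect_equal(out$pairs$protein_accession, c("A", "A"))
  expect_equal(out$pairs$aptamer_id, c("a1", "a2"))
  expect_equal(out$ms_only$feature_id, "B")
  expect_equal(out$soma_only$feature_id, "a3")
  expect_equal(unname(out$counts["pooled_total"]), 4)
  # disjoint platforms
  out2 <- pair_shared_features(mk_diff("X"), soma, annot)
  expect_equal(nrow(out2$pairs), 0)
  # unannotated aptamers dropped with a warning
  expect_warning(pair_shared_features(ms, mk_diff("zz"), annot), "without annotation")
})

test_that("266 shared proteins with 87 two-aptamer proteins give 353 pairs", {
  prots <- sprintf("P%03d", 1:300)
  shared <- prots[1:266]
  ms <- mk_diff(shared)
  apt1 <- data.frame(aptamer_id = paste0(shared, "_1"), protein_accession = shared,
                     gene_symbol = shared)
  apt2 <- data.frame(aptamer_id = paste0(shared[1:87], "_2"),
                     protein_accession = shared[1:87], gene_symbol = shared[1:87])
  extra <- data.frame(aptamer_id = sprintf("O%04d", 1:4050),
                      protein_accession = sprintf("OP%04d", 1:4050),
                      gene_symbol = sprintf("OP%04d", 1:4050))
  annot <- rbind(apt1, apt2, extra)
  soma <- mk_diff(annot$aptamer_id)
  out <- pair_shared_features(ms, soma, annot)
  expect_equal(nrow(out$pairs), 353)
  expect_equal(unname(out$counts["shared_proteins"]), 266)
  expect_equal(nrow(out$soma_only), 4050)
})

test_that("effective-studies estimate hits its algebraic limits", {
  studies <- simulate_paired_null_studies(n_features = 500, seed = 40)
  # duplicated studies: r = 1, k_eff = 1
  est <- estimate_effective_studies(studies$ms$p, studies$ms$p,
                                    studies$ms$sign, studies$ms$sign)
  expect_equal(est$r, 1)
  expect_equal(est$k_eff, 1)
  expect_equal(est$lambda, c(2, 0))
  # r = 0.48 -> k_eff = 2 - 0.48^2 ~ 1.77 (the magnitude reported for
  # a 50-subject study nested in a 224-subject study)
  expect_equal(2 - 0.48^2, 1.7696, tolerance = 1e-4)
  # too few pairs -> instructive error
  expect_error(estimate_effective_studies(runif(5), runif(5),
                                          rep(1, 5), rep(1, 5)),
               "supply k_eff manually")
  # sign-0 pairs are excluded
  s <- studies$ms$sign; s[1:490] <- 0
  expect_error(estimate_effective_studies(studies$ms$p, studies$soma$p,
                                          s, studies$soma$sign),
               "usable pairs")
})

test_that("adjmaxp follows the stated power law and propagates NA", {
  expect_equal(adjmaxp(0.04, 0.01, 2), 0.0016)
  expect_equal(adjmaxp(0.04, 0.01, 1), 0.04)
  expect_equal(adjmaxp(0.05, 0.05, 1.77), 0.05^1.77)
  expect_equal(round(adjmaxp(0.05, 0.05, 1.77), 5), 0.00498)
  expect_true(is.na(adjmaxp(NA, 0.5, 1.5)))
  expect_error(adjmaxp(0, 0.5, 1.5), "\\(0, 1\\]")
  expect_error(adjmaxp(0.5, 0.5, 2.5), "k_eff")
  # monotone nondecreasing in each argument and in k_eff for p < 1
  p <- seq(0.01, 0.99, by = 0.02)
  expect_true(all(diff(adjmaxp(p, 0.5, 1.5)) >= 0))
  expect_true(all(adjmaxp(0.3, 0.4, 1.2) >= adjmaxp(0.3, 0.4, 1.8)))
  # p_cons never exceeds the max input p (k_eff >= 1)
  expect_true(all(adjmaxp(p, 0.5, 1.77) <= pmax(p, 0.5)))
})

test_that("pooled_fdr widens the correction and enforces disjoint sets", {
  pairs <- data.frame(feature_id = paste0("pr", 1:353), p = runif(353))
  ms <- data.frame(feature_id = paste0("m", 1:132), p = runif(132))
  soma <- data.frame(feature_id = paste0("s", 1:4050), p = runif(4050))
  out <- pooled_fdr(pairs, ms, soma)
  expect_equal(nrow(out), 4535)
  expect_true(all(out$q >= out$p - 1e-12 | out$q == max(out$q)))
  expect_error(pooled_fdr(pairs, data.frame(feature_id = "pr1", p = 0.5), NULL),
               "overlap")
  # empty unique sets reduce to BH over pairs alone
  alone <- pooled_fdr(pairs)
  expect_equal(alone$q, bh_fdr(pairs$p))
  # adding unique features with p = 1 can only raise (or keep) a pair's q
  ones <- data.frame(feature_id = paste0("u", 1:50), p = 1)
  with_ones <- pooled_fdr(pairs, ones)
  expect_true(all(with_ones$q[1:353] >= alone$q - 1e-12))
})

test_that("conservation classes and directions follow the sign rules", {
  pairs <- data.frame(
    protein_accession = c("IGFALS", "KNG1", "TGFBI", "NS", "NEG"),
    aptamer_id = paste0("a", 1:5),
    # (ms_control, ms_offspring, soma_control, soma_offspring)
    ms_beta_control = c(0.639, 0.172, 0.5, 1, -0.4),
    ms_beta_offspring = c(0.793, 0.260, 0.5, 1, -0.3),
    soma_beta_control = c(0.741, -0.047, -0.5, 1, -0.2),
    soma_beta_offspring = c(0.642, 0.151, -0.5, 1, -0.1)
  )
  q <- c(1e-6, 0.002, 0.01, 0.5, 0.001)
  out <- classify_conservation(pairs, q, threshold = 0.05)
  expect_equal(out$conservation_class,
               c("full", "partial", "discordant", "ns", "full"))
  expect_equal(out$assigned_direction,
               c("higher_in_offspring_controls",     # all four positive
                 "higher_in_offspring_controls",     # offspring comparison conserved
                 "none", "none",
                 "higher_in_centenarians"))          # all four negative
  # zero coefficient counts as mismatch
  pz <- pairs[1, ]
  pz$soma_beta_control <- 0
  outz <- suppressMessages(classify_conservation(pz, 0.001))
  expect_equal(outz$conservation_class, "partial")
  # protein-level signature takes the best pair and drops discordant
  sig <- conserved_signature(out)
  expect_setequal(sig$protein_accession, c("IGFALS", "KNG1", "NEG"))
})

test_that("max-p without adjustment is anti-conservative under strong dependence", {
  studies <- simulate_paired_null_studies(n_features = 2000, shared_frac = 1,
                                          platform_sd = 0, seed = 41)
  p_cons <- adjmaxp(studies$ms$p, studies$soma$p, 2)
  # identical studies: max p = p, squaring makes it stochastically smaller
  expect_lt(ks.test(p_cons, "punif", alternative = "greater")$p.value, 0.01)
  expect_lt(mean(p_cons), 0.4)
})
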