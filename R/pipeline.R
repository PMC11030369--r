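#' End-to-end synthetic cross-platform conservation study
#'
#' Generates a complete synthetic study (manifest, TMT peptide data, aptamer
#' data, ground truth), runs both platform pipelines and the conservation
#' analysis, and scores the recovered conserved signature against the truth.
#'
#' @param config a [sim_config()].
#' @param fdr pooled-FDR threshold for the conserved signature.
#' @param qc run the (slow, diagnostic-only) missingness QC regressions.
#' @param k_eff override the estimated effective number of studies.
#' @return list: `truth`, `manifest`, `ms` (differential table), `soma`,
#'   `pairing`, `keff`, `pooled`, `classified`, `signature`, `metrics`
#'   (sensitivity, fdp, n_detected, n_conserved_measured).
#' @export
run_conservation_study <- function(config, fdr = 0.05, qc = FALSE,
                                   k_eff = NULL) {
  manifest <- simulate_manifest(config)
  truth <- simulate_ground_truth(config)
  peptides <- simulate_peptide_data(manifest, config, truth)
  soma_raw <- simulate_somascan(manifest, config, truth)

  ms_pre <- run_ms_preprocess(peptides, manifest, depleted = NULL, qc = qc,
                              n_replicates = config$n_replicates,
                              seed = sub_seed(config$seed, 8L))
  soma_log2 <- preprocess_soma(soma_raw$rfu)

  ms_diff <- fit_ms_differential(ms_pre$values, ms_pre$profiles, manifest)
  soma_diff <- fit_soma_differential(soma_log2, soma_raw$samples)

  pairing <- pair_shared_features(ms_diff, soma_diff, soma_raw$annot)
  pr <- pairing$pairs
  keff <- if (is.null(k_eff)) {
    estimate_effective_studies(pr$ms_p, pr$soma_p,
                               pr$ms_beta_control, pr$soma_beta_control)
  } else list(r = NA_real_, lambda = c(NA_real_, NA_real_), k_eff = k_eff,
              n_used = NA_integer_)
  p_cons <- adjmaxp(pr$ms_p, pr$soma_p, keff$k_eff)

  pair_ids <- paste0(pr$protein_accession, "|", pr$aptamer_id)
  pooled <- pooled_fdr(
    data.frame(feature_id = pair_ids, p = p_cons),
    data.frame(feature_id = pairing$ms_only$feature_id,
               p = pairing$ms_only$global_p),
    data.frame(feature_id = pairing$soma_only$feature_id,
               p = pairing$soma_only$global_p)
  )
  q_pairs <- pooled$q[match(pair_ids, pooled$feature_id)]
  classified <- classify_conservation(pr, q_pairs, threshold = fdr)
  signature <- conserved_signature(classified)

  detected <- unique(signature$protein_accession)
  conserved <- truth$protein_accession[truth$conserved]
  measured <- conserved[conserved %in% pr$protein_accession]
  metrics <- list(
    sensitivity = if (length(conserved)) length(intersect(detected, conserved)) /
      length(conserved) else NA_real_,
    fdp = if (length(detected)) length(setdiff(detected, conserved)) /
      length(detected) else 0,
    n_detected = length(detected),
    n_conserved_measured = length(measured)
  )
  list(truth = truth, manifest = manifest, ms = ms_diff, soma = soma_diff,
       pairing = pairing, keff = keff, pooled = pooled,
       classified = classified, signature = signature, metrics = metrics)
}
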