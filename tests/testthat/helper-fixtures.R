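# Shared fixture builders. Everything is generated in code; no data files.

# Minimal manifest: n subjects per cohort spread over `n_pools` pools.
tiny_manifest <- function(n_per_cohort = c(2, 2, 2), n_pools = 2,
                          n_channels = 10, seed = 42) {
  simulate_manifest(sim_config(
    n_per_cohort = stats::setNames(n_per_cohort,
                                   c("centenarian", "offspring", "control")),
    n_pools = n_pools, n_channels = n_channels, seed = seed))
}

# Long peptide table from an explicit peptide x profile intensity matrix.
# `mat` rows are peptides; NA entries become absent rows (missing cells).
peptides_from_matrix <- function(mat, manifest, n_replicates = 3,
                                 protein = rep("PROTA", nrow(mat)),
                                 gene = rep("GENEA", nrow(mat))) {
  prof <- expand.grid(replicate = seq_len(n_replicates),
                      i = seq_len(nrow(manifest)), stringsAsFactors = FALSE)
  prof$pool_id <- manifest$pool_id[prof$i]
  prof$channel <- manifest$channel[prof$i]
  prof$run_id <- paste0(prof$pool_id, "_R", prof$replicate)
  prof <- prof[order(prof$run_id, prof$channel), ]
  stopifnot(ncol(mat) == nrow(prof))
  rows <- do.call(rbind, lapply(seq_len(nrow(mat)), function(p) {
    keep <- !is.na(mat[p, ])
    data.frame(peptide_id = sprintf("PEP%02d", p),
               protein_accession = protein[p], gene_symbol = gene[p],
               run_id = prof$run_id[keep], pool_id = prof$pool_id[keep],
               replicate = prof$replicate[keep], channel = prof$channel[keep],
               intensity = mat[p, keep], stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

# Reference-design (5 pools x 10 channels x 3 replicates = 150 profiles)
# fixture with hand-constructed missingness patterns for the filter rules.
# Profiles are ordered run-major (runs sorted, channels 1..10 within run).
filter_fixture <- function() {
  man <- tiny_manifest(n_per_cohort = c(9, 17, 24), n_pools = 5, seed = 11)
  n_prof <- 150
  runs <- sort(unique(paste0(man$pool_id[order(man$pool_id)], "")))
  # profile layout replicated from peptides_from_matrix: run-major
  prof <- expand.grid(replicate = 1:3, i = seq_len(nrow(man)))
  prof$pool_id <- man$pool_id[prof$i]
  prof$channel <- man$channel[prof$i]
  prof$run_id <- paste0(prof$pool_id, "_R", prof$replicate)
  prof <- prof[order(prof$run_id, prof$channel), ]
  run_ids <- sort(unique(prof$run_id))            # 15 runs, P1_R1..P5_R3

  M <- matrix(100, 20, n_prof)                    # peptide x profile, NA = missing
  miss <- function(p, idx) M[p, idx] <<- NA
  in_run <- function(r) which(prof$run_id == r)
  # 1: complete -> retained
  # 2: exactly 30 missing, spread over all 15 runs (2 per run) -> removed (rule 1 boundary)
  for (r in run_ids) miss(2, in_run(r)[1:2])
  # 3: 29 missing, spread -> retained
  for (r in run_ids[1:14]) miss(3, in_run(r)[1:2])
  miss(3, in_run(run_ids[15])[1])
  # 4: 3 full runs in 3 different pools -> removed (rule 2 boundary; also 30 profiles)
  for (r in c("P1_R1", "P2_R2", "P3_R3")) miss(4, in_run(r))
  # 5: 2 full runs of the same pool -> retained (20 profiles, 2 runs, pool survives)
  for (r in c("P1_R1", "P1_R2")) miss(5, in_run(r))
  # 6: all 3 runs of pool P2 -> removed (rule 3 boundary: 1 of 5 pools)
  for (r in c("P2_R1", "P2_R2", "P2_R3")) miss(6, in_run(r))
  # 7: 2 full runs + 9 scattered = 29 profiles -> retained
  for (r in c("P4_R1", "P5_R2")) miss(7, in_run(r))
  miss(7, in_run("P3_R1")[1:9])
  # 8: 40 scattered (max 3 per run) -> removed (rule 1)
  k <- 0
  for (r in run_ids) { miss(8, in_run(r)[1:3]); k <- k + 3; if (k >= 39) break }
  miss(8, in_run(run_ids[14])[10])
  # 9: missing in 149 of 150 profiles -> removed
  miss(9, 2:n_prof)
  # 10: 1 missing value -> retained
  miss(10, 1)
  # 11-20: complete -> retained
  expected_removed <- sprintf("PEP%02d", c(2, 4, 6, 8, 9))
  list(table = peptides_from_matrix(M, man,
                                    protein = sprintf("PR%02d", 1:20),
                                    gene = sprintf("GN%02d", 1:20)),
       manifest = man,
       expected_retained = setdiff(sprintf("PEP%02d", 1:20), expected_removed),
       expected_removed = expected_removed)
}

# Independent hypergeometric upper-tail oracle by explicit log-gamma sum.
hyper_tail_oracle <- function(k, K, n, N) {
  j <- seq(k, min(n, K))
  if (length(j) == 0) return(0)
  lg <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  sum(exp(lg))
}
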