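#' Default depleted-protein list
#'
#' Gene symbols of the 12 high-abundance serum proteins targeted by the
#' depletion column; residual peptides annotated to them are excluded
#' before any statistics.
#'
#' @export
default_depleted_proteins <- function() {
  c("ALBU", "APOA1", "APOA2", "CRP", "A1AG1", "A1AG2",
    "A1AT", "A2MG", "FIB", "HPT", "IGH", "TRFE")
}

#' Remove peptides of depleted proteins
#'
#' Drops every peptide annotated (by gene symbol or accession) to a listed
#' protein. Identifiers in the list that match nothing produce a warning,
#' not an error.
#'
#' @param table peptide table (long format).
#' @param depleted character vector of gene symbols and/or accessions.
#' @return filtered peptide table; attribute `n_removed` holds the count of
#'   removed peptide ids.
#' @export
remove_depleted <- function(table, depleted = default_depleted_proteins()) {
  if (length(depleted) == 0L) stop("depleted list must be nonempty")
  hit <- table$gene_symbol %in% depleted | table$protein_accession %in% depleted
  known <- depleted %in% c(table$gene_symbol, table$protein_accession)
  if (any(!known)) {
    warning("identifiers not present in table: ",
            paste(depleted[!known], collapse = ", "))
  }
  n_removed <- length(unique(table$peptide_id[hit]))
  message("remove_depleted: removed ", n_removed, " peptides of ",
          sum(known), " matched depleted proteins")
  out <- table[!hit, , drop = FALSE]
  attr(out, "n_removed") <- n_removed
  out
}

# Full profile grid (run x sample channel with subject annotation) implied by
# the manifest and the run structure observed in the table. Channels beyond
# the sample channels (the pooled reference) are excluded.
profile_grid <- function(table, manifest, n_replicates = NULL) {
  dt <- data.table::as.data.table(table)
  runs <- unique(dt[, c("run_id", "pool_id", "replicate")])
  if (!is.null(n_replicates)) {
    runs <- data.table::as.data.table(
      expand.grid(pool_id = unique(manifest$pool_id),
                  replicate = seq_len(n_replicates),
                  stringsAsFactors = FALSE))
    runs[, run_id := paste0(pool_id, "_R", replicate)]
  }
  man <- data.table::as.data.table(manifest)
  prof <- merge(runs, man[, c("pool_id", "channel", "subject_id")],
                by = "pool_id", allow.cartesian = TRUE)
  prof[, profile_id := paste0(run_id, ":", channel)]
  data.table::setorder(prof, pool_id, replicate, channel)
  prof
}

# Peptide x profile presence matrix (TRUE = observed with intensity > 0).
presence_matrix <- function(table, prof) {
  dt <- data.table::as.data.table(table)
  dt <- dt[channel %in% unique(prof$channel)]
  dt[, profile_id := paste0(run_id, ":", channel)]
  peps <- sort(unique(dt$peptide_id))
  M <- matrix(FALSE, length(peps), nrow(prof),
              dimnames = list(peps, prof$profile_id))
  obs <- dt[intensity > 0]
  M[cbind(match(obs$peptide_id, peps), match(obs$profile_id, prof$profile_id))] <- TRUE
  M
}

#' Missingness QC: association between missingness and cohort
#'
#' Per peptide, a logistic GEE of the binary missingness indicator on cohort,
#' year of collection and gender, clustered by subject across replicate runs
#' (exchangeable working correlation), tested globally on the two cohort
#' coefficients (2-df robust Wald). A cohort-associated missingness pattern
#' suggests informative missingness. Peptides missing everywhere or nowhere
#' carry no information and are skipped; separation or non-convergence marks
#' a peptide untestable (logged, never flagged).
#'
#' @param table peptide table.
#' @param manifest sample manifest.
#' @param n_replicates replicates per pool (fixes the full profile grid even
#'   for peptides absent from whole runs).
#' @param alpha familywise level for the Bonferroni flag.
#' @return data.frame: peptide_id, p, testable, flagged; attribute
#'   `n_skipped` counts degenerate (all-present / all-missing) peptides.
#' @export
missingness_qc <- function(table, manifest, n_replicates = 3L, alpha = 0.05) {
  if (length(unique(manifest$cohort)) < 2L) stop("need at least 2 cohorts")
  prof <- profile_grid(table, manifest, n_replicates)
  M <- presence_matrix(table, prof)
  X <- stats::model.matrix(
    ~ cohort + year_of_collection + gender,
    data.frame(cohort = factor(manifest$cohort[match(prof$subject_id, manifest$subject_id)],
                               levels = c("centenarian", "offspring", "control")),
               year_of_collection = scale(manifest$year_of_collection[
                 match(prof$subject_id, manifest$subject_id)])[, 1],
               gender = manifest$gender[match(prof$subject_id, manifest$subject_id)]))
  cidx <- grep("^cohort", colnames(X))
  id <- prof$subject_id

  res <- lapply(rownames(M), function(pep) {
    miss <- as.numeric(!M[pep, ])
    if (all(miss == 0) || all(miss == 1)) {
      return(data.frame(peptide_id = pep, p = NA_real_, testable = FALSE,
                        skipped = TRUE))
    }
    p <- tryCatch({
      fit <- gee_fit(X, miss, id, family = "binomial")
      if (!fit$converged) NA_real_ else gee_wald(fit, cidx)$p
    }, error = function(e) NA_real_)
    data.frame(peptide_id = pep, p = p, testable = !is.na(p), skipped = FALSE)
  })
  res <- do.call(rbind, res)
  n_tested <- sum(res$testable)
  res$flagged <- res$testable & !is.na(res$p) & res$p < alpha / max(n_tested, 1L)
  n_unt <- sum(!res$testable & !res$skipped)
  message("missingness_qc: ", n_tested, " peptides tested, ",
          sum(res$skipped), " skipped (no variation), ", n_unt,
          " untestable, ", sum(res$flagged), " flagged at Bonferroni ", alpha)
  attr(res, "n_skipped") <- sum(res$skipped)
  res$skipped <- NULL
  res
}

#' Three-rule 20% missingness filter
#'
#' A peptide is removed when any of the following holds: missing in at least
#' 20% of profiles (30 of 150 in the reference design); missing-in-run
#' (absent from every sample channel of a run) in at least 20% of runs
#' (3 of 15); or missing-in-pool (missing-in-run for every replicate of a
#' pool) in at least 20% of pools (1 of 5). All three are "at least", so
#' exact boundaries are removed.
#'
#' @inheritParams missingness_qc
#' @return filtered peptide table; attribute `filter_report` is a list with
#'   per-rule and total removal counts.
#' @export
filter_missingness <- function(table, manifest, n_replicates = 3L) {
  prof <- profile_grid(table, manifest, n_replicates)
  M <- presence_matrix(table, prof)
  n_prof <- ncol(M)
  run_of <- prof$run_id
  pool_of_run <- unique(data.frame(run_id = prof$run_id, pool_id = prof$pool_id))
  n_runs <- nrow(pool_of_run)
  n_pools <- length(unique(pool_of_run$pool_id))

  miss_prof <- rowSums(!M)
  # run fully missing: no observed channel of that run
  obs_run <- t(rowsum(t(M * 1), run_of))            # peptide x run observed counts
  run_missing <- obs_run == 0
  miss_runs <- rowSums(run_missing)
  pool_missing <- t(rowsum(t((!run_missing) * 1), pool_of_run$pool_id[
    match(colnames(run_missing), pool_of_run$run_id)])) == 0
  miss_pools <- rowSums(pool_missing)

  r1 <- miss_prof >= 0.2 * n_prof
  r2 <- miss_runs >= 0.2 * n_runs
  r3 <- miss_pools >= 0.2 * n_pools
  drop <- r1 | r2 | r3
  report <- list(n_input = nrow(M),
                 removed_profiles_rule = sum(r1),
                 removed_runs_rule = sum(r2),
                 removed_pools_rule = sum(r3),
                 n_removed = sum(drop), n_retained = sum(!drop),
                 thresholds = c(profiles = ceiling(0.2 * n_prof),
                                runs = ceiling(0.2 * n_runs),
                                pools = ceiling(0.2 * n_pools)))
  message("filter_missingness: removed ", report$n_removed, " of ",
          report$n_input, " peptides (profiles rule ", sum(r1),
          ", runs rule ", sum(r2), ", pools rule ", sum(r3), ")")
  out <- table[table$peptide_id %in% rownames(M)[!drop], , drop = FALSE]
  attr(out, "filter_report") <- report
  out
}

#' Impute missing peptide values and aggregate to proteins
#'
#' Every missing (peptide, profile) cell is imputed with a draw from
#' Uniform(0, m_b), where m_b is the minimum observed intensity of the
#' peptide's run (batch); draws are strictly positive almost surely, keeping
#' downstream log2 finite. Protein abundance is then the sum of its peptides'
#' (observed or imputed) raw intensities per profile.
#'
#' @inheritParams missingness_qc
#' @param seed RNG seed for the imputation draws.
#' @return list: `values` (protein x profile raw matrix), `profiles`
#'   (profile annotation: run, pool, replicate, channel, subject),
#'   `peptide_values` (peptide x profile matrix after imputation).
#' @export
impute_and_aggregate <- function(table, manifest, n_replicates = 3L, seed = 1L) {
  prof <- profile_grid(table, manifest, n_replicates)
  dt <- data.table::as.data.table(table)
  dt <- dt[channel %in% unique(prof$channel) & intensity > 0]
  dt[, profile_id := paste0(run_id, ":", channel)]
  peps <- sort(unique(dt$peptide_id))
  prot_of_pep <- dt$protein_accession[match(peps, dt$peptide_id)]

  V <- matrix(NA_real_, length(peps), nrow(prof),
              dimnames = list(peps, prof$profile_id))
  V[cbind(match(dt$peptide_id, peps), match(dt$profile_id, prof$profile_id))] <-
    dt$intensity

  run_min <- tapply(dt$intensity, dt$run_id, min)
  if (!all(unique(prof$run_id) %in% names(run_min))) {
    stop("run(s) with no observed intensities: no imputation bound: ",
         paste(setdiff(unique(prof$run_id), names(run_min)), collapse = ", "))
  }
  miss <- which(is.na(V), arr.ind = TRUE)
  with_seed(seed, {
    if (nrow(miss) > 0) {
      bounds <- run_min[prof$run_id[miss[, 2]]]
      V[miss] <- stats::runif(nrow(miss), 0, bounds)
    }
  })
  P <- rowsum(V, prot_of_pep)
  list(values = P, profiles = data.table::setDF(prof), peptide_values = V)
}

#' Trimmed-mean profile normalization and log2 transform
#'
#' Each profile (column) is divided by its own trimmed mean (default: 10%
#' of observations trimmed from each tail) and log2-transformed. Division by
#' a profile-level scale makes the result invariant to any multiplicative
#' profile factor (loading, labeling efficiency).
#'
#' @param values protein x profile positive matrix.
#' @param trim trimmed proportion per tail.
#' @param total_trim if TRUE, interpret `trim` as the total trimmed
#'   proportion (split across tails).
#' @return log2 normalized matrix.
#' @export
normalize_log2 <- function(values, trim = 0.1, total_trim = FALSE) {
  tm <- apply(values, 2L, trimmed_mean, trim = trim, total = total_trim)
  if (any(!is.finite(tm)) || any(tm <= 0)) {
    stop("nonpositive trimmed mean in profile(s): ",
         paste(colnames(values)[!is.finite(tm) | tm <= 0], collapse = ", "))
  }
  log2(sweep(values, 2L, tm, "/"))
}

#' Batch-correct a protein matrix across runs
#'
#' Applies the parametric empirical-Bayes adjustment of [combat_adjust()]
#' with the LC-MS/MS run as batch. By default cohort, gender and collection
#' year are included in the design so biological signal is preserved.
#'
#' @param values protein x profile log2 matrix.
#' @param profiles profile annotation (from [impute_and_aggregate()]).
#' @param manifest sample manifest.
#' @param protect_covariates include cohort/gender/year in the design.
#' @return corrected matrix.
#' @export
correct_batches <- function(values, profiles, manifest, protect_covariates = TRUE) {
  stopifnot(ncol(values) == nrow(profiles))
  mod <- NULL
  if (protect_covariates) {
    ann <- manifest[match(profiles$subject_id, manifest$subject_id), ]
    mod <- stats::model.matrix(~ cohort + gender + year_of_collection,
                               data.frame(cohort = factor(ann$cohort),
                                          gender = factor(ann$gender),
                                          year_of_collection = ann$year_of_collection))[, -1, drop = FALSE]
  }
  combat_adjust(values, profiles$run_id, mod = mod)
}

#' Run the full MS preprocessing chain
#'
#' Depleted-protein removal, optional missingness QC, the three 20%
#' missingness filters, uniform imputation, peptide-to-protein aggregation,
#' trimmed-mean/log2 normalization, and run-level batch correction.
#'
#' @param peptides raw peptide table.
#' @param manifest sample manifest.
#' @param depleted depleted-protein identifiers (NULL to skip removal).
#' @param n_replicates replicates per pool.
#' @param qc run the missingness QC regressions (diagnostic only; flagged
#'   peptides are reported, not removed, mirroring a QC step that flags
#'   nothing on well-behaved data).
#' @param seed imputation seed.
#' @param trim trimmed-mean proportion per tail.
#' @return list: `values` (protein x profile log2, batch corrected),
#'   `profiles`, `qc` (or NULL), `filter_report`.
#' @export
run_ms_preprocess <- function(peptides, manifest,
                              depleted = default_depleted_proteins(),
                              n_replicates = 3L, qc = TRUE, seed = 1L,
                              trim = 0.1) {
  tab <- peptides
  if (!is.null(depleted)) {
    has <- any(tab$gene_symbol %in% depleted | tab$protein_accession %in% depleted)
    if (has) tab <- remove_depleted(tab, depleted)
  }
  qc_res <- if (qc) missingness_qc(tab, manifest, n_replicates) else NULL
  tab <- filter_missingness(tab, manifest, n_replicates)
  report <- attr(tab, "filter_report")
  agg <- impute_and_aggregate(tab, manifest, n_replicates, seed = seed)
  norm <- normalize_log2(agg$values, trim = trim)
  corrected <- correct_batches(norm, agg$profiles, manifest)
  list(values = corrected, profiles = agg$profiles, qc = qc_res,
       filter_report = report)
}
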