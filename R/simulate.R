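#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generators in one validated
#' list. The defaults encode the study design the pipeline targets: 50
#' subjects (9 centenarians, 17 offspring, 24 controls) arranged in 5 TMT
#' pools of 10 channels run in triplicate (150 sample profiles), an
#' aptamer-array study of 224 subjects containing those 50 as a subset,
#' intensity-dependent peptide missingness, run-level batch effects, and a
#' 10% fraction of proteins with a 1.0 log2 cohort effect conserved across
#' both platforms.
#'
#' @param n_per_cohort subjects per cohort (centenarian, offspring, control).
#' @param n_pools,n_replicates,n_channels TMT design: pools, LC-MS/MS runs
#'   per pool, sample channels per pool.
#' @param n_proteins number of simulated proteins quantified by MS.
#' @param peptides_per_protein `c(mean, dispersion)` of a shifted
#'   negative-binomial peptide count (minimum 1 peptide).
#' @param frac_conserved fraction of proteins with a cohort effect on both
#'   platforms (same sign).
#' @param frac_ms_effect_only,frac_soma_effect_only fractions with a cohort
#'   effect on only one platform (null on the other).
#' @param effect_size log2 cohort effect (applied to both the control and
#'   offspring contrasts vs centenarians, random sign per protein).
#' @param sigma_subject subject-level biological SD (log2), shared between
#'   platforms for shared subjects.
#' @param sigma_tech replicate-level technical SD (log2) of an MS profile.
#' @param batch_sd SD of run-level batch shifts (log2).
#' @param protein_mean,protein_sd,peptide_sd latent log2 abundance scale.
#' @param gender_sd SD of per-protein gender effects.
#' @param missingness_params `c(intercept = a, slope = b)` of
#'   logit P(missing) = a - b * latent log2 intensity. Set
#'   `intercept = -Inf` for no missingness.
#' @param run_dropout_prob probability a peptide fails identification in an
#'   entire run (all channels missing).
#' @param soma_extra_subjects aptamer-study subjects beyond the MS subset.
#' @param soma_cohort_totals cohort totals of the full aptamer study.
#' @param frac_multi_aptamer fraction of MS proteins with 2 aptamers.
#' @param n_soma_only aptamers targeting proteins absent from MS.
#' @param soma_sigma platform measurement SD of a log2 RFU.
#' @param soma_outlier_prob probability of a gross outlier RFU entry.
#' @param year_range collection-year range.
#' @param n_subjects_rna,n_genes,family_size_range,frac_age_genes,
#'   age_slope_sd,rna_dispersion,sigma_g,sigma_e transcriptome generator:
#'   subjects, genes, kinship family sizes, fraction of age-associated genes,
#'   SD of their log2/year slopes, NB dispersion, genetic and residual SD.
#' @param seed base RNG seed; every generator derives a fixed sub-stream
#'   from it, so each is a pure function of (config, seed).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_per_cohort = c(centenarian = 9, offspring = 17, control = 24),
                       n_pools = 5L, n_replicates = 3L, n_channels = 10L,
                       n_proteins = 500L,
                       peptides_per_protein = c(mean = 5, dispersion = 2),
                       frac_conserved = 0.10,
                       frac_ms_effect_only = 0.05,
                       frac_soma_effect_only = 0.05,
                       effect_size = 1.0,
                       sigma_subject = 0.5,
                       sigma_tech = 0.2,
                       batch_sd = 0.3,
                       protein_mean = 20, protein_sd = 2, peptide_sd = 1,
                       gender_sd = 0.1,
                       missingness_params = c(intercept = 10, slope = 0.6),
                       run_dropout_prob = 0.02,
                       soma_extra_subjects = 174L,
                       soma_cohort_totals = c(centenarian = 77, offspring = 82, control = 65),
                       frac_multi_aptamer = 0.33,
                       n_soma_only = 200L,
                       soma_sigma = 0.5,
                       soma_outlier_prob = 0.002,
                       year_range = c(1995L, 2010L),
                       n_subjects_rna = 100L, n_genes = 1000L,
                       family_size_range = c(1L, 4L),
                       frac_age_genes = 0.10, age_slope_sd = 0.02,
                       rna_dispersion = 0.1, sigma_g = 0.5, sigma_e = 0.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  props <- c("frac_conserved", "frac_ms_effect_only", "frac_soma_effect_only",
             "frac_multi_aptamer", "run_dropout_prob", "soma_outlier_prob",
             "frac_age_genes")
  for (nm in props) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  }
  if (cfg$frac_conserved + cfg$frac_ms_effect_only + cfg$frac_soma_effect_only > 1) {
    stop("effect-class fractions sum to more than 1")
  }
  counts <- c("n_pools", "n_replicates", "n_channels", "n_proteins",
              "n_subjects_rna", "n_genes")
  for (nm in counts) if (cfg[[nm]] < 1) stop(nm, " must be positive")
  if (any(cfg$n_per_cohort < 0)) stop("cohort counts must be nonnegative")
  structure(cfg, class = "sim_config")
}

#' Simulate the sample manifest
#'
#' Assigns subjects of the three cohorts to TMT pools and channels. With the
#' default layout subjects are randomly permuted across pools (pool
#' composition was an open design choice); `stratified = TRUE` deals cohorts
#' round-robin so every pool has a near-proportional mix.
#'
#' @param config a [sim_config()].
#' @param stratified stratify cohorts across pools.
#' @return data.frame with columns subject_id, cohort, gender,
#'   year_of_collection, pool_id, channel.
#' @export
simulate_manifest <- function(config, stratified = FALSE) {
  n <- sum(config$n_per_cohort)
  capacity <- config$n_pools * config$n_channels
  if (n > capacity) {
    stop("cohort counts (", n, ") exceed pool capacity (", capacity, ")")
  }
  cohorts <- factor(rep(c("centenarian", "offspring", "control"),
                        times = config$n_per_cohort),
                    levels = c("centenarian", "offspring", "control"))
  with_seed(sub_seed(config$seed, 1L), {
    man <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      cohort = cohorts,
      gender = factor(sample(c("F", "M"), n, replace = TRUE), levels = c("F", "M")),
      year_of_collection = sample(seq(config$year_range[1], config$year_range[2]),
                                  n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    ord <- if (n == 0L) integer(0) else if (stratified) {
      order(stats::ave(seq_len(n), man$cohort, FUN = seq_along), man$cohort)
    } else {
      sample.int(n)
    }
    slot <- integer(n)
    slot[ord] <- seq_len(n)
    man$pool_id <- sprintf("P%d", (slot - 1L) %/% config$n_channels + 1L)
    man$channel <- (slot - 1L) %% config$n_channels + 1L
    if (n == 0L) {
      man$pool_id <- character(0); man$channel <- integer(0)
    }
    man
  })
}

#' Simulate per-protein ground truth
#'
#' Draws the effect class of every protein: conserved (same-sign cohort
#' effects on both platforms), MS-only effect, aptamer-only effect, or null.
#' Both cohort contrasts (control - centenarian, offspring - centenarian)
#' get the configured effect size with a common random sign per protein.
#'
#' @param config a [sim_config()].
#' @return data.frame keyed by protein_accession with per-platform true
#'   betas and a `conserved` flag.
#' @export
simulate_ground_truth <- function(config) {
  P <- config$n_proteins
  n_cons <- round(config$frac_conserved * P)
  n_ms <- round(config$frac_ms_effect_only * P)
  n_soma <- round(config$frac_soma_effect_only * P)
  with_seed(sub_seed(config$seed, 2L), {
    cls <- rep("null", P)
    pick <- sample.int(P, n_cons + n_ms + n_soma)
    cls[pick[seq_len(n_cons)]] <- "conserved"
    if (n_ms > 0) cls[pick[n_cons + seq_len(n_ms)]] <- "ms_only"
    if (n_soma > 0) cls[pick[n_cons + n_ms + seq_len(n_soma)]] <- "soma_only"
    sgn <- sample(c(-1, 1), P, replace = TRUE)
    eff <- config$effect_size * sgn
    data.frame(
      protein_accession = sprintf("PROT%04d", seq_len(P)),
      gene_symbol = sprintf("GENE%04d", seq_len(P)),
      class = cls,
      conserved = cls == "conserved",
      ms_beta_control = ifelse(cls %in% c("conserved", "ms_only"), eff, 0),
      ms_beta_offspring = ifelse(cls %in% c("conserved", "ms_only"), eff, 0),
      soma_beta_control = ifelse(cls %in% c("conserved", "soma_only"), eff, 0),
      soma_beta_offspring = ifelse(cls %in% c("conserved", "soma_only"), eff, 0),
      stringsAsFactors = FALSE
    )
  })
}

# Subject-level biological deviations shared across platforms: an
# n_proteins x (MS subjects + soma extras) matrix drawn from a dedicated
# sub-stream so the MS and aptamer generators see identical values for
# shared subjects.
subject_bio_matrix <- function(config) {
  n_sub <- sum(config$n_per_cohort) + config$soma_extra_subjects
  with_seed(sub_seed(config$seed, 3L), {
    matrix(stats::rnorm(config$n_proteins * n_sub, 0, config$sigma_subject),
           config$n_proteins, n_sub)
  })
}

#' Simulate a peptide-level TMT quantification table
#'
#' Long table of raw intensities for every identified (peptide, run, channel)
#' cell. Latent log2 intensity = protein baseline + peptide offset + cohort
#' effect + gender effect + shared subject deviation + run batch shift +
#' technical noise; raw intensity is 2^latent. A cell is missing (row absent)
#' with probability `plogis(a - b * latent)`, and a peptide can additionally
#' fail identification in a whole run. An 11th reference channel per run
#' (pooled mixture) is emitted for format fidelity but carries no subject.
#'
#' @param manifest from [simulate_manifest()].
#' @param config a [sim_config()].
#' @param truth from [simulate_ground_truth()].
#' @return data.frame: peptide_id, protein_accession, gene_symbol, run_id,
#'   pool_id, replicate, channel, intensity.
#' @export
simulate_peptide_data <- function(manifest, config, truth) {
  P <- config$n_proteins
  bio <- subject_bio_matrix(config)
  with_seed(sub_seed(config$seed, 4L), {
    npep <- 1L + stats::rnbinom(P, size = config$peptides_per_protein[["dispersion"]],
                                mu = max(config$peptides_per_protein[["mean"]] - 1, 0.01))
    prot_of_pep <- rep.int(seq_len(P), npep)
    n_pep <- length(prot_of_pep)
    pep_id <- sprintf("PEP%05d", seq_len(n_pep))
    b_prot <- stats::rnorm(P, config$protein_mean, config$protein_sd)
    o_pep <- stats::rnorm(n_pep, 0, config$peptide_sd)
    g_eff <- stats::rnorm(P, 0, config$gender_sd)

    runs <- data.table::CJ(pool_id = sprintf("P%d", seq_len(config$n_pools)),
                           replicate = seq_len(config$n_replicates))
    runs[, run_id := paste0(pool_id, "_R", replicate)]
    batch_shift <- stats::setNames(stats::rnorm(nrow(runs), 0, config$batch_sd),
                                   runs$run_id)

    man <- data.table::as.data.table(manifest)
    sub_idx <- stats::setNames(seq_len(nrow(man)), man$subject_id)
    # profile grid: every (run, sample channel) with its subject
    prof <- merge(runs, man[, .(pool_id, channel, subject_id, cohort, gender)],
                  by = "pool_id", allow.cartesian = TRUE)
    data.table::setorder(prof, run_id, channel)
    n_prof <- nrow(prof)
    if (n_prof == 0L) {
      return(data.frame(peptide_id = character(0), protein_accession = character(0),
                        gene_symbol = character(0), run_id = character(0),
                        pool_id = character(0), replicate = integer(0),
                        channel = integer(0), intensity = numeric(0)))
    }

    # per (peptide, profile) latent intensity, vectorized peptide-major
    pp <- data.table::data.table(
      pep = rep(seq_len(n_pep), each = n_prof),
      prof = rep(seq_len(n_prof), times = n_pep)
    )
    pr <- prot_of_pep[pp$pep]
    coh <- prof$cohort[pp$prof]
    eff <- ifelse(coh == "control", truth$ms_beta_control[pr],
                  ifelse(coh == "offspring", truth$ms_beta_offspring[pr], 0))
    latent <- b_prot[pr] + o_pep[pp$pep] + eff +
      ifelse(prof$gender[pp$prof] == "M", g_eff[pr], 0) +
      bio[cbind(pr, sub_idx[prof$subject_id[pp$prof]])] +
      batch_shift[prof$run_id[pp$prof]] +
      stats::rnorm(nrow(pp), 0, config$sigma_tech)

    a <- config$missingness_params[["intercept"]]
    b <- config$missingness_params[["slope"]]
    p_miss <- if (is.infinite(a) && a < 0) rep(0, nrow(pp)) else stats::plogis(a - b * latent)
    miss <- stats::runif(nrow(pp)) < p_miss
    # run-level identification failures
    run_of_prof <- match(prof$run_id, runs$run_id)
    drop_run <- matrix(stats::runif(n_pep * nrow(runs)) < config$run_dropout_prob,
                       n_pep, nrow(runs))
    miss <- miss | drop_run[cbind(pp$pep, run_of_prof[pp$prof])]

    keep <- !miss
    out <- data.table::data.table(
      peptide_id = pep_id[pp$pep[keep]],
      protein_accession = truth$protein_accession[pr[keep]],
      gene_symbol = truth$gene_symbol[pr[keep]],
      run_id = prof$run_id[pp$prof[keep]],
      pool_id = prof$pool_id[pp$prof[keep]],
      replicate = prof$replicate[pp$prof[keep]],
      channel = prof$channel[pp$prof[keep]],
      intensity = 2^latent[keep]
    )

    # reference (11th) channel: pooled mixture per run, never consumed downstream
    ref_latent <- b_prot[prot_of_pep] + o_pep +
      rep(batch_shift[runs$run_id], each = n_pep) +
      stats::rnorm(n_pep * nrow(runs), 0, config$sigma_tech)
    ref <- data.table::data.table(
      peptide_id = rep(pep_id, times = nrow(runs)),
      protein_accession = rep(truth$protein_accession[prot_of_pep], nrow(runs)),
      gene_symbol = rep(truth$gene_symbol[prot_of_pep], nrow(runs)),
      run_id = rep(runs$run_id, each = n_pep),
      pool_id = rep(runs$pool_id, each = n_pep),
      replicate = rep(runs$replicate, each = n_pep),
      channel = config$n_channels + 1L,
      intensity = 2^ref_latent
    )
    res <- data.table::rbindlist(list(out, ref))
    data.table::setorder(res, peptide_id, run_id, channel)
    data.table::setDF(res)
    res
  })
}

#' Simulate an aptamer-array (RFU) study
#'
#' RFU matrix over the MS subjects plus `soma_extra_subjects` additional
#' subjects (the larger published-study design containing the MS subset).
#' Conserved proteins carry the same-sign effects as on MS; a configurable
#' fraction of proteins get two aptamers; `n_soma_only` aptamers target
#' proteins absent from MS. Occasional gross outliers emulate assay
#' artifacts for the outlier-masking stage.
#'
#' @param manifest MS manifest (shared subjects).
#' @param config a [sim_config()].
#' @param truth from [simulate_ground_truth()].
#' @return list: `rfu` (aptamer x subject raw RFU matrix), `annot`
#'   (aptamer_id, protein_accession, gene_symbol), `samples` (subject_id,
#'   cohort, gender, year_of_collection).
#' @export
simulate_somascan <- function(manifest, config, truth) {
  P <- config$n_proteins
  bio <- subject_bio_matrix(config)
  with_seed(sub_seed(config$seed, 5L), {
    n_extra <- config$soma_extra_subjects
    extra_counts <- pmax(config$soma_cohort_totals - config$n_per_cohort, 0)
    if (n_extra != sum(extra_counts)) {
      # honour soma_extra_subjects; keep cohort proportions of the remainder
      extra_counts <- round(extra_counts / max(sum(extra_counts), 1) * n_extra)
      extra_counts[1] <- n_extra - sum(extra_counts[-1])
    }
    extras <- data.frame(
      subject_id = if (n_extra > 0) sprintf("X%03d", seq_len(n_extra)) else character(0),
      cohort = factor(rep(c("centenarian", "offspring", "control"), times = extra_counts),
                      levels = c("centenarian", "offspring", "control")),
      gender = factor(sample(c("F", "M"), n_extra, replace = TRUE), levels = c("F", "M")),
      year_of_collection = sample(seq(config$year_range[1], config$year_range[2]),
                                  n_extra, replace = TRUE),
      stringsAsFactors = FALSE
    )
    samples <- rbind(manifest[, c("subject_id", "cohort", "gender", "year_of_collection")],
                     extras)
    n_sub <- nrow(samples)

    n_multi <- round(config$frac_multi_aptamer * P)
    multi <- sample.int(P, n_multi)
    prot_of_apt <- c(seq_len(P), multi)
    annot <- data.frame(
      aptamer_id = sprintf("APT%04d_%d", prot_of_apt,
                           c(rep(1L, P), rep(2L, n_multi))),
      protein_accession = truth$protein_accession[prot_of_apt],
      gene_symbol = truth$gene_symbol[prot_of_apt],
      stringsAsFactors = FALSE
    )
    if (config$n_soma_only > 0) {
      annot <- rbind(annot, data.frame(
        aptamer_id = sprintf("APTS%04d_1", seq_len(config$n_soma_only)),
        protein_accession = sprintf("SPROT%04d", seq_len(config$n_soma_only)),
        gene_symbol = sprintf("SGENE%04d", seq_len(config$n_soma_only)),
        stringsAsFactors = FALSE
      ))
    }
    n_apt <- nrow(annot)
    is_ms_prot <- seq_len(n_apt) <= length(prot_of_apt)

    base <- stats::rnorm(n_apt, 8, 1)
    g_eff <- stats::rnorm(n_apt, 0, config$gender_sd)
    eff_con <- eff_off <- numeric(n_apt)
    eff_con[is_ms_prot] <- truth$soma_beta_control[prot_of_apt]
    eff_off[is_ms_prot] <- truth$soma_beta_offspring[prot_of_apt]

    coh <- samples$cohort
    eff_mat <- outer(eff_con, as.numeric(coh == "control")) +
      outer(eff_off, as.numeric(coh == "offspring"))
    bio_mat <- matrix(0, n_apt, n_sub)
    bio_mat[is_ms_prot, ] <- bio[prot_of_apt, , drop = FALSE][, seq_len(n_sub), drop = FALSE]
    if (config$n_soma_only > 0) {
      bio_mat[!is_ms_prot, ] <- matrix(
        stats::rnorm(config$n_soma_only * n_sub, 0, config$sigma_subject),
        config$n_soma_only, n_sub)
    }
    log2rfu <- base + eff_mat + bio_mat +
      outer(g_eff, as.numeric(samples$gender == "M")) +
      matrix(stats::rnorm(n_apt * n_sub, 0, config$soma_sigma), n_apt, n_sub)
    out_mask <- matrix(stats::runif(n_apt * n_sub) < config$soma_outlier_prob,
                       n_apt, n_sub)
    log2rfu[out_mask] <- log2rfu[out_mask] +
      sample(c(-1, 1), sum(out_mask), replace = TRUE) *
      (5 + abs(stats::rnorm(sum(out_mask))))
    rfu <- 2^log2rfu
    dimnames(rfu) <- list(annot$aptamer_id, samples$subject_id)
    list(rfu = rfu, annot = annot, samples = samples)
  })
}

#' Simulate a whole-blood RNA-seq study with family structure
#'
#' Negative-binomial counts with library-size variation, per-gene age slopes
#' for a configurable fraction of genes, standard covariates (gender, site,
#' batch, intergenic read percentage, 4 genetic PCs), and a block-diagonal
#' kinship matrix (families with 0.5 / 0.25 off-diagonal relatedness) driving
#' a polygenic random effect.
#'
#' @param config a [sim_config()].
#' @return list: `counts` (gene x subject integer matrix), `covariates`
#'   (data.frame incl. age), `kinship` (subject x subject matrix), `truth`
#'   (per-gene true log2/year age slope).
#' @export
simulate_transcriptome <- function(config) {
  with_seed(sub_seed(config$seed, 6L), {
    n <- config$n_subjects_rna
    G <- config$n_genes
    # families
    sizes <- integer(0)
    while (sum(sizes) < n) {
      sizes <- c(sizes, sample(seq(config$family_size_range[1],
                                   config$family_size_range[2]), 1L))
    }
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
    sizes <- sizes[sizes > 0]
    fam <- rep(seq_along(sizes), sizes)
    K <- matrix(0, n, n)
    pos <- 0L
    for (m in sizes) {
      j <- pos + seq_len(m)
      # two nuclear sub-units per family: 0.5 within, 0.25 across
      sub <- (seq_len(m) > ceiling(m / 2)) + 1L
      blk <- 0.25 + 0.25 * outer(sub, sub, "==")
      diag(blk) <- 1
      K[j, j] <- blk
      pos <- pos + m
    }
    subjects <- sprintf("R%04d", seq_len(n))
    dimnames(K) <- list(subjects, subjects)

    covars <- data.frame(
      subject_id = subjects,
      age = round(stats::runif(n, 25, 100), 1),
      gender = factor(sample(c("F", "M"), n, TRUE), levels = c("F", "M")),
      site = factor(sample(paste0("site", 1:3), n, TRUE)),
      batch = factor(sample(paste0("b", 1:5), n, TRUE)),
      intergenic_pct = pmax(stats::rnorm(n, 3, 1), 0.1),
      PC1 = stats::rnorm(n), PC2 = stats::rnorm(n),
      PC3 = stats::rnorm(n), PC4 = stats::rnorm(n),
      stringsAsFactors = FALSE
    )

    n_assoc <- round(config$frac_age_genes * G)
    slope <- numeric(G)
    if (n_assoc > 0) {
      slope[sample.int(G, n_assoc)] <- stats::rnorm(n_assoc, 0, config$age_slope_sd)
    }
    base <- stats::rnorm(G, 5, 2)
    ek <- eigen(K, symmetric = TRUE)
    L <- ek$vectors %*% diag(sqrt(pmax(ek$values, 0)))
    gmat <- config$sigma_g * (matrix(stats::rnorm(G * n), G, n) %*% t(L))
    covar_eff <- outer(stats::rnorm(G, 0, 0.1), as.numeric(covars$gender == "M")) +
      outer(stats::rnorm(G, 0, 0.05), covars$PC1) +
      outer(stats::rnorm(G, 0, 0.05), scale(covars$intergenic_pct)[, 1])
    latent <- base + outer(slope, covars$age - 65) + covar_eff + gmat +
      matrix(stats::rnorm(G * n, 0, config$sigma_e), G, n)
    libfac <- exp(stats::rnorm(n, 0, 0.3))
    mu <- t(t(2^latent) * libfac)
    counts <- matrix(stats::rnbinom(G * n, mu = mu, size = 1 / config$rna_dispersion),
                     G, n)
    dimnames(counts) <- list(sprintf("G%05d", seq_len(G)), subjects)
    list(counts = counts, covariates = covars, kinship = K,
         truth = data.frame(gene = rownames(counts), age_slope = slope,
                            stringsAsFactors = FALSE))
  })
}
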