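#' Pair shared features across platforms
#'
#' Intersects the MS protein results with the aptamer results through the
#' aptamer annotation. A protein targeted by k aptamers yields k pairs.
#' Features unique to one platform are returned separately: they enter the
#' pooled FDR with their own nominal p-values.
#'
#' @param ms MS differential table (feature_id = protein accession).
#' @param soma aptamer differential table (feature_id = aptamer_id).
#' @param annot aptamer annotation (aptamer_id, protein_accession).
#' @return list: `pairs` (one row per protein-aptamer pair, with both
#'   platforms' betas and p-values), `ms_only`, `soma_only`, `counts`.
#' @export
pair_shared_features <- function(ms, soma, annot) {
  known <- soma$feature_id %in% annot$aptamer_id
  if (any(!known)) {
    warning("dropping ", sum(!known), " aptamer(s) without annotation")
    soma <- soma[known, , drop = FALSE]
  }
  acc <- annot$protein_accession[match(soma$feature_id, annot$aptamer_id)]
  shared <- acc %in% ms$feature_id
  pairs <- data.frame(
    protein_accession = acc[shared],
    aptamer_id = soma$feature_id[shared],
    stringsAsFactors = FALSE
  )
  if ("gene_symbol" %in% names(annot)) {
    pairs$gene_symbol <- annot$gene_symbol[match(pairs$aptamer_id, annot$aptamer_id)]
  }
  mi <- match(pairs$protein_accession, ms$feature_id)
  si <- match(pairs$aptamer_id, soma$feature_id)
  pairs$ms_beta_control <- ms$beta_control[mi]
  pairs$ms_beta_offspring <- ms$beta_offspring[mi]
  pairs$ms_p <- ms$global_p[mi]
  pairs$soma_beta_control <- soma$beta_control[si]
  pairs$soma_beta_offspring <- soma$beta_offspring[si]
  pairs$soma_p <- soma$global_p[si]

  ms_only <- ms[!ms$feature_id %in% pairs$protein_accession, , drop = FALSE]
  soma_only <- soma[!shared, , drop = FALSE]
  counts <- c(pairs = nrow(pairs),
              shared_proteins = length(unique(pairs$protein_accession)),
              ms_only = nrow(ms_only), soma_only = nrow(soma_only),
              pooled_total = nrow(pairs) + nrow(ms_only) + nrow(soma_only))
  list(pairs = pairs, ms_only = ms_only, soma_only = soma_only, counts = counts)
}

#' Effective number of studies from signed normal scores
#'
#' Transforms each study's per-pair p-value into a signed z score
#' z = sign(beta_control) * qnorm(1 - p/2), computes the Pearson correlation
#' r of the two score vectors, and maps it to an effective number of studies
#' by the two-study eigenvalue (Nyholt-style) form: the eigenvalues of the
#' 2x2 correlation matrix are 1 +/- r, giving
#' k_eff = 1 + (1 - Var(lambda)/2) = 2 - r^2. Independent studies give
#' k_eff ~ 2, duplicated studies k_eff = 1. Pairs with missing p-values or a
#' zero coefficient (sign 0) are excluded from the estimate.
#'
#' @param p_ms,p_soma per-pair p-values.
#' @param sign_ms,sign_soma signs of the control-vs-centenarian coefficients.
#' @param min_pairs minimum usable pairs.
#' @return list: `r`, `lambda` (eigenvalues), `k_eff`, `n_used`.
#' @export
estimate_effective_studies <- function(p_ms, p_soma, sign_ms, sign_soma,
                                       min_pairs = 30L) {
  s1 <- sign(sign_ms); s2 <- sign(sign_soma)
  ok <- !is.na(p_ms) & !is.na(p_soma) & s1 != 0 & s2 != 0 &
    !is.na(s1) & !is.na(s2)
  if (sum(ok) < min_pairs) {
    stop("only ", sum(ok), " usable pairs (need >= ", min_pairs,
         "); supply k_eff manually")
  }
  pm <- pmax(pmin(p_ms[ok], 1 - 1e-16), 1e-300)
  ps <- pmax(pmin(p_soma[ok], 1 - 1e-16), 1e-300)
  z1 <- s1[ok] * stats::qnorm(pm / 2, lower.tail = FALSE)
  z2 <- s2[ok] * stats::qnorm(ps / 2, lower.tail = FALSE)
  r <- stats::cor(z1, z2)
  list(r = r, lambda = c(1 + r, 1 - r), k_eff = 2 - r^2, n_used = sum(ok))
}

#' Adjusted maximum-p conserved-association p-value
#'
#' p_cons = max(p_ms, p_soma)^k_eff. Under two independent studies the
#' maximum of two uniform p-values has CDF t^2, so squaring restores
#' uniformity; k_eff < 2 calibrates the test when the studies share samples.
#' NA in either input propagates.
#'
#' @param p_ms,p_soma per-pair p-values in (0, 1\].
#' @param k_eff effective number of studies in \[1, 2\].
#' @return vector of conserved-association p-values.
#' @export
adjmaxp <- function(p_ms, p_soma, k_eff) {
  stopifnot(length(k_eff) == 1L, is.finite(k_eff), k_eff >= 1, k_eff <= 2)
  bad <- function(p) any(!is.na(p) & (p <= 0 | p > 1))
  if (bad(p_ms) || bad(p_soma)) stop("p-values must lie in (0, 1]")
  pmax(p_ms, p_soma)^k_eff
}

#' Pooled FDR over pairs and platform-unique features
#'
#' A single BH correction over the concatenation of the shared pairs'
#' conserved p-values and the platform-unique features' nominal p-values:
#' the unique features widen the correction to the full tested feature
#' space (e.g. 353 pairs + 132 MS-only + 4,050 aptamer-only = 4,535
#' adjusted features). The three id sets must be disjoint.
#'
#' @param pairs data.frame with `feature_id` and `p` (conserved p).
#' @param ms_only,soma_only data.frames with `feature_id` and `p` (nominal).
#' @return data.frame: feature_id, source (pair/ms_only/soma_only), p, q.
#' @export
pooled_fdr <- function(pairs, ms_only = NULL, soma_only = NULL) {
  grab <- function(d, tag) {
    if (is.null(d) || nrow(d) == 0L) return(NULL)
    data.frame(feature_id = d$feature_id, source = tag, p = d$p,
               stringsAsFactors = FALSE)
  }
  all <- rbind(grab(pairs, "pair"), grab(ms_only, "ms_only"),
               grab(soma_only, "soma_only"))
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(feature_id = character(0), source = character(0),
                      p = numeric(0), q = numeric(0)))
  }
  if (anyDuplicated(all$feature_id)) {
    stop("feature sets overlap: ",
         paste(unique(all$feature_id[duplicated(all$feature_id)]), collapse = ", "))
  }
  all$q <- bh_fdr(all$p)
  all
}

#' Classify cross-platform conservation and assign direction
#'
#' For pairs significant at the pooled-FDR threshold: `full` conservation if
#' the control-vs-centenarian and offspring-vs-centenarian coefficients each
#' agree in sign across platforms; `partial` if exactly one comparison
#' agrees (direction taken from the agreeing comparison); `discordant` if
#' neither does. Direction is `higher_in_offspring_controls` when the
#' governing signs are positive, `higher_in_centenarians` when negative,
#' `none` for discordant pairs. A zero coefficient counts as a sign
#' mismatch. Non-significant pairs are classified `ns` with direction
#' `none`.
#'
#' @param pairs pair table from [pair_shared_features()].
#' @param q pooled-FDR q-values aligned with `pairs`.
#' @param threshold FDR threshold (the reporting convention uses 0.01 and
#'   0.05 tiers).
#' @return `pairs` with columns q_pooled, conservation_class,
#'   assigned_direction appended.
#' @export
classify_conservation <- function(pairs, q, threshold = 0.05) {
  stopifnot(length(q) == nrow(pairs))
  strict_sign <- function(x) ifelse(is.na(x), 0, sign(x))
  s_mc <- strict_sign(pairs$ms_beta_control)
  s_mo <- strict_sign(pairs$ms_beta_offspring)
  s_sc <- strict_sign(pairs$soma_beta_control)
  s_so <- strict_sign(pairs$soma_beta_offspring)
  if (any(c(s_mc, s_mo, s_sc, s_so) == 0)) {
    message("classify_conservation: zero coefficient(s) treated as sign mismatch")
  }
  match_con <- s_mc != 0 & s_mc == s_sc
  match_off <- s_mo != 0 & s_mo == s_so
  n_match <- match_con + match_off

  cls <- rep("ns", nrow(pairs))
  dir <- rep("none", nrow(pairs))
  sig <- !is.na(q) & q <= threshold
  cls[sig & n_match == 2] <- "full"
  cls[sig & n_match == 1] <- "partial"
  cls[sig & n_match == 0] <- "discordant"

  gov <- ifelse(match_con & match_off,
                ifelse(s_mc == s_mo, s_mc, 0),   # full: common sign (0 if the
                ifelse(match_con, s_mc,          # two comparisons disagree)
                       ifelse(match_off, s_mo, 0)))
  dir[sig & gov > 0] <- "higher_in_offspring_controls"
  dir[sig & gov < 0] <- "higher_in_centenarians"
  dir[cls == "discordant"] <- "none"

  out <- pairs
  out$q_pooled <- q
  out$conservation_class <- cls
  out$assigned_direction <- dir
  out
}

#' Protein-level conserved signature
#'
#' Collapses pair-level conservation calls to one row per protein (the pair
#' with the smallest pooled q, the convention used for protein-level report
#' tables), keeping only significant non-discordant pairs.
#'
#' @param classified output of [classify_conservation()].
#' @return protein-level data.frame.
#' @export
conserved_signature <- function(classified) {
  keep <- classified[classified$conservation_class %in% c("full", "partial"), ,
                     drop = FALSE]
  if (nrow(keep) == 0L) return(keep)
  keep <- keep[order(keep$q_pooled), ]
  keep[!duplicated(keep$protein_accession), , drop = FALSE]
}

#' Simulate two null studies sharing subjects
#'
#' Calibration world for the conserved-association test: per feature, every
#' subject has a latent biological value (SD `bio_sd`) measured by each
#' platform with independent noise (SD `platform_sd`, default equal to the
#' biological SD, consistent with the moderate per-sample concordance of
#' MS vs aptamer assays); study B shares `shared_frac` of study A's
#' subjects. Each study reports a one-sample t-test p-value and effect sign
#' per feature. No feature carries real signal.
#'
#' @param n_features,n_subjects features and subjects per study.
#' @param shared_frac fraction of study A subjects reused by study B.
#' @param bio_sd,platform_sd biological and platform noise SD.
#' @param seed RNG seed.
#' @return list of two data.frames (`ms`, `soma`) with p and sign columns.
#' @export
simulate_paired_null_studies <- function(n_features = 2000L, n_subjects = 50L,
                                         shared_frac = 0.5, bio_sd = 1,
                                         platform_sd = 1, seed = 1L) {
  with_seed(seed, {
    n_sh <- round(shared_frac * n_subjects)
    n_tot <- 2L * n_subjects - n_sh
    bio <- matrix(stats::rnorm(n_features * n_tot, 0, bio_sd), n_features, n_tot)
    idx_a <- seq_len(n_subjects)
    idx_b <- c(seq_len(n_sh), n_subjects + seq_len(n_subjects - n_sh))
    one_study <- function(idx) {
      y <- bio[, idx, drop = FALSE] +
        matrix(stats::rnorm(n_features * length(idx), 0, platform_sd),
               n_features, length(idx))
      m <- rowMeans(y)
      s <- sqrt(apply(y, 1L, stats::var) / length(idx))
      t <- m / s
      data.frame(p = 2 * stats::pt(-abs(t), length(idx) - 1L), sign = sign(m))
    }
    list(ms = one_study(idx_a), soma = one_study(idx_b))
  })
}
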