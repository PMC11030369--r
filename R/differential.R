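# Shared design construction: cohort (centenarian reference), collection
# year (numeric) and gender, in that column order.
cohort_design <- function(cohort, year, gender) {
  d <- data.frame(
    cohort = factor(cohort, levels = c("centenarian", "offspring", "control")),
    year_of_collection = as.numeric(year),
    gender = factor(gender)
  )
  X <- stats::model.matrix(~ cohort + year_of_collection + gender, d)
  attr(X, "cohort_idx") <- grep("^cohort", colnames(X))
  X
}

#' MS differential testing by linear GEE
#'
#' Per protein: mean model log2 expression ~ cohort + year + gender with
#' centenarians as reference; clusters are subjects (their triplicate
#' profiles) with exchangeable working correlation; the global cohort test
#' is the 2-df robust Wald chi-square on the two cohort coefficients (a
#' working-model likelihood-ratio variant is available). A positive beta
#' means higher expression in the named younger cohort than in centenarians.
#' BH FDR is computed across converged proteins; non-converged features are
#' carried with NA p and excluded from the ranking.
#'
#' @param values protein x profile log2 matrix (preprocessed).
#' @param profiles profile annotation with subject_id per column of `values`.
#' @param manifest sample manifest (cohort/gender/year per subject).
#' @param test "wald" (default) or "working-lrt".
#' @return data.frame: feature_id, beta_control, beta_offspring, se_control,
#'   se_offspring, global_p, fdr, converged, platform.
#' @export
fit_ms_differential <- function(values, profiles, manifest,
                                test = c("wald", "working-lrt")) {
  test <- match.arg(test)
  stopifnot(ncol(values) == nrow(profiles))
  ann <- manifest[match(profiles$subject_id, manifest$subject_id), ]
  if (length(unique(ann$cohort)) < 3L) stop("all three cohorts must be present")
  X <- cohort_design(ann$cohort, ann$year_of_collection, ann$gender)
  cidx <- attr(X, "cohort_idx")
  id <- profiles$subject_id

  rows <- lapply(seq_len(nrow(values)), function(i) {
    y <- values[i, ]
    out <- tryCatch({
      fit <- gee_fit(X, y, id, family = "gaussian")
      gl <- if (test == "wald") gee_wald(fit, cidx) else gee_working_lrt(fit, cidx)
      data.frame(feature_id = rownames(values)[i],
                 beta_control = unname(fit$beta["cohortcontrol"]),
                 beta_offspring = unname(fit$beta["cohortoffspring"]),
                 se_control = sqrt(fit$vbeta["cohortcontrol", "cohortcontrol"]),
                 se_offspring = sqrt(fit$vbeta["cohortoffspring", "cohortoffspring"]),
                 global_p = gl$p, converged = fit$converged)
    }, error = function(e) {
      data.frame(feature_id = rownames(values)[i], beta_control = NA_real_,
                 beta_offspring = NA_real_, se_control = NA_real_,
                 se_offspring = NA_real_, global_p = NA_real_, converged = FALSE)
    })
    out
  })
  res <- do.call(rbind, rows)
  res$fdr <- bh_fdr(res$global_p)
  res$platform <- "ms"
  res
}

#' Aptamer differential testing by OLS with a global F-test
#'
#' Per aptamer: OLS of log2 RFU on cohort + year + gender over subjects with
#' unmasked values; the global cohort test is the F statistic on 2 and
#' n - 5 denominator degrees of freedom (45 with 50 complete subjects:
#' intercept, two cohort terms, year, gender). Aptamers with fewer than 10
#' usable observations are returned with NA. BH FDR across aptamers.
#'
#' @param values aptamer x subject log2 matrix (NA = masked).
#' @param samples per-subject annotation (subject_id, cohort, gender,
#'   year_of_collection) matching the columns of `values`.
#' @return data.frame like [fit_ms_differential()], plus `df_den`.
#' @export
fit_soma_differential <- function(values, samples) {
  stopifnot(ncol(values) == nrow(samples))
  X <- cohort_design(samples$cohort, samples$year_of_collection, samples$gender)
  cidx <- attr(X, "cohort_idx")
  p <- ncol(X)

  rows <- lapply(seq_len(nrow(values)), function(i) {
    y <- values[i, ]
    ok <- which(!is.na(y))
    if (length(ok) < 10L) {
      return(data.frame(feature_id = rownames(values)[i], beta_control = NA_real_,
                        beta_offspring = NA_real_, se_control = NA_real_,
                        se_offspring = NA_real_, global_p = NA_real_,
                        df_den = NA_real_))
    }
    Xi <- X[ok, , drop = FALSE]
    fit <- stats::lm.fit(Xi, y[ok])
    df_den <- length(ok) - p
    s2 <- sum(fit$residuals^2) / df_den
    XtXinv <- chol2inv(chol(crossprod(Xi)))
    b <- fit$coefficients[cidx]
    V <- s2 * XtXinv[cidx, cidx]
    Fstat <- drop(t(b) %*% solve(V, b)) / length(cidx)
    data.frame(feature_id = rownames(values)[i],
               beta_control = unname(fit$coefficients["cohortcontrol"]),
               beta_offspring = unname(fit$coefficients["cohortoffspring"]),
               se_control = sqrt(s2 * XtXinv[cidx[2], cidx[2]]),
               se_offspring = sqrt(s2 * XtXinv[cidx[1], cidx[1]]),
               global_p = stats::pf(Fstat, length(cidx), df_den, lower.tail = FALSE),
               df_den = df_den)
  })
  res <- do.call(rbind, rows)
  res$fdr <- bh_fdr(res$global_p)
  res$platform <- "soma"
  res
}
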