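#' Median-of-ratios count normalization
#'
#' DESeq-style size factors: per sample, the median over reference genes of
#' the ratio of its count to that gene's geometric mean across samples.
#' Reference genes are those with nonzero counts in every sample. Returns
#' the log2 normalized matrix log2(count / s_j + 1) and the size factors.
#'
#' @param counts gene x sample nonnegative integer matrix.
#' @return list: `log2` matrix, `size_factors`.
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    stop("no gene with nonzero counts in every sample; ",
         "consider a pseudo-reference variant")
  }
  loggeo <- rowMeans(log(counts[ref, , drop = FALSE]))
  sf <- apply(counts[ref, , drop = FALSE], 2L, function(cnts) {
    exp(stats::median(log(cnts) - loggeo))
  })
  list(log2 = log2(sweep(counts, 2L, sf, "/") + 1), size_factors = sf)
}

#' Remove lowly expressed genes
#'
#' Keeps a gene iff it reaches at least `cpm` counts per million in at least
#' `frac` of samples (genes with >= 10 CPM in fewer than 3% of samples are
#' removed under the defaults).
#'
#' @param counts gene x sample count matrix.
#' @param cpm CPM threshold.
#' @param frac minimum fraction of samples at or above the threshold.
#' @return filtered count matrix.
#' @export
filter_low_expressed <- function(counts, cpm = 10, frac = 0.03) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample(s) with zero library size")
  cpm_mat <- sweep(counts, 2L, lib, "/") * 1e6
  keep <- rowSums(cpm_mat >= cpm) >= frac * ncol(counts)
  counts[keep, , drop = FALSE]
}

#' Per-gene kinship-aware linear mixed model of age
#'
#' Fits, for every gene, y = X beta + g + e with cov(g) = sigma_g^2 K and
#' cov(e) = sigma_e^2 I, where K is the genetic relatedness (kinship)
#' matrix. The one-time eigendecomposition K = U L U' rotates y and X so
#' the covariance is diagonal, and the variance ratio
#' delta = sigma_g^2 / sigma_e^2 is profiled per gene by 1-D REML
#' optimization. Age is the predictor of interest; its Wald t-test p-value
#' (df = n - p) and BH FDR across genes are reported. With K = I the
#' estimates reduce to OLS.
#'
#' @param expr gene x subject matrix (log2 normalized expression).
#' @param covariates data.frame with an `age` column plus adjustment
#'   covariates; factors are expanded via `model.matrix`. Order must match
#'   the columns of `expr`.
#' @param kinship subject x subject PSD relatedness matrix.
#' @param covariate_cols columns of `covariates` to adjust for (default:
#'   everything except subject_id and age).
#' @return data.frame: gene, beta_age, se, p, q, var_ratio, at_bound.
#' @export
fit_lmm_age <- function(expr, covariates, kinship,
                        covariate_cols = setdiff(names(covariates),
                                                 c("subject_id", "age"))) {
  expr <- as.matrix(expr)
  n <- ncol(expr)
  stopifnot(nrow(covariates) == n, all(dim(kinship) == n))
  K <- as.matrix(kinship)
  if (max(abs(K - t(K))) > 1e-8) stop("kinship matrix must be symmetric")
  ek <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(ek$values) < -1e-6) stop("kinship matrix must be PSD")
  lam <- pmax(ek$values, 0)
  U <- ek$vectors

  fml <- stats::as.formula(paste("~ age +", paste(covariate_cols, collapse = " + ")))
  X <- stats::model.matrix(fml, covariates)
  aidx <- match("age", colnames(X))
  p <- ncol(X)
  Xr <- crossprod(U, X)
  Er <- expr %*% U               # each row: rotated y'
  log_bounds <- c(-12, 12)

  reml_fit <- function(yr) {
    nll <- function(ld) {
      d <- exp(ld) * lam + 1
      w <- 1 / d
      XtWX <- crossprod(Xr * w, Xr)
      b <- solve(XtWX, crossprod(Xr * w, yr))
      r <- yr - drop(Xr %*% b)
      rss <- sum(w * r^2)
      0.5 * ((n - p) * log(rss) + sum(log(d)) + determinant(XtWX)$modulus[1])
    }
    opt <- stats::optimize(nll, log_bounds)
    ld <- opt$minimum
    d <- exp(ld) * lam + 1
    w <- 1 / d
    XtWX <- crossprod(Xr * w, Xr)
    XtWXinv <- solve(XtWX)
    b <- drop(XtWXinv %*% crossprod(Xr * w, yr))
    r <- yr - drop(Xr %*% b)
    s2 <- sum(w * r^2) / (n - p)
    se <- sqrt(s2 * XtWXinv[aidx, aidx])
    tstat <- b[aidx] / se
    list(beta = b[aidx], se = se,
         p = 2 * stats::pt(-abs(tstat), n - p),
         ratio = exp(ld),
         at_bound = min(abs(ld - log_bounds)) < 1e-3)
  }

  rows <- lapply(seq_len(nrow(expr)), function(i) {
    f <- reml_fit(Er[i, ])
    data.frame(gene = rownames(expr)[i], beta_age = f$beta, se = f$se,
               p = f$p, var_ratio = f$ratio, at_bound = f$at_bound)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_fdr(res$p)
  res
}

#' One-sided over-representation test
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the upper-tail Fisher test of
#' whether a signature of size n overlaps a category of size K (in a
#' universe of N) by at least the observed k.
#'
#' @param n signature size.
#' @param k observed overlap.
#' @param K category size.
#' @param N universe size.
#' @return data.frame: n, k, K, N, p_one_sided.
#' @export
overrepresentation_test <- function(n, k, K, N) {
  data.frame(n = n, k = k, K = K, N = N,
             p_one_sided = hyper_upper_tail(k, K, n, N))
}

#' Correlation of proteomic and transcriptomic effect sizes
#'
#' For each proteomic contrast (control - centenarian and offspring -
#' centenarian), negates the proteomic beta so a positive value means higher
#' at older age (matching the sign of a transcriptomic age slope), pairs
#' features through the gene mapping, and reports the correlation and its
#' two-sided p-value.
#'
#' @param protein_betas data.frame: gene_symbol, beta_control,
#'   beta_offspring.
#' @param gene_betas data.frame: gene (symbol), beta_age.
#' @param method "pearson" (default) or "spearman".
#' @return data.frame, one row per contrast: contrast, n_pairs, r, p.
#' @export
effect_correlation <- function(protein_betas, gene_betas,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  idx <- match(protein_betas$gene_symbol, gene_betas$gene)
  ok <- !is.na(idx)
  out <- lapply(c(control = "beta_control", offspring = "beta_offspring"),
                function(col) {
    x <- -protein_betas[[col]][ok]     # reverse: positive = higher at older age
    y <- gene_betas$beta_age[idx[ok]]
    use <- !is.na(x) & !is.na(y)
    if (sum(use) < 5L) {
      return(data.frame(n_pairs = sum(use), r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(x[use], y[use], method = method, exact = FALSE)
    data.frame(n_pairs = sum(use), r = unname(ct$estimate), p = ct$p.value)
  })
  res <- do.call(rbind, out)
  res <- cbind(contrast = c("control_vs_centenarian", "offspring_vs_centenarian"),
               res)
  rownames(res) <- NULL
  res
}
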