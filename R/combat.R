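#' Parametric empirical-Bayes batch correction
#'
#' Location/scale batch adjustment of an expression matrix in the ComBat
#' style: per-feature batch means and variances are estimated after removing
#' covariate effects, shrunk toward common batch-level priors (normal prior
#' on locations, inverse-gamma on scales, both fit by method of moments), and
#' the data are adjusted to the pooled location/scale. Biological covariates
#' supplied through `mod` are protected: they are part of the standardization
#' design, so their effects are put back untouched.
#'
#' @param mat feature x sample matrix (log2 scale, no missing values).
#' @param batch factor (or coercible) of length `ncol(mat)`.
#' @param mod optional covariate design matrix (no intercept column) whose
#'   effects must be preserved, e.g. `model.matrix(~ cohort + gender + year)[, -1]`.
#' @param eb use empirical-Bayes shrinkage (TRUE) or per-feature estimates.
#' @return adjusted matrix, same dimensions as `mat`.
#' @export
combat_adjust <- function(mat, batch, mod = NULL, eb = TRUE) {
  mat <- as.matrix(mat)
  batch <- droplevels(factor(batch))
  nb <- nlevels(batch)
  if (nb < 2L) stop("batch correction requires at least 2 batches")
  sizes <- table(batch)
  if (any(sizes < 2L)) stop("every batch needs at least 2 samples")
  n <- ncol(mat)
  stopifnot(length(batch) == n)

  bdes <- stats::model.matrix(~ -1 + batch)
  if (!is.null(mod)) {
    mod <- as.matrix(mod)
    if (any(apply(mod, 2L, function(x) all(x == x[1L])))) {
      stop("constant column in covariate design; drop the intercept")
    }
  }
  design <- cbind(bdes, mod)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[seq(qrd$rank + 1L, ncol(design))]]
    stop("batch is confounded with covariate(s): ", paste(bad, collapse = ", "))
  }

  B <- solve(crossprod(design), crossprod(design, t(mat)))   # (nb+q) x G
  w <- as.numeric(sizes) / n
  grand <- drop(w %*% B[seq_len(nb), , drop = FALSE])        # per-feature grand mean
  resid <- mat - t(design %*% B)
  var_pooled <- rowMeans(resid^2)
  if (any(var_pooled <= 0)) stop("zero pooled variance for some feature")

  stand_mean <- matrix(grand, nrow(mat), n)
  if (!is.null(mod)) {
    stand_mean <- stand_mean + t(design[, -seq_len(nb), drop = FALSE] %*%
                                   B[-seq_len(nb), , drop = FALSE])
  }
  s_data <- (mat - stand_mean) / sqrt(var_pooled)

  idx <- split(seq_len(n), batch)
  gamma_hat <- vapply(idx, function(j) rowMeans(s_data[, j, drop = FALSE]),
                      numeric(nrow(mat)))                    # G x nb
  delta_hat <- vapply(idx, function(j) apply(s_data[, j, drop = FALSE], 1L, stats::var),
                      numeric(nrow(mat)))
  delta_hat <- pmax(delta_hat, 1e-8)

  if (eb) {
    gamma_bar <- colMeans(gamma_hat)
    t2 <- apply(gamma_hat, 2L, stats::var)
    a_prior <- apply(delta_hat, 2L, function(d) {
      m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2
    })
    b_prior <- apply(delta_hat, 2L, function(d) {
      m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2
    })
    gamma_star <- gamma_hat
    delta_star <- delta_hat
    for (i in seq_len(nb)) {
      ni <- as.numeric(sizes[i])
      sdat <- s_data[, idx[[i]], drop = FALSE]
      g_new <- gamma_hat[, i]; d_new <- delta_hat[, i]
      for (it in seq_len(100L)) {
        g_old <- g_new; d_old <- d_new
        g_new <- (t2[i] * ni * gamma_hat[, i] + d_new * gamma_bar[i]) /
          (t2[i] * ni + d_new)
        ss <- rowSums((sdat - g_new)^2)
        d_new <- (0.5 * ss + b_prior[i]) / (ni / 2 + a_prior[i] - 1)
        if (max(abs(g_new - g_old)) < 1e-6 && max(abs(d_new - d_old)) < 1e-6) break
      }
      gamma_star[, i] <- g_new
      delta_star[, i] <- d_new
    }
  } else {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
  }

  out <- s_data
  for (i in seq_len(nb)) {
    j <- idx[[i]]
    out[, j] <- (s_data[, j, drop = FALSE] - gamma_star[, i]) /
      sqrt(delta_star[, i])
  }
  out * sqrt(var_pooled) + stand_mean
}
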