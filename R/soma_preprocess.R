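#' Preprocess an aptamer RFU matrix
#'
#' Log2-transforms raw RFU and masks per-aptamer outliers: values farther
#' than `nsd` standard deviations from the aptamer's 5% trimmed mean (5% per
#' tail) are set to missing. The spread estimate is the ordinary SD of the
#' aptamer's log2 values by default; `trimmed_sd = TRUE` uses the SD of the
#' trimmed set instead. Aptamers with fewer than 5 observed values are left
#' unmasked with a warning.
#'
#' @param rfu aptamer x subject matrix of positive raw RFU.
#' @param nsd masking threshold in SD units.
#' @param trim trimmed proportion per tail for the center.
#' @param trimmed_sd use the trimmed-set SD as spread.
#' @param log2_input set TRUE if `rfu` is already log2 scale.
#' @return log2 matrix with masked entries set to NA; attribute `n_masked`
#'   gives the per-aptamer masked counts.
#' @export
preprocess_soma <- function(rfu, nsd = 3, trim = 0.05, trimmed_sd = FALSE,
                            log2_input = FALSE) {
  x <- as.matrix(rfu)
  if (!log2_input) {
    if (any(x <= 0, na.rm = TRUE)) stop("raw RFU must be positive")
    x <- log2(x)
  }
  n_masked <- integer(nrow(x))
  few <- 0L
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    obs <- which(!is.na(v))
    if (length(obs) < 5L) { few <- few + 1L; next }
    m <- trimmed_mean(v[obs], trim = trim)
    s <- if (trimmed_sd) {
      vv <- sort(v[obs]); g <- floor(trim * length(vv))
      stats::sd(vv[(g + 1):(length(vv) - g)])
    } else stats::sd(v[obs])
    if (!is.finite(s) || s == 0) next
    out <- obs[abs(v[obs] - m) > nsd * s]
    if (length(out)) {
      x[i, out] <- NA_real_
      n_masked[i] <- length(out)
    }
  }
  if (few > 0) warning(few, " aptamer(s) with < 5 observed values left unmasked")
  attr(x, "n_masked") <- stats::setNames(n_masked, rownames(x))
  x
}

#' Apply an aptamer annotation remap/drop table
#'
#' Models annotation updating (identifier remapping, aptamer retirement) as
#' a user-supplied table instead of a web-service call: rows with a new
#' accession replace the old one; rows with `NA`/empty new accession drop
#' the aptamer.
#'
#' @param annot annotation data.frame (aptamer_id, protein_accession, ...).
#' @param remap data.frame with columns `old` and `new` accessions.
#' @return updated annotation.
#' @export
apply_aptamer_remap <- function(annot, remap) {
  stopifnot(all(c("old", "new") %in% names(remap)))
  idx <- match(annot$protein_accession, remap$old)
  hit <- !is.na(idx)
  newacc <- remap$new[idx[hit]]
  annot$protein_accession[hit] <- newacc
  drop <- is.na(annot$protein_accession) | annot$protein_accession == ""
  if (any(drop)) message("apply_aptamer_remap: dropped ", sum(drop), " aptamer(s)")
  annot[!drop, , drop = FALSE]
}
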