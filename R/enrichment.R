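#' Read a GMT gene-set file
#'
#' Standard GMT: one set per tab-separated line, fields are set name,
#' description, then members. Duplicated members within a set are counted
#' once.
#'
#' @param path file path.
#' @return named list of character vectors (class `gene_set_collection`);
#'   attribute `description` keeps the per-set description field.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(structure(list(), class = "gene_set_collection",
                     description = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("malformed GMT line ", short[1L], ": fewer than 3 fields")
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  structure(sets, class = "gene_set_collection",
            description = stats::setNames(vapply(fields, `[[`, "", 2L),
                                          names(sets)))
}

#' Hypergeometric over-representation of a signature in gene sets
#'
#' For every set in the collection: members are first intersected with the
#' universe (the total feature space assayed, e.g. the union of proteins
#' measured by both platforms), and the one-sided hypergeometric upper-tail
#' p-value of the signature/set overlap is computed, with BH adjustment
#' within the collection. Signature identifiers outside the universe are
#' dropped with a warning.
#'
#' @param signature character vector of feature identifiers.
#' @param collection a [read_gmt()] collection (or named list of vectors).
#' @param universe background identifiers.
#' @return data.frame: set, k (overlap), K (set size in universe),
#'   n (signature size), N (universe size), p, q, members (overlap,
#'   comma-separated).
#' @export
enrich <- function(signature, collection, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  sig <- unique(signature)
  out <- setdiff(sig, universe)
  if (length(out)) {
    warning("dropping ", length(out), " signature id(s) outside the universe")
    sig <- intersect(sig, universe)
  }
  N <- length(universe)
  n <- length(sig)
  rows <- lapply(names(collection), function(nm) {
    set_u <- intersect(unique(collection[[nm]]), universe)
    hits <- intersect(sig, set_u)
    data.frame(set = nm, k = length(hits), K = length(set_u), n = n, N = N,
               p = hyper_upper_tail(length(hits), length(set_u), n, N),
               members = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(set = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), members = character(0)))
  }
  res$q <- bh_fdr(res$p)
  res[order(res$p), c("set", "k", "K", "n", "N", "p", "q", "members")]
}
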