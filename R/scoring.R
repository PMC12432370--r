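#' Read / write an expression matrix as TSV
#'
#' The TSV dialect used throughout: first column `gene_id`, header row of
#' sample identifiers, tab-separated numeric values.
#'
#' @param path file path.
#' @param log_transformed logical; whether the stored values are already on a
#'   log2 scale (stored as a `log_transformed` attribute on the matrix).
#' @return A numeric genes x samples matrix with a `log_transformed` attribute.
#' @export
read_expression_tsv <- function(path, log_transformed = FALSE) {
  mat <- read_matrix_tsv(path)
  if (anyDuplicated(rownames(mat))) stop("duplicate gene ids in ", path)
  if (anyDuplicated(colnames(mat))) stop("duplicate sample ids in ", path)
  if (any(!is.finite(mat))) stop("non-finite expression values in ", path)
  if (!log_transformed && any(mat < 0)) {
    stop("negative values in a matrix declared linear (TPM-like): ", path)
  }
  attr(mat, "log_transformed") <- log_transformed
  mat
}

#' @rdname read_expression_tsv
#' @param expr numeric genes x samples matrix.
#' @export
write_expression_tsv <- function(expr, path) {
  write_matrix_tsv(expr, path)
}

#' Score signature activity per sample
#'
#' Computes one activity score per (gene set, sample).  Two unified methods:
#'
#' * `mean_z`: each gene is z-scored across samples (on log2(x+1) values if
#'   the input is linear); the set score is the mean z over member genes
#'   present in the matrix.  Zero-variance genes contribute z = 0.
#' * `rank_enrichment`: a single-sample rank-weighted enrichment score; genes
#'   are ranked by expression within the sample and the set's weighted
#'   Kolmogorov-Smirnov deviation (weights = centered-rank magnitude) is
#'   reported, normalized to \[-1, 1\].
#'
#' Member genes absent from the matrix are dropped with a warning; a set with
#' fewer than `min_genes` members present scores `NA` for every sample.
#'
#' @param expr genes x samples numeric matrix; linear TPM-like unless its
#'   `log_transformed` attribute (or the argument) says otherwise.
#' @param sets an [gene_sets()] collection.
#' @param method `"mean_z"` (default) or `"rank_enrichment"`.
#' @param log_transformed overrides the matrix attribute when not `NULL`.
#' @param min_genes minimum member genes present for a set to be scored.
#' @return signatures x samples numeric matrix of class `iges_scores` with a
#'   `standardized = FALSE` attribute.
#' @export
score_signatures <- function(expr, sets, method = c("mean_z", "rank_enrichment"),
                             log_transformed = NULL, min_genes = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(sets, "iges_genesets"), is.matrix(expr))
  if (length(sets) == 0L) stop("empty gene set collection")
  is_log <- log_transformed %||% isTRUE(attr(expr, "log_transformed"))
  x <- if (is_log) expr else log2(expr + 1)

  present <- lapply(sets, function(g) intersect(g, rownames(expr)))
  n_missing <- sum(lengths(sets) - lengths(present))
  if (n_missing > 0) {
    warning(sprintf("%d set member gene(s) absent from the matrix were dropped",
                    n_missing))
  }
  scorable <- lengths(present) >= min_genes
  if (!any(scorable)) stop("no gene set has >= ", min_genes,
                           " member genes present in the matrix")
  if (!all(scorable)) {
    warning("set(s) with too few genes present score NA: ",
            paste(names(sets)[!scorable], collapse = ", "))
  }

  scores <- matrix(NA_real_, length(sets), ncol(x),
                   dimnames = list(names(sets), colnames(x)))
  if (method == "mean_z") {
    if (ncol(x) < 2L) stop("mean_z scoring needs >= 2 samples")
    mu <- rowMeans(x)
    sdv <- apply(x, 1L, stats::sd)
    z <- (x - mu) / ifelse(sdv > 0, sdv, 1)
    z[sdv == 0, ] <- 0
    for (i in which(scorable)) {
      scores[i, ] <- colMeans(z[present[[i]], , drop = FALSE])
    }
  } else {
    n <- nrow(x)
    for (j in seq_len(ncol(x))) {
      r <- rank(x[, j], ties.method = "average")
      metric <- r - (n + 1) / 2            # centered rank, sign carries order
      ord <- order(metric, decreasing = TRUE)
      ms <- metric[ord]
      names(ms) <- rownames(x)[ord]
      for (i in which(scorable)) {
        if (length(present[[i]]) >= n) {
          stop("set '", names(sets)[i], "' covers the whole gene universe")
        }
        scores[i, j] <- es_observed(ms, present[[i]])
      }
    }
  }
  structure(scores, standardized = FALSE, class = c("iges_scores", "matrix",
                                                    "array"))
}

#' Standardize signature scores within cohorts
#'
#' Z-transforms each signature row within each cohort to mean 0 and standard
#' deviation 1.  A constant row within a cohort is set to all zeros with a
#' warning rather than NaN.
#'
#' @param scores signatures x samples matrix (e.g. from [score_signatures()]).
#' @param cohort_labels character/factor of length `ncol(scores)`; `NULL`
#'   treats all samples as one cohort.
#' @return The standardized matrix with attribute `standardized = TRUE`.
#' @export
standardize_scores <- function(scores, cohort_labels = NULL) {
  stopifnot(is.matrix(scores))
  if (is.null(cohort_labels)) cohort_labels <- rep("all", ncol(scores))
  stopifnot(length(cohort_labels) == ncol(scores))
  out <- scores
  n_const <- 0L
  for (co in unique(cohort_labels)) {
    j <- which(cohort_labels == co)
    if (length(j) < 2L) {
      out[, j] <- 0
      next
    }
    sub <- scores[, j, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 1L, stats::sd, na.rm = TRUE)
    const <- !is.na(sdv) & sdv == 0
    n_const <- n_const + sum(const)
    sdv[const | is.na(sdv)] <- 1
    out[, j] <- (sub - mu) / sdv
    out[const, j] <- 0
  }
  if (n_const > 0) {
    warning(n_const, " constant signature row(s) within a cohort set to zero")
  }
  attr(out, "standardized") <- TRUE
  class(out) <- c("iges_scores", "matrix", "array")
  out
}

#' @export
print.iges_scores <- function(x, ...) {
  cat(sprintf("Signature score matrix: %d signatures x %d samples (%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "standardized"))) "standardized" else "raw"))
  invisible(x)
}
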