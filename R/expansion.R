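#' Partial Spearman correlation adjusting for one confounder
#'
#' Rank-transforms the three vectors (average ties) and computes the
#' first-order partial correlation of x and y given z on the ranks:
#' \deqn{r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}}
#' with a two-sided p-value from the t distribution on n - 3 degrees of
#' freedom.  A constant confounder degrades to the plain Spearman correlation
#' (logged); a confounder perfectly correlated with x or y leaves the partial
#' correlation undefined and returns `NA` with a warning.
#'
#' @param x,y,z equal-length numeric vectors; `z` is the confounder (here
#'   tumor purity).
#' @return list with `estimate` (the PSCC) and `p.value`.
#' @export
partial_spearman <- function(x, y, z) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  if (n < 4L) stop("partial Spearman needs n >= 4")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(z) == 0) {
    message("constant confounder: falling back to plain Spearman")
    r <- stats::cor(rx, ry)
  } else {
    rz <- rank(z, ties.method = "average")
    rxy <- stats::cor(rx, ry)
    rxz <- stats::cor(rx, rz)
    ryz <- stats::cor(ry, rz)
    if (abs(rxz) >= 1 || abs(ryz) >= 1) {
      warning("confounder perfectly correlated with an input; PSCC undefined")
      return(list(estimate = NA_real_, p.value = NA_real_))
    }
    r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  }
  r <- max(-1, min(1, r))
  df <- n - 3
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tval), df)
  }
  list(estimate = r, p.value = p)
}

#' Detectability proportion of genes across cell lines
#'
#' The fraction of cell lines in which a gene has at least one read.
#'
#' @param cellline_counts non-negative genes x cell-lines count matrix.
#' @return named numeric vector of detectability proportions in \[0, 1\].
#' @export
detectability <- function(cellline_counts) {
  stopifnot(is.matrix(cellline_counts))
  if (ncol(cellline_counts) == 0L) stop("no cell lines in count matrix")
  if (any(cellline_counts < 0)) stop("counts must be non-negative")
  rowMeans(cellline_counts >= 1)
}

#' Expand a signature to a cancer-type-specific gene list
#'
#' For every gene in the tissue matrix, computes the tumor-purity-adjusted
#' partial Spearman correlation (PSCC) with the signature's per-sample score,
#' adjusts p-values by Benjamini-Hochberg across all genes tested for this
#' signature, and keeps genes passing the three strict filters
#' PSCC > `pscc_min`, FDR < `fdr_max`, detectability > `dp_min`
#' (defaults 0.4 / 0.05 / 0.8).  Survivors are ranked by PSCC descending
#' (ties broken by gene id) and truncated to `max_genes` (default 200).
#'
#' If nothing survives, the expansion falls back to the original member genes
#' with detectability above `dp_min`, with a loud warning, so downstream
#' models never silently lose a feature.
#'
#' @param signature_id name of the signature being expanded.
#' @param tissue genes x samples expression matrix of the tissue panel.
#' @param score numeric per-sample signature score vector (same samples).
#' @param purity numeric per-sample tumor-purity vector in \[0, 1\].
#' @param dp named detectability vector from [detectability()]; genes absent
#'   from it get dp = 0.
#' @param original_genes optional character vector backing the fallback.
#' @param cancer_type label carried into the result.
#' @param pscc_min,fdr_max,dp_min,max_genes filter thresholds.
#' @return Object of class `iges_expansion`: list with `signature_id`,
#'   `cancer_type`, `genes` (ranked), `table` (audit data.frame: gene, pscc,
#'   p, fdr, dp, selected), `thresholds`, `fallback`.
#' @export
expand_signature <- function(signature_id, tissue, score, purity, dp,
                             original_genes = NULL,
                             cancer_type = NA_character_,
                             pscc_min = 0.4, fdr_max = 0.05, dp_min = 0.8,
                             max_genes = 200L) {
  stopifnot(is.matrix(tissue), ncol(tissue) == length(score),
            length(purity) == length(score))
  if (any(purity < 0 | purity > 1)) stop("purity must lie in [0, 1]")
  genes <- rownames(tissue)
  est <- p <- numeric(length(genes))
  for (i in seq_along(genes)) {
    ps <- suppressMessages(partial_spearman(tissue[i, ], score, purity))
    est[i] <- ps$estimate
    p[i] <- ps$p.value
  }
  fdr <- stats::p.adjust(p, method = "BH")
  dpv <- ifelse(genes %in% names(dp), dp[genes], 0)
  selected <- !is.na(est) & est > pscc_min & fdr < fdr_max & dpv > dp_min
  audit <- data.frame(gene = genes, pscc = est, p = p, fdr = fdr, dp = dpv,
                      selected = selected, stringsAsFactors = FALSE,
                      row.names = NULL)
  audit <- audit[order(-audit$pscc, audit$gene), ]

  fallback <- FALSE
  if (any(selected)) {
    keep <- audit$gene[audit$selected]
    if (length(keep) > max_genes) keep <- keep[seq_len(max_genes)]
  } else {
    fallback <- TRUE
    keep <- intersect(original_genes %||% character(),
                      names(dp)[dp > dp_min])
    warning(sprintf(
      "no gene passed the expansion filters for '%s'; falling back to %d detectable original member gene(s)",
      signature_id, length(keep)))
  }
  structure(list(signature_id = signature_id, cancer_type = cancer_type,
                 genes = keep, table = audit,
                 thresholds = c(pscc_min = pscc_min, fdr_max = fdr_max,
                                dp_min = dp_min, max_genes = max_genes),
                 fallback = fallback),
            class = "iges_expansion")
}

#' @export
print.iges_expansion <- function(x, ...) {
  cat(sprintf("Expanded signature '%s' (%s): %d gene(s)%s\n",
              x$signature_id,
              if (is.na(x$cancer_type)) "unspecified cancer type" else x$cancer_type,
              length(x$genes),
              if (x$fallback) " [FALLBACK to original detectable members]" else ""))
  th <- x$thresholds
  cat(sprintf("Filters: PSCC > %g, FDR < %g, DP > %g, cap %d\n",
              th["pscc_min"], th["fdr_max"], th["dp_min"], th["max_genes"]))
  invisible(x)
}
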