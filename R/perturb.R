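#' Read / write perturbation profiles (long TSV)
#'
#' One row per (condition, role): columns `compound`, `cell_line`,
#' `cancer_type`, `dose_um`, `time_h`, `plate`, `role` (`treated` or
#' `control`), then one column per gene (log-scale expression).  Treated rows
#' are paired with the control row sharing (cell_line, plate); the pairing is
#' the plate-matched DMSO convention.
#'
#' @param path TSV path.
#' @return Object of class `iges_perturbations`: list with `conditions`
#'   (data.frame: condition_id, compound, cell_line, cancer_type, dose_um,
#'   time_h, plate), `treated` and `control` (genes x conditions matrices).
#' @export
read_perturbations_tsv <- function(path) {
  df <- read_tsv(path)
  meta_cols <- c("compound", "cell_line", "cancer_type", "dose_um", "time_h",
                 "plate", "role")
  if (!all(meta_cols %in% colnames(df))) {
    stop("perturbation TSV must have columns: ", paste(meta_cols, collapse = ", "))
  }
  genes <- setdiff(colnames(df), meta_cols)
  tr <- df[df$role == "treated", , drop = FALSE]
  ct <- df[df$role == "control", , drop = FALSE]
  key <- function(d) paste(d$cell_line, d$plate, sep = "|")
  ctl_idx <- match(key(tr), key(ct))
  if (anyNA(ctl_idx)) stop("treated condition without a plate-matched control")
  conditions <- data.frame(
    condition_id = paste(tr$compound, tr$cell_line, tr$dose_um, tr$time_h,
                         tr$plate, sep = "|"),
    compound = tr$compound, cell_line = tr$cell_line,
    cancer_type = tr$cancer_type, dose_um = tr$dose_um, time_h = tr$time_h,
    plate = tr$plate, stringsAsFactors = FALSE
  )
  treated <- t(as.matrix(tr[, genes, drop = FALSE]))
  control <- t(as.matrix(ct[ctl_idx, genes, drop = FALSE]))
  colnames(treated) <- colnames(control) <- conditions$condition_id
  structure(list(conditions = conditions, treated = treated, control = control),
            class = "iges_perturbations")
}

#' @rdname read_perturbations_tsv
#' @param perturb an `iges_perturbations` object.
#' @export
write_perturbations_tsv <- function(perturb, path) {
  cond <- perturb$conditions
  genes <- rownames(perturb$treated)
  rows <- list()
  ctl_seen <- character()
  for (i in seq_len(nrow(cond))) {
    meta <- cond[i, c("compound", "cell_line", "cancer_type", "dose_um",
                      "time_h", "plate")]
    rows[[length(rows) + 1L]] <- cbind(meta, role = "treated",
                                       as.data.frame(t(perturb$treated[, i])))
    ck <- paste(cond$cell_line[i], cond$plate[i], sep = "|")
    if (!ck %in% ctl_seen) {
      ctl_seen <- c(ctl_seen, ck)
      cmeta <- meta
      cmeta$compound <- "DMSO"
      cmeta$dose_um <- 0
      rows[[length(rows) + 1L]] <- cbind(cmeta, role = "control",
                                         as.data.frame(t(perturb$control[, i])))
    }
  }
  out <- do.call(rbind, rows)
  colnames(out)[-(1:7)] <- genes
  write_tsv(out, path)
}

#' @export
print.iges_perturbations <- function(x, ...) {
  cat(sprintf("Perturbation set: %d conditions, %d compounds, %d cell lines, %d genes\n",
              nrow(x$conditions), length(unique(x$conditions$compound)),
              length(unique(x$conditions$cell_line)), nrow(x$treated)))
  invisible(x)
}

#' Rank genes by treated-minus-control expression difference
#'
#' The ranking metric is `treated - control` on the (log-scale) expression
#' values; genes are ordered by decreasing metric with exact ties broken
#' lexicographically by gene id.
#'
#' @param treated,control named numeric vectors over the same gene universe.
#' @return data.frame (`gene`, `metric`) in ranking order.
#' @export
rank_genes <- function(treated, control) {
  if (!setequal(names(treated), names(control))) {
    stop("treated and control must share the same gene universe")
  }
  metric <- treated - control[names(treated)]
  ord <- order(-metric, names(treated))
  data.frame(gene = names(treated)[ord], metric = unname(metric[ord]),
             stringsAsFactors = FALSE)
}

#' Preranked GSEA of one gene set against one ranked list
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic (exponent 1 on the
#' absolute metric): the enrichment score ES is the signed maximum deviation.
#' The null distribution comes from `nperm` gene-label permutations (uniform
#' redraws of the member positions); NES divides ES by the mean |null ES| of
#' the matching sign, and the permutation p-value is
#' `(1 + #{same-sign null at least as extreme}) / (1 + #{same-sign null})`.
#'
#' @param ranked data.frame from [rank_genes()] (columns `gene`, `metric`) or
#'   a named metric vector already in ranking order.
#' @param set character vector of member gene ids.
#' @param nperm number of permutations (>= 100).
#' @param seed integer seed for the permutation draws.
#' @return list of class `iges_enrichment`: `es`, `nes`, `p_perm`, `size`,
#'   `nperm`.
#' @export
gsea_prerank <- function(ranked, set, nperm = 1000L, seed = 1L) {
  if (is.data.frame(ranked)) {
    metric <- ranked$metric
    names(metric) <- ranked$gene
  } else {
    metric <- ranked
  }
  if (nperm < 100L) stop("nperm must be >= 100")
  inset <- names(metric) %in% set
  s <- sum(inset)
  if (s == 0L) stop("gene set does not intersect the ranked universe")
  if (s == length(metric)) stop("degenerate set: covers the whole universe")
  es <- es_observed(metric, set)
  null_es <- with_seed(seed, es_null(metric, s, nperm))
  np <- nes_and_p(es, null_es)
  structure(list(es = es, nes = np$nes, p_perm = np$p, size = s,
                 nperm = nperm),
            class = "iges_enrichment")
}

#' @export
print.iges_enrichment <- function(x, ...) {
  cat(sprintf("GSEA: ES = %.3f, NES = %.3f, p_perm = %.4g (set size %d, %d permutations)\n",
              x$es, x$nes, x$p_perm, x$size, x$nperm))
  invisible(x)
}

#' Enrichment of every signature in every perturbation condition
#'
#' For each condition: genes are ranked by treated-minus-control difference
#' and each signature is scored by preranked GSEA.  The permutation null is
#' shared across signatures of equal size within a condition (gene-label
#' permutation depends only on the metric and the set size).  FDR is
#' Benjamini-Hochberg across signatures within each condition.
#'
#' @param perturb an `iges_perturbations` object.
#' @param sets an [gene_sets()] collection.
#' @param nperm permutations per (condition, set size).
#' @param seed master seed; per-condition seeds are derived deterministically.
#' @return data.frame: condition_id, compound, cell_line, cancer_type,
#'   dose_um, time_h, signature, size, es, nes, p_perm, fdr.
#' @export
score_conditions <- function(perturb, sets, nperm = 1000L, seed = 1L) {
  stopifnot(inherits(perturb, "iges_perturbations"),
            inherits(sets, "iges_genesets"))
  cond <- perturb$conditions
  genes <- rownames(perturb$treated)
  members <- lapply(sets, intersect, y = genes)
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warning("signature(s) with no genes in the perturbation universe skipped: ",
            paste(names(sets)[empty], collapse = ", "))
    members <- members[!empty]
  }
  if (length(members) == 0L) stop("no scorable signature")

  out <- vector("list", nrow(cond))
  for (i in seq_len(nrow(cond))) {
    ranked <- rank_genes(perturb$treated[, i], perturb$control[, i])
    metric <- ranked$metric
    names(metric) <- ranked$gene
    sizes <- unique(lengths(members))
    nulls <- lapply(sizes, function(s) {
      with_seed(seed + 7L * i + s, es_null(metric, s, nperm))
    })
    names(nulls) <- as.character(sizes)
    es <- vapply(members, function(g) es_observed(metric, g), numeric(1))
    res <- t(vapply(seq_along(members), function(k) {
      np <- nes_and_p(es[k], nulls[[as.character(length(members[[k]]))]])
      c(np$nes, np$p)
    }, numeric(2)))
    out[[i]] <- data.frame(
      condition_id = cond$condition_id[i], compound = cond$compound[i],
      cell_line = cond$cell_line[i], cancer_type = cond$cancer_type[i],
      dose_um = cond$dose_um[i], time_h = cond$time_h[i],
      signature = names(members), size = lengths(members),
      es = unname(es), nes = res[, 1], p_perm = res[, 2],
      fdr = stats::p.adjust(res[, 2], method = "BH"),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  do.call(rbind, out)
}

#' Cauchy combination (ACAT) of p-values
#'
#' \deqn{T = \sum_i w_i \tan((0.5 - p_i)\pi) / \sum_i w_i;\quad
#'       p_{comb} = 0.5 - \arctan(T)/\pi.}
#' P-values of exactly 0 or 1 are clipped to \[1e-15, 1 - 1e-15\] with a
#' warning.  With all inputs equal to p the combination returns p exactly
#' (Cauchy identity).
#'
#' @param pvals numeric vector of p-values in (0, 1).
#' @param weights non-negative weights, not all zero (default equal).
#' @return the combined p-value.
#' @export
acat_combine <- function(pvals, weights = NULL) {
  if (length(pvals) == 0L) stop("no p-values to combine")
  if (any(is.na(pvals))) stop("NA p-values")
  if (is.null(weights)) weights <- rep(1, length(pvals))
  stopifnot(length(weights) == length(pvals))
  if (any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative and not all zero")
  }
  if (any(pvals <= 0 | pvals >= 1)) {
    warning("p-value(s) at 0 or 1 clipped to [1e-15, 1 - 1e-15]")
    pvals <- pmin(pmax(pvals, 1e-15), 1 - 1e-15)
  }
  t_stat <- sum(weights * tan((0.5 - pvals) * pi)) / sum(weights)
  0.5 - atan(t_stat) / pi
}

#' Cell-line weight lookup with cancer-type fallback
#'
#' @param weights data.frame with columns `cell_line`, `cancer_type`, `W`
#'   (weights normalized so the maximum per cancer type is 1).
#' @param cell_line,cancer_type the condition's identifiers.
#' @return the weight; the cancer-type mean when the cell line is absent, and
#'   1.0 (with a warning) when the cancer type is absent too.
#' @export
cell_weight <- function(weights, cell_line, cancer_type) {
  hit <- weights$W[weights$cell_line == cell_line &
                     weights$cancer_type == cancer_type]
  if (length(hit) >= 1L) return(hit[1])
  ct <- weights$W[weights$cancer_type == cancer_type]
  if (length(ct) >= 1L) return(mean(ct))
  warning("no weight for cell line '", cell_line, "' or cancer type '",
          cancer_type, "'; using 1.0")
  1.0
}

# Pick the reference condition among rows of `df` (one cell line):
# exact (ref_dose, ref_time) if present, else the nearest condition in
# (log10 dose, log2 time) Euclidean distance, ties -> lower dose, then
# shorter time.
pick_reference <- function(df, ref_dose = 10, ref_time = 24) {
  exact <- which(df$dose_um == ref_dose & df$time_h == ref_time)
  if (length(exact) >= 1L) return(exact[1])
  d <- sqrt((log10(df$dose_um) - log10(ref_dose))^2 +
              (log2(df$time_h) - log2(ref_time))^2)
  ord <- order(d, df$dose_um, df$time_h)
  ord[1]
}

#' Perturb gene expression score (PGES) per (signature, cancer type, compound)
#'
#' Integrates per-condition NES values into one score per trio.  With a single
#' condition overall the score is exactly `W_cell * NES`.  Otherwise each cell
#' line contributes `W_cell * (NES_ref + f)`, where the reference condition is
#' (10 uM, 24 h) or the nearest available in (log10 dose, log2 time), and the
#' awarding term `f` is the mean of `NES_condition - NES_ref` over the cell
#' line's non-reference conditions (`basket_mode = "pooled"`), or the sum of
#' per-basket means with baskets defined by dose/time relative to the
#' reference (`basket_mode = "basket"`).  Contributions are averaged over the
#' reference conditions (one per cell line).  The trio's combined p-value is
#' the ACAT combination of the per-condition FDR-adjusted p-values.
#'
#' @param enrich data.frame from [score_conditions()].
#' @param weights cell-weight table (`cell_line`, `cancer_type`, `W`).
#' @param ref_dose,ref_time reference condition (10 uM, 24 h).
#' @param basket_mode `"pooled"` (default) or `"basket"`.
#' @return data.frame of class `iges_pges`: signature, cancer_type, compound,
#'   pges, p_combined, n_conditions, n_cell_lines.
#' @export
compute_pges <- function(enrich, weights, ref_dose = 10, ref_time = 24,
                         basket_mode = c("pooled", "basket")) {
  basket_mode <- match.arg(basket_mode)
  key <- interaction(enrich$signature, enrich$cancer_type, enrich$compound,
                     drop = TRUE, sep = "\r")
  out <- lapply(split(enrich, key), function(df) {
    pges_trio(df, weights, ref_dose, ref_time, basket_mode)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[order(res$cancer_type, res$compound, res$signature), ]
  class(res) <- c("iges_pges", "data.frame")
  res
}

pges_trio <- function(df, weights, ref_dose, ref_time, basket_mode) {
  if (nrow(df) == 0L) stop("no conditions for trio")
  contrib <- 0
  cells <- unique(df$cell_line)
  for (cl in cells) {
    sub <- df[df$cell_line == cl, , drop = FALSE]
    w <- cell_weight(weights, cl, sub$cancer_type[1])
    r <- pick_reference(sub, ref_dose, ref_time)
    nes_ref <- sub$nes[r]
    others <- sub[-r, , drop = FALSE]
    f <- if (nrow(others) == 0L) {
      0
    } else if (basket_mode == "pooled") {
      mean(others$nes - nes_ref)
    } else {
      b <- paste(sign(others$dose_um - sub$dose_um[r]),
                 sign(others$time_h - sub$time_h[r]))
      sum(vapply(split(others$nes - nes_ref, b), mean, numeric(1)))
    }
    contrib <- contrib + w * (nes_ref + f)
  }
  data.frame(signature = df$signature[1], cancer_type = df$cancer_type[1],
             compound = df$compound[1],
             pges = contrib / length(cells),
             p_combined = acat_combine(df$fdr),
             n_conditions = nrow(df), n_cell_lines = length(cells),
             stringsAsFactors = FALSE)
}

#' Boosting score of a compound for a cancer type
#'
#' `BS = sum over significant signatures of Coe_i * PGES_i`, where the
#' significant subset N holds trios whose ACAT-combined FDR-adjusted p-value
#' is below `fdr_threshold` (default 0.05) and Coe_i is the elastic-net
#' coefficient.  Significant signatures without a model coefficient are
#' skipped with a warning; an empty N gives BS = 0.
#'
#' @param pges an `iges_pges` table (one or many compounds / cancer types).
#' @param model an `iges_en` model supplying the coefficients.
#' @param fdr_threshold significance cut on the combined p-value.
#' @return data.frame of class `iges_bs`: compound, cancer_type, bs,
#'   n_significant.
#' @export
compute_boosting_score <- function(pges, model, fdr_threshold = 0.05) {
  stopifnot(inherits(model, "iges_en"))
  coefs <- model$coefficients
  unknown <- setdiff(unique(pges$signature[pges$p_combined < fdr_threshold]),
                     names(coefs))
  if (length(unknown)) {
    warning("significant signature(s) without a model coefficient skipped: ",
            paste(unknown, collapse = ", "))
  }
  key <- interaction(pges$compound, pges$cancer_type, drop = TRUE, sep = "\r")
  out <- lapply(split(pges, key), function(df) {
    sig <- df$p_combined < fdr_threshold & df$signature %in% names(coefs)
    data.frame(compound = df$compound[1], cancer_type = df$cancer_type[1],
               bs = if (any(sig)) sum(coefs[df$signature[sig]] * df$pges[sig]) else 0,
               n_significant = sum(sig), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("iges_bs", "data.frame")
  res
}

#' Rank compounds by boosting score within each cancer type
#'
#' Rank 1 is the highest BS; ties are broken by compound id.  The percentile
#' column is `rank / number of compounds` (rank 20 of 1768 gives ~0.0113,
#' i.e. top 1.2%).
#'
#' @param scores an `iges_bs` table.
#' @return the table with `rank` and `percentile` columns added, sorted by
#'   cancer type then rank.
#' @export
rank_compounds <- function(scores) {
  stopifnot(nrow(scores) >= 1L)
  out <- lapply(split(scores, scores$cancer_type), function(df) {
    ord <- order(-df$bs, df$compound)
    df <- df[ord, , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    df$percentile <- df$rank / nrow(df)
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("iges_bs", "data.frame")
  res
}

#' @export
print.iges_bs <- function(x, n = 10L, ...) {
  cat(sprintf("Boosting scores: %d compound x cancer-type pairs\n", nrow(x)))
  print(utils::head(as.data.frame(x), n))
  invisible(x)
}

#' Enrichment of known boosters among high-scoring compounds
#'
#' Effect size is the difference in mean boosting score between compounds
#' with and without supporting evidence; significance is a one-sided Wilcoxon
#' rank-sum test of known > other.  Evidence is called "enriched" when the
#' effect size exceeds 1 and p < 0.05.
#'
#' @param scores numeric vector of boosting scores.
#' @param known_labels logical vector; `TRUE` marks compounds with evidence.
#' @return list: `effect_size`, `p`, `enriched`, `n_known`, `n_other`.
#' @export
booster_enrichment_test <- function(scores, known_labels) {
  stopifnot(length(scores) == length(known_labels))
  known <- scores[known_labels]
  other <- scores[!known_labels]
  if (length(known) == 0L || length(other) == 0L) {
    stop("both compound groups must be non-empty")
  }
  effect <- mean(known) - mean(other)
  p <- stats::wilcox.test(known, other, alternative = "greater")$p.value
  list(effect_size = effect, p = p,
       enriched = effect > 1 && p < 0.05,
       n_known = length(known), n_other = length(other))
}

#' Direction consistency between two enrichment call sets
#'
#' Restricts to signatures regulated in source A (adjusted p below
#' `padj_cut`, default 0.1) and reports the proportion whose NES sign in
#' source B matches the sign in A.  Returns `NA` with a warning when A calls
#' nothing regulated.
#'
#' @param calls_a,calls_b data.frames with columns `signature`, `nes`,
#'   `padj` over the same signatures.
#' @param padj_cut regulation threshold on source A's adjusted p.
#' @return proportion in \[0, 1\], or `NA`.
#' @export
direction_consistency <- function(calls_a, calls_b, padj_cut = 0.1) {
  m <- match(calls_a$signature, calls_b$signature)
  if (anyNA(m)) stop("call sets must cover the same signatures")
  reg <- which(calls_a$padj < padj_cut)
  if (length(reg) == 0L) {
    warning("no signature regulated in source A; consistency undefined")
    return(NA_real_)
  }
  mean(sign(calls_a$nes[reg]) == sign(calls_b$nes[m[reg]]))
}
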