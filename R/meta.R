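#' Per-cohort logistic association between a signature and response
#'
#' Fits `response ~ score` by maximum-likelihood logistic regression
#' ([stats::glm()]) and returns the slope (log-odds of response per 1-SD
#' increase in the standardized signature score), its standard error and the
#' Wald p-value.  Under complete separation the slope is capped at |beta| = 10
#' and the fit is flagged `converged = FALSE` so that pooling can exclude it.
#'
#' @param scores_z numeric vector of standardized per-sample scores.
#' @param response binary 0/1 vector, 1 = responder.
#' @param cohort_id optional identifier carried into the result.
#' @return list of class `iges_cohort_effect`: `cohort_id`, `beta`, `se`, `p`,
#'   `n`, `converged`.
#' @export
fit_cohort_logistic <- function(scores_z, response, cohort_id = NA_character_) {
  stopifnot(length(scores_z) == length(response))
  keep <- is.finite(scores_z) & !is.na(response)
  scores_z <- scores_z[keep]
  response <- response[keep]
  n <- length(response)
  if (n < 4L) stop("need at least 4 samples for a cohort logistic fit")
  if (!all(response %in% c(0, 1))) stop("response must be binary 0/1")
  tab <- table(factor(response, levels = c(0, 1)))
  if (any(tab == 0L)) stop("degenerate response: a single class in cohort ",
                           cohort_id)
  if (any(tab < 2L)) stop("need >= 2 samples per response class")

  fit <- suppressWarnings(
    stats::glm(response ~ scores_z, family = stats::binomial())
  )
  sm <- summary(fit)$coefficients
  beta <- unname(sm["scores_z", "Estimate"])
  se <- unname(sm["scores_z", "Std. Error"])
  converged <- isTRUE(fit$converged) && abs(beta) < 10
  if (!converged) beta <- sign(beta) * min(abs(beta), 10)
  p <- 2 * stats::pnorm(-abs(beta / se))
  structure(list(cohort_id = cohort_id, beta = beta, se = se, p = p,
                 n = n, converged = converged),
            class = "iges_cohort_effect")
}

#' Pool cohort effects by DerSimonian-Laird random-effects meta-analysis
#'
#' Classic moment estimator: with fixed-effect weights \eqn{w_i = 1/se_i^2},
#' Cochran's \eqn{Q = \sum w_i (\beta_i - \beta_{FE})^2} and
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w_i - \sum w_i^2 / \sum w_i))};
#' random-effect weights \eqn{w_i^* = 1/(se_i^2 + \tau^2)} give the pooled
#' log-odds, its Wald standard error \eqn{1/\sqrt{\sum w_i^*}}, 95% CI and
#' two-sided p-value.  Odds-ratio fields are the exponentiated equivalents.
#' Non-converged cohort effects are excluded before pooling.
#'
#' @param effects list of `iges_cohort_effect` objects (or a list of lists
#'   with `beta`, `se`, `converged` fields).
#' @param signature_id optional identifier carried into the result.
#' @return list of class `iges_meta`: `beta_pooled`, `se_pooled`, `or_pooled`,
#'   `ci_low`, `ci_high` (OR scale), `p`, `tau2`, `q_stat`, `k`,
#'   `cohort_effects`.
#' @export
pool_random_effects <- function(effects, signature_id = NA_character_) {
  if (length(effects) == 0L) stop("no cohort effects to pool")
  conv <- vapply(effects, function(e) isTRUE(e$converged %||% TRUE), logical(1))
  used <- effects[conv]
  if (length(used) == 0L) stop("no converged cohort effects to pool")
  beta <- vapply(used, `[[`, numeric(1), "beta")
  se <- vapply(used, `[[`, numeric(1), "se")
  if (any(se <= 0)) stop("standard errors must be positive")
  k <- length(beta)

  w <- 1 / se^2
  beta_fe <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - beta_fe)^2)
  tau2 <- if (k > 1) max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  wr <- 1 / (se^2 + tau2)
  beta_pooled <- sum(wr * beta) / sum(wr)
  se_pooled <- 1 / sqrt(sum(wr))
  z <- beta_pooled / se_pooled
  p <- 2 * stats::pnorm(-abs(z))
  ci <- beta_pooled + c(-1, 1) * stats::qnorm(0.975) * se_pooled

  structure(list(signature_id = signature_id,
                 beta_pooled = beta_pooled, se_pooled = se_pooled,
                 or_pooled = exp(beta_pooled),
                 ci_low = exp(ci[1]), ci_high = exp(ci[2]),
                 p = p, tau2 = tau2, q_stat = q, k = k,
                 cohort_effects = effects),
            class = "iges_meta")
}

#' Classify a pooled signature as sensitivity- or resistance-associated
#'
#' `sIGeS` when the pooled p-value is below `alpha` and the pooled odds ratio
#' exceeds 1; `rIGeS` when p < alpha and OR is in (0, 1); otherwise `none`.
#' An OR of exactly 1 is `none` regardless of p (boundary case).
#'
#' @param meta an `iges_meta` result from [pool_random_effects()].
#' @param alpha significance threshold on the pooled p-value (default 0.05).
#' @return `"sIGeS"`, `"rIGeS"` or `"none"`.
#' @export
classify_iges <- function(meta, alpha = 0.05) {
  stopifnot(inherits(meta, "iges_meta"))
  if (is.na(meta$p) || meta$p >= alpha) return("none")
  if (meta$or_pooled > 1) return("sIGeS")
  if (meta$or_pooled < 1) return("rIGeS")
  "none"
}

#' Discover immunotherapy-related signatures across cohorts
#'
#' Full discovery pipeline: score every gene set in every cohort, standardize
#' scores within each cohort (Z-transformation), fit the per-cohort logistic
#' association, pool across cohorts by DerSimonian-Laird random-effects
#' meta-analysis, and label each signature `sIGeS` / `rIGeS` / `none`.
#' Cohorts where a set cannot be scored or the logistic fit is infeasible
#' (e.g. single-class response after NA removal) are skipped for that set.
#'
#' @param cohorts list of cohort objects, each a list with `expr` (genes x
#'   samples matrix), `response` (0/1 vector aligned to samples) and
#'   `cohort_id`.
#' @param sets an [gene_sets()] collection.
#' @param method scoring method passed to [score_signatures()].
#' @param alpha significance threshold for labelling.
#' @param min_cohorts minimum cohorts a set must be fit in to be pooled.
#' @return Object of class `iges_discovery`: list with `results` (data.frame
#'   sorted by pooled p: signature, or, ci_low, ci_high, p, p_bh, tau2,
#'   q_stat, k, label, beta_pooled, se_pooled) and `meta` (named list of
#'   `iges_meta` objects).
#' @export
run_discovery <- function(cohorts, sets, method = c("mean_z", "rank_enrichment"),
                          alpha = 0.05, min_cohorts = 1L) {
  method <- match.arg(method)
  stopifnot(length(cohorts) >= 1L, inherits(sets, "iges_genesets"))
  if (length(cohorts) == 1L) {
    message("single-cohort discovery: no between-cohort heterogeneity estimable")
  }

  per_cohort <- lapply(cohorts, function(co) {
    sc <- score_signatures(co$expr, sets, method = method)
    sz <- standardize_scores(sc)
    list(scores = sz, response = co$response, cohort_id = co$cohort_id)
  })

  metas <- vector("list", length(sets))
  names(metas) <- names(sets)
  for (s in names(sets)) {
    effects <- list()
    for (pc in per_cohort) {
      x <- pc$scores[s, ]
      if (all(!is.finite(x))) next                  # unscorable in this cohort
      eff <- tryCatch(
        fit_cohort_logistic(x, pc$response, cohort_id = pc$cohort_id),
        error = function(e) NULL
      )
      if (!is.null(eff)) effects[[length(effects) + 1L]] <- eff
    }
    if (length(effects) >= min_cohorts && length(effects) > 0L) {
      metas[[s]] <- pool_random_effects(effects, signature_id = s)
    }
  }
  metas <- metas[!vapply(metas, is.null, logical(1))]
  if (length(metas) == 0L) stop("no signature could be pooled in any cohort")

  res <- data.frame(
    signature = names(metas),
    or = vapply(metas, `[[`, numeric(1), "or_pooled"),
    ci_low = vapply(metas, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(metas, `[[`, numeric(1), "ci_high"),
    p = vapply(metas, `[[`, numeric(1), "p"),
    tau2 = vapply(metas, `[[`, numeric(1), "tau2"),
    q_stat = vapply(metas, `[[`, numeric(1), "q_stat"),
    k = vapply(metas, `[[`, integer(1), "k"),
    beta_pooled = vapply(metas, `[[`, numeric(1), "beta_pooled"),
    se_pooled = vapply(metas, `[[`, numeric(1), "se_pooled"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$label <- vapply(metas, classify_iges, "", alpha = alpha)
  res$p_bh <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$signature), ]
  rownames(res) <- NULL
  structure(list(results = res, meta = metas, alpha = alpha, method = method),
            class = "iges_discovery")
}

#' @export
print.iges_discovery <- function(x, n = 10L, ...) {
  r <- x$results
  cat(sprintf("IGeS discovery: %d signatures pooled, %d sIGeS / %d rIGeS at alpha = %g\n",
              nrow(r), sum(r$label == "sIGeS"), sum(r$label == "rIGeS"),
              x$alpha))
  print(utils::head(r[, c("signature", "or", "ci_low", "ci_high", "p", "tau2",
                          "label")], n))
  invisible(x)
}

#' @export
as.data.frame.iges_discovery <- function(x, ...) x$results
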