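# Independent oracles used across the suite.  Each deliberately takes the
# slow, literal route so it shares no code path with the implementation.

# Full running-sum enrichment score: walk the whole ranking, adding the
# weighted hit increment or subtracting the miss step, and return the signed
# maximum deviation (an exact +/- tie resolves to the positive deviation).
oracle_es <- function(metric_sorted, set_genes) {
  hit <- names(metric_sorted) %in% set_genes
  s <- sum(hit)
  nw <- sum(abs(metric_sorted[hit]))
  run <- 0
  hi <- lo <- 0
  for (i in seq_along(metric_sorted)) {
    if (hit[i]) {
      run <- run + if (nw > 0) abs(metric_sorted[i]) / nw else 1 / s
    } else {
      run <- run - 1 / (length(metric_sorted) - s)
    }
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  # positive deviation wins ties; compare with a tolerance because the
  # sequential accumulation here carries rounding the closed form does not
  unname(if (hi >= -lo - 1e-9) hi else lo)
}

# Pairwise AUC: count concordant positive/negative pairs, ties worth 1/2.
oracle_auc <- function(prob, y) {
  pos <- prob[y == 1]
  neg <- prob[y == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Logistic regression by hand-rolled iteratively reweighted least squares.
oracle_irls <- function(x, y, tol = 1e-12, maxit = 100) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(t(X) %*% (w * X), t(X) %*% (w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- as.numeric(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  vcv <- solve(t(X) %*% ((mu * (1 - mu)) * X))
  list(beta = beta[2], se = sqrt(vcv[2, 2]))
}

# Exact one-sided Wilcoxon rank-sum p-value (known > other) by enumerating
# every assignment of the pooled ranks to the "known" group.
oracle_wilcoxon_p <- function(known, other) {
  pooled <- c(known, other)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(known)])
  combos <- utils::combn(length(pooled), length(known))
  w_null <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(w_null >= w_obs)
}

# Partial Spearman via the independent residual route: regress the ranks of
# x and y on the ranks of z and correlate the residuals.
oracle_partial_spearman <- function(x, y, z) {
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  ex <- stats::resid(stats::lm(rx ~ rz))
  ey <- stats::resid(stats::lm(ry ~ rz))
  stats::cor(ex, ey)
}

# Minimal elastic-net style model object for arithmetic tests.
make_model <- function(coefficients, intercept = 0) {
  structure(list(features = names(coefficients),
                 coefficients = coefficients, intercept = intercept,
                 alpha = 0.5, lambda = 0.1, seed = 1L, cv_auc = NA_real_),
            class = "iges_en")
}

# Minimal pooled-meta object for classification tests.
make_meta <- function(or, p) {
  structure(list(signature_id = "x", beta_pooled = log(or),
                 se_pooled = 0.1, or_pooled = or, ci_low = or * 0.8,
                 ci_high = or * 1.2, p = p, tau2 = 0, q_stat = 0, k = 3,
                 cohort_effects = list()),
            class = "iges_meta")
}

cli_path <- function() system.file("cli", "igesbs.R", package = "igesbs")
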