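#' Cross-cohort harmonization of signature scores
#'
#' Light location/scale batch alignment: each signature is z-scored within
#' each cohort and rescaled to the pooled (all-cohort) mean and standard
#' deviation of that signature.  A signature constant within a cohort is
#' placed at the pooled mean with a warning.  With a single cohort the
#' transformation is the identity.
#'
#' @param scores signatures x samples matrix.
#' @param cohort_labels vector of length `ncol(scores)`.
#' @return harmonized matrix of the same shape and attributes.
#' @export
harmonize_cohorts <- function(scores, cohort_labels) {
  stopifnot(is.matrix(scores), length(cohort_labels) == ncol(scores))
  pooled_mu <- rowMeans(scores)
  pooled_sd <- apply(scores, 1L, stats::sd)
  pooled_sd[pooled_sd == 0] <- 1
  out <- scores
  n_const <- 0L
  for (co in unique(cohort_labels)) {
    j <- which(cohort_labels == co)
    sub <- scores[, j, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- if (length(j) > 1) apply(sub, 1L, stats::sd) else rep(0, nrow(sub))
    const <- sdv == 0
    n_const <- n_const + sum(const)
    sdv[const] <- 1
    z <- (sub - mu) / sdv
    z[const, ] <- 0
    out[, j] <- z * pooled_sd + pooled_mu
  }
  if (n_const > 0 && length(unique(cohort_labels)) > 1) {
    warning(n_const, " signature row(s) constant within a cohort placed at the pooled mean")
  }
  out
}

#' Train the elastic-net response model with nested cross-validation
#'
#' Outer 5-fold stratified cross-validation; within each outer training set an
#' inner 10-fold stratified grid search over the mixing parameter
#' (`alphas`, default 0.1..1.0) and the glmnet lambda path selects the
#' hyperparameters maximizing inner CV AUC.  Out-of-fold predicted
#' probabilities are stacked across the outer folds to give the overall CV
#' AUC.  The final model is refit on all samples with hyperparameters chosen
#' by the same inner search on the full data.  All randomness (fold
#' assignment) derives from `seed`; rerunning with the same seed reproduces
#' the model exactly.
#'
#' @param scores signatures x samples matrix (standardized / harmonized).
#' @param response binary 0/1 vector aligned to columns.
#' @param cohort_labels optional, stored in the model metadata.
#' @param seed integer seed controlling fold assignment.
#' @param alphas elastic-net mixing grid in (0, 1\].
#' @param n_outer,n_inner outer/inner fold counts (5 / 10).
#' @param nlambda length of the glmnet lambda path.
#' @return list with `model` (class `iges_en`: `features`, `coefficients`,
#'   `intercept`, `alpha`, `lambda`, `seed`, `cv`) and `cv` (class
#'   `iges_cv_report`: per-fold AUC, stacked `overall_auc`, fold assignment
#'   and per-fold tuning-sample audit).
#' @export
train_elastic_net <- function(scores, response, cohort_labels = NULL,
                              seed = 1L, alphas = seq(0.1, 1, by = 0.1),
                              n_outer = 5L, n_inner = 10L, nlambda = 50L) {
  stopifnot(is.matrix(scores), length(response) == ncol(scores))
  if (ncol(scores) < 20L) stop("insufficient for nested CV: need >= 20 samples")
  y <- as.integer(response)
  if (length(unique(y)) < 2L) stop("single response class: cannot train")
  x <- t(scores)

  with_seed(seed, {
    outer_fold <- stratified_folds(y, n_outer)
    oof <- rep(NA_real_, length(y))
    fold_auc <- numeric(n_outer)
    fold_n <- integer(n_outer)
    tuning_samples <- vector("list", n_outer)

    # Inner 10-fold grid search: AUC of stacked out-of-fold predictions per
    # (alpha, lambda); the lambda path per alpha comes from a full-data fit
    # within the training split.
    pick_hyper <- function(xtr, ytr) {
      foldid <- stratified_folds(ytr, n_inner)
      best <- list(auc = -Inf)
      for (a in alphas) {
        path <- glmnet::glmnet(xtr, ytr, family = "binomial", alpha = a,
                               nlambda = nlambda, standardize = FALSE)
        lam <- path$lambda
        pred <- matrix(NA_real_, length(ytr), length(lam))
        for (g in seq_len(n_inner)) {
          itr <- foldid != g
          fit_g <- glmnet::glmnet(xtr[itr, , drop = FALSE], ytr[itr],
                                  family = "binomial", alpha = a,
                                  lambda = lam, standardize = FALSE)
          pred[!itr, ] <- as.matrix(
            stats::predict(fit_g, xtr[!itr, , drop = FALSE], s = lam,
                           type = "response"))
        }
        aucs <- apply(pred, 2L, evaluate_auc, labels = ytr)
        i <- which.max(aucs)
        if (aucs[i] > best$auc) {
          best <- list(auc = aucs[i], alpha = a, lambda = lam[i])
        }
      }
      best
    }

    refit_predict <- function(xtr, ytr, best, xnew) {
      fit <- glmnet::glmnet(xtr, ytr, family = "binomial",
                            alpha = best$alpha, nlambda = nlambda,
                            standardize = FALSE)
      list(fit = fit,
           pred = as.numeric(stats::predict(fit, xnew, s = best$lambda,
                                            type = "response")))
    }

    for (f in seq_len(n_outer)) {
      tr <- which(outer_fold != f)
      te <- which(outer_fold == f)
      if (length(unique(y[tr])) < 2L || length(unique(y[te])) < 2L) {
        stop("a CV fold lost a response class; use more samples or fewer folds")
      }
      best <- pick_hyper(x[tr, , drop = FALSE], y[tr])
      oof[te] <- refit_predict(x[tr, , drop = FALSE], y[tr], best,
                               x[te, , drop = FALSE])$pred
      fold_auc[f] <- evaluate_auc(oof[te], y[te])
      fold_n[f] <- length(te)
      tuning_samples[[f]] <- tr
    }

    best_all <- pick_hyper(x, y)
    fit <- refit_predict(x, y, best_all, x)$fit
    cfm <- stats::predict(fit, s = best_all$lambda, type = "coefficients")
    cf <- as.numeric(cfm)
    names(cf) <- rownames(cfm)

    cv <- structure(list(
      fold_auc = fold_auc, fold_n = fold_n,
      overall_auc = evaluate_auc(oof, y),
      oof_probabilities = oof,
      outer_fold = outer_fold,
      tuning_samples = tuning_samples,
      inner_auc = best_all$auc
    ), class = "iges_cv_report")

    model <- structure(list(
      features = rownames(scores),
      coefficients = stats::setNames(cf[-1], rownames(scores)),
      intercept = unname(cf[1]),
      alpha = best_all$alpha, lambda = best_all$lambda,
      seed = seed,
      cohorts = unique(cohort_labels),
      cv_auc = cv$overall_auc
    ), class = "iges_en")

    list(model = model, cv = cv)
  })
}

#' Predict response probability from an elastic-net model
#'
#' Applies the logistic link to `intercept + sum(Coe_i * score_i)` per sample.
#'
#' @param model an `iges_en` model.
#' @param scores signatures x samples matrix containing every model feature
#'   as a row; extra rows are ignored.  Warns when the matrix does not carry
#'   a `standardized`/harmonized scale (scale mismatch with training).
#' @return named numeric vector of per-sample response probabilities.
#' @export
predict_response <- function(model, scores) {
  stopifnot(inherits(model, "iges_en"), is.matrix(scores))
  missing <- setdiff(model$features, rownames(scores))
  if (length(missing)) {
    stop("score matrix lacks model feature(s): ",
         paste(missing, collapse = ", "))
  }
  if (!isTRUE(attr(scores, "standardized"))) {
    warning("scores are not flagged standardized; scale may not match training")
  }
  eta <- model$intercept +
    as.numeric(crossprod(scores[model$features, , drop = FALSE],
                         model$coefficients[model$features]))
  p <- stats::plogis(eta)
  names(p) <- colnames(scores)
  p
}

#' @export
predict.iges_en <- function(object, newdata, ...) {
  predict_response(object, newdata)
}

#' @export
coef.iges_en <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
print.iges_en <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("Elastic-net response model: %d/%d signatures selected (alpha = %g, lambda = %.4g)\n",
              nz, length(x$coefficients), x$alpha, x$lambda))
  cat(sprintf("Nested-CV overall AUC: %.3f (seed %d)\n", x$cv_auc, x$seed))
  invisible(x)
}

#' @export
print.iges_cv_report <- function(x, ...) {
  cat(sprintf("Cross-validation: %d folds, per-fold AUC %s, overall AUC %.3f\n",
              length(x$fold_auc),
              paste(sprintf("%.3f", x$fold_auc), collapse = "/"),
              x$overall_auc))
  invisible(x)
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive outranks
#' a random negative, with ties counted one half (average ranks).
#'
#' @param probabilities numeric predictions (any monotone score).
#' @param labels binary 0/1 vector.
#' @return AUC in \[0, 1\].
#' @export
evaluate_auc <- function(probabilities, labels) {
  stopifnot(length(probabilities) == length(labels))
  y <- as.integer(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(probabilities, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Serialize / restore an elastic-net model as JSON
#'
#' @param model an `iges_en` model.
#' @param path output (input) JSON path.
#' @return `path` invisibly; `read_model_json` returns the model.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "iges_en"))
  obj <- list(features = model$features,
              coefficients = as.list(model$coefficients),
              intercept = model$intercept,
              alpha = model$alpha, lambda = model$lambda,
              seed = model$seed, cv_auc = model$cv_auc)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(features = obj$features,
                 coefficients = unlist(obj$coefficients),
                 intercept = obj$intercept,
                 alpha = obj$alpha, lambda = obj$lambda,
                 seed = obj$seed, cv_auc = obj$cv_auc),
            class = "iges_en")
}
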