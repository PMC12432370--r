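#' Specification of a synthetic study
#'
#' Bundles every tunable of the synthetic-data generators into one validated
#' object.  The defaults emulate, at desk scale, the statistical structure of
#' the real inputs: a handful of response-labelled expression cohorts with
#' latent signature activities, a purity-confounded tissue panel with a
#' cell-line count matrix, and a perturbation screen with engineered booster
#' compounds among nulls.  All generators are pure functions of the spec
#' (identical spec, identical output).
#'
#' @param seed master integer seed.
#' @param n_genes,n_sets,genes_per_set cohort gene universe and disjoint
#'   set blocks (defaults 1000 / 40 / 25).
#' @param cohorts list of `list(n_samples=, responder_fraction=)`; default 5
#'   cohorts of 100 samples at 40% responders.
#' @param planted_effects named numeric: true log-odds of response per 1-SD
#'   latent activity for the named sets (others 0).
#' @param noise_sd residual SD of gene expression around its set activity.
#' @param batch_sd SD of the per-cohort per-gene batch shift.
#' @param baseline mean log2 expression level.
#' @param n_tissue_genes,n_tissue_samples tissue panel size (500 / 200).
#' @param purity_alpha,purity_beta Beta parameters of tumor purity (5, 2).
#' @param score_purity_cor correlation between the signature score and
#'   (standardized) purity in the tissue panel; this is what makes purity a
#'   genuine confounder (default 0.6).
#' @param score_loadings,purity_loadings named numeric loadings of tissue
#'   genes on the signature score / on purity; `NULL` plants 3 of each
#'   (loading 1.5) on disjoint genes.
#' @param n_cell_lines cell lines in the detectability count panel.
#' @param dropout named per-gene probability that a cell line yields zero
#'   reads (default 0 for all genes).
#' @param cancer_type label used throughout the synthetic study.
#' @param cell_lines,cell_weights perturbation cell lines and their weights
#'   (normalized so the maximum is 1).
#' @param n_null_compounds compounds perturbing random non-signature genes.
#' @param booster_magnitude log2 expression shift applied to target genes by
#'   engineered boosters at the reference condition (1 SD).
#' @param doses,times dose (uM) / time (h) grids per compound; defaults to
#'   the single reference condition (10, 24).
#' @param perturb_noise_sd technical noise of the perturbation profiles.
#' @return validated list of class `iges_sim_spec`.
#' @export
simulation_spec <- function(seed = 1L,
                            n_genes = 1000L, n_sets = 40L, genes_per_set = 25L,
                            cohorts = rep(list(list(n_samples = 100L,
                                                    responder_fraction = 0.4)), 5),
                            planted_effects = numeric(),
                            noise_sd = 1, batch_sd = 0.5, baseline = 6,
                            n_tissue_genes = 500L, n_tissue_samples = 200L,
                            purity_alpha = 5, purity_beta = 2,
                            score_purity_cor = 0.6,
                            score_loadings = NULL, purity_loadings = NULL,
                            n_cell_lines = 10L, dropout = NULL,
                            cancer_type = "CT1",
                            cell_lines = c("cl1", "cl2", "cl3"),
                            cell_weights = c(0.7, 0.85, 1),
                            n_null_compounds = 58L,
                            booster_magnitude = 1,
                            doses = 10, times = 24,
                            perturb_noise_sd = 0.5) {
  stopifnot(n_genes >= 1, n_sets >= 1, genes_per_set >= 1,
            n_sets * genes_per_set <= n_genes,
            length(cohorts) >= 1,
            noise_sd > 0, batch_sd >= 0,
            abs(score_purity_cor) < 1,
            length(cell_lines) == length(cell_weights),
            all(cell_weights > 0), all(doses > 0), all(times > 0))
  for (co in cohorts) {
    stopifnot(co$n_samples >= 4,
              co$responder_fraction > 0, co$responder_fraction < 1)
  }
  set_names <- sprintf("S%02d", seq_len(n_sets))
  if (length(planted_effects) > 0) {
    if (is.null(names(planted_effects)) ||
        !all(names(planted_effects) %in% set_names)) {
      stop("planted_effects must be named after existing sets (",
           set_names[1], "..", set_names[n_sets], ")")
    }
  }
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               n_sets = as.integer(n_sets),
               genes_per_set = as.integer(genes_per_set),
               cohorts = cohorts, planted_effects = planted_effects,
               noise_sd = noise_sd, batch_sd = batch_sd, baseline = baseline,
               n_tissue_genes = as.integer(n_tissue_genes),
               n_tissue_samples = as.integer(n_tissue_samples),
               purity_alpha = purity_alpha, purity_beta = purity_beta,
               score_purity_cor = score_purity_cor,
               score_loadings = score_loadings,
               purity_loadings = purity_loadings,
               n_cell_lines = as.integer(n_cell_lines), dropout = dropout,
               cancer_type = cancer_type,
               cell_lines = cell_lines,
               cell_weights = cell_weights / max(cell_weights),
               n_null_compounds = as.integer(n_null_compounds),
               booster_magnitude = booster_magnitude,
               doses = doses, times = times,
               perturb_noise_sd = perturb_noise_sd)
  structure(spec, class = "iges_sim_spec")
}

#' Gene sets of a simulation spec
#'
#' Deterministic disjoint blocks: set `Sxx` holds `genes_per_set` consecutive
#' gene ids from the universe `g0001..`.
#'
#' @param spec an [simulation_spec()].
#' @return an [gene_sets()] collection.
#' @export
sim_gene_sets <- function(spec) {
  stopifnot(inherits(spec, "iges_sim_spec"))
  genes <- sim_gene_ids(spec)
  sets <- lapply(seq_len(spec$n_sets), function(i) {
    genes[((i - 1) * spec$genes_per_set + 1):(i * spec$genes_per_set)]
  })
  names(sets) <- sprintf("S%02d", seq_len(spec$n_sets))
  gene_sets(sets, category = "function")
}

sim_gene_ids <- function(spec) sprintf("g%04d", seq_len(spec$n_genes))

#' Generate response-labelled expression cohorts
#'
#' Per sample, latent signature activities are standard normal; response is
#' Bernoulli under a logistic model whose slope per activity is the planted
#' log-odds (intercept at the logit of the cohort's responder fraction).
#' Expression of a set-member gene is its set's activity plus Gaussian noise;
#' each cohort adds its own per-gene batch shift.  Values are on the log2
#' scale around `baseline`, clipped at zero.
#'
#' @param spec an [simulation_spec()].
#' @return list of cohorts, each `list(expr, response, cohort_id,
#'   activities)`, with the gene-set collection attached as attribute `sets`.
#' @export
generate_cohorts <- function(spec) {
  stopifnot(inherits(spec, "iges_sim_spec"))
  sets <- sim_gene_sets(spec)
  genes <- sim_gene_ids(spec)
  set_of_gene <- rep(NA_integer_, spec$n_genes)
  set_of_gene[seq_len(spec$n_sets * spec$genes_per_set)] <-
    rep(seq_len(spec$n_sets), each = spec$genes_per_set)
  b <- rep(0, spec$n_sets)
  names(b) <- names(sets)
  b[names(spec$planted_effects)] <- spec$planted_effects

  with_seed(spec$seed, {
    lapply(seq_along(spec$cohorts), function(ci) {
      co <- spec$cohorts[[ci]]
      n <- co$n_samples
      act <- matrix(stats::rnorm(spec$n_sets * n), spec$n_sets, n,
                    dimnames = list(names(sets), NULL))
      eta <- stats::qlogis(co$responder_fraction) + as.numeric(crossprod(act, b))
      response <- stats::rbinom(n, 1L, stats::plogis(eta))
      batch <- stats::rnorm(spec$n_genes, 0, spec$batch_sd)
      signal <- matrix(0, spec$n_genes, n)
      in_set <- !is.na(set_of_gene)
      signal[in_set, ] <- act[set_of_gene[in_set], , drop = FALSE]
      expr <- spec$baseline + batch + signal +
        matrix(stats::rnorm(spec$n_genes * n, 0, spec$noise_sd), spec$n_genes, n)
      expr[expr < 0] <- 0
      sample_ids <- sprintf("c%02d_s%03d", ci, seq_len(n))
      dimnames(expr) <- list(genes, sample_ids)
      colnames(act) <- sample_ids
      names(response) <- sample_ids
      attr(expr, "log_transformed") <- TRUE
      list(expr = expr, response = response,
           cohort_id = sprintf("cohort%02d", ci), activities = act)
    }) -> cohorts
    attr(cohorts, "sets") <- sets
    cohorts
  })
}

#' Generate the tissue panel for expansion testing
#'
#' One signature score per sample, correlated with tumor purity at
#' `score_purity_cor` so purity genuinely confounds; designated genes load on
#' the score (true expansion targets) or on purity (confounders); a cell-line
#' count panel with per-gene dropout exercises the detectability filter.
#'
#' @param spec an [simulation_spec()].
#' @return list: `expr` (genes x samples), `scores` (named per-sample score),
#'   `purity` (data.frame sample_id, purity, cancer_type), `cellline_counts`,
#'   `truth` (list of target / confounder gene ids).
#' @export
generate_tissue_panel <- function(spec) {
  stopifnot(inherits(spec, "iges_sim_spec"))
  genes <- sprintf("t%04d", seq_len(spec$n_tissue_genes))
  ls <- stats::setNames(rep(0, spec$n_tissue_genes), genes)
  lp <- ls
  if (is.null(spec$score_loadings)) {
    ls[1:3] <- 1.5
  } else {
    ls[names(spec$score_loadings)] <- spec$score_loadings
  }
  if (is.null(spec$purity_loadings)) {
    lp[4:6] <- 1.5
  } else {
    lp[names(spec$purity_loadings)] <- spec$purity_loadings
  }

  with_seed(spec$seed + 1000L, {
    n <- spec$n_tissue_samples
    purity <- stats::rbeta(n, spec$purity_alpha, spec$purity_beta)
    pz <- as.numeric(scale(purity))
    rho <- spec$score_purity_cor
    score <- rho * pz + sqrt(1 - rho^2) * stats::rnorm(n)
    expr <- spec$baseline + outer(ls, score) + outer(lp, pz) +
      matrix(stats::rnorm(spec$n_tissue_genes * n), spec$n_tissue_genes, n)
    expr[expr < 0] <- 0
    sample_ids <- sprintf("t_s%03d", seq_len(n))
    dimnames(expr) <- list(genes, sample_ids)
    attr(expr, "log_transformed") <- TRUE
    names(score) <- sample_ids

    drop_p <- stats::setNames(rep(0, spec$n_tissue_genes), genes)
    if (!is.null(spec$dropout)) drop_p[names(spec$dropout)] <- spec$dropout
    counts <- matrix(stats::rpois(spec$n_tissue_genes * spec$n_cell_lines, 5),
                     spec$n_tissue_genes, spec$n_cell_lines,
                     dimnames = list(genes,
                                     sprintf("ccle%02d", seq_len(spec$n_cell_lines))))
    zero <- matrix(stats::runif(length(counts)) < drop_p,
                   nrow(counts), ncol(counts))
    counts[zero] <- 0L

    list(expr = expr, scores = score,
         purity = data.frame(sample_id = sample_ids, purity = purity,
                             cancer_type = spec$cancer_type,
                             stringsAsFactors = FALSE),
         cellline_counts = counts,
         truth = list(score_genes = genes[ls != 0],
                      purity_genes = genes[lp != 0 & ls == 0]))
  })
}

#' Generate a perturbation screen with engineered boosters
#'
#' Plate-matched treated/control profiles over the cohort gene universe.
#' Two engineered compounds are included: `booster_up` raises every gene of
#' the `siges` sets and lowers every gene of the `riges` sets by
#' `booster_magnitude` (at the reference condition); `booster_down` is its
#' inversion.  Null compounds shift an equal number of randomly chosen
#' non-signature genes.  The shift scales with dose
#' (`1 + 0.5 log10(dose/10)`) and time (`(time/24)^0.3`), so a 10 uM / 24 h
#' profile sits between lower- and higher-dose profiles.
#'
#' @param spec an [simulation_spec()].
#' @param sets gene sets the targets refer to (e.g. [sim_gene_sets()] or
#'   expanded signatures translated to a collection).
#' @param siges,riges character vectors of set names treated as
#'   sensitivity- / resistance-associated targets.
#' @return list: `perturb` (`iges_perturbations`), `weights` (cell-weight
#'   table), `boosters` (data.frame compound, known_booster).
#' @export
generate_perturbations <- function(spec, sets, siges, riges = character()) {
  stopifnot(inherits(spec, "iges_sim_spec"), inherits(sets, "iges_genesets"))
  stopifnot(all(c(siges, riges) %in% names(sets)))
  genes <- sim_gene_ids(spec)
  up_genes <- unique(unlist(sets[siges], use.names = FALSE))
  down_genes <- unique(unlist(sets[riges], use.names = FALSE))
  target_union <- union(unlist(sets, use.names = FALSE), character())
  free_genes <- setdiff(genes, target_union)
  n_hit <- max(1L, length(up_genes) + length(down_genes))

  compounds <- c("booster_up", "booster_down",
                 sprintf("null_%03d", seq_len(spec$n_null_compounds)))

  with_seed(spec$seed + 2000L, {
    conds <- list(); treated <- list(); control <- list()
    for (cl_i in seq_along(spec$cell_lines)) {
      cl <- spec$cell_lines[cl_i]
      base <- spec$baseline + stats::rnorm(spec$n_genes)
      ctl <- base + stats::rnorm(spec$n_genes, 0, spec$perturb_noise_sd)
      for (cmp in compounds) {
        effect <- rep(0, spec$n_genes)
        names(effect) <- genes
        if (cmp == "booster_up") {
          effect[up_genes] <- spec$booster_magnitude
          effect[down_genes] <- -spec$booster_magnitude
        } else if (cmp == "booster_down") {
          effect[up_genes] <- -spec$booster_magnitude
          effect[down_genes] <- spec$booster_magnitude
        } else {
          hit <- sample(free_genes, min(n_hit, length(free_genes)))
          effect[hit] <- sample(c(-1, 1), length(hit), replace = TRUE) *
            spec$booster_magnitude
        }
        for (dose in spec$doses) for (tm in spec$times) {
          scale <- (1 + 0.5 * log10(dose / 10)) * (tm / 24)^0.3
          tr <- base + scale * effect +
            stats::rnorm(spec$n_genes, 0, spec$perturb_noise_sd)
          id <- paste(cmp, cl, dose, tm, paste0("p", cl_i), sep = "|")
          conds[[id]] <- data.frame(
            condition_id = id, compound = cmp, cell_line = cl,
            cancer_type = spec$cancer_type, dose_um = dose, time_h = tm,
            plate = paste0("p", cl_i), stringsAsFactors = FALSE)
          treated[[id]] <- tr
          control[[id]] <- ctl
        }
      }
    }
    perturb <- structure(list(
      conditions = do.call(rbind, c(conds, list(make.row.names = FALSE))),
      treated = matrix(unlist(treated), spec$n_genes,
                       dimnames = list(genes, names(treated))),
      control = matrix(unlist(control), spec$n_genes,
                       dimnames = list(genes, names(control)))
    ), class = "iges_perturbations")
    weights <- data.frame(cell_line = spec$cell_lines,
                          cancer_type = spec$cancer_type,
                          W = spec$cell_weights, stringsAsFactors = FALSE)
    boosters <- data.frame(compound = compounds,
                           known_booster = compounds == "booster_up",
                           stringsAsFactors = FALSE)
    list(perturb = perturb, weights = weights, boosters = boosters)
  })
}
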