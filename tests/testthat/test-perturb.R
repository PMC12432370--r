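test_that("rank_genes orders by expression difference with lexicographic ties", {
  g <- paste0("g", 1:8)
  tr <- setNames(c(5, 3, 8, 1, 9, 2, 7, 4), g)
  ct <- setNames(c(1, 3, 2, 5, 4, 2, 7, 1), g)
  rk <- rank_genes(tr, ct)
  expect_equal(rk$gene, g[order(-(tr - ct), g)])
  expect_equal(rk$metric, sort(tr - ct, decreasing = TRUE),
               ignore_attr = TRUE)

  same <- rank_genes(tr, tr)
  expect_true(all(same$metric == 0))
  expect_equal(same$gene, sort(g))

  up <- ct; up["g4"] <- up["g4"] + 2
  expect_equal(rank_genes(up, ct)$gene[1], "g4")
  expect_error(rank_genes(tr, ct[-1]), "same gene universe")
})

test_that("enrichment score equals the exhaustive running-sum oracle", {
  metric <- setNames(c(3, 2, 1, -1, -2, -3), paste0("g", 1:6))
  es <- gsea_prerank(metric, c("g1", "g2"), nperm = 100, seed = 1)$es
  expect_equal(es, oracle_es(metric, c("g1", "g2")))

  # all-tied (zero) metric degrades to the unweighted statistic
  zero <- setNames(rep(0, 6), paste0("g", 1:6))
  expect_equal(gsea_prerank(zero, c("g1", "g2"), nperm = 100, seed = 1)$es,
               oracle_es(zero, c("g1", "g2")))
})

test_that("extreme enrichment yields the minimal permutation p", {
  metric <- setNames(c(10, 9, 8, seq(-0.1, -5, length.out = 17)),
                     sprintf("g%02d", 1:20))
  r <- gsea_prerank(metric, c("g01", "g02", "g03"), nperm = 500, seed = 2)
  expect_gt(r$es, 0.9)
  expect_gt(r$nes, 1)
  expect_lte(r$p_perm, 0.02)
  expect_gte(r$p_perm, 1 / 501)
})

test_that("preranked GSEA rejects degenerate sets", {
  metric <- setNames(rnorm(6), paste0("g", 1:6))
  expect_error(gsea_prerank(metric, c("x1", "x2"), nperm = 100),
               "does not intersect")
  expect_error(gsea_prerank(metric, paste0("g", 1:6), nperm = 100),
               "degenerate set")
  expect_error(gsea_prerank(metric, "g1", nperm = 10), "nperm")
})

test_that("NES sign matches ES sign and p stays within permutation bounds", {
  set.seed(61)
  for (i in 1:20) {
    metric <- setNames(rnorm(30), sprintf("g%02d", 1:30))
    set <- sample(names(metric), 5)
    r <- gsea_prerank(metric[order(-metric)], set, nperm = 200, seed = i)
    expect_equal(sign(r$nes), sign(r$es))
    expect_gte(r$p_perm, 1 / 201)
    expect_lte(r$p_perm, 1)
  }
})

test_that("ACAT identities, closed form and monotonicity hold", {
  expect_equal(acat_combine(c(0.5, 0.5, 0.5)), 0.5, tolerance = 1e-12)
  for (p in c(0.001, 0.01, 0.2, 0.5, 0.77, 0.999)) {
    expect_equal(acat_combine(rep(p, 4)), p, tolerance = 1e-12)
  }
  # direct scalar evaluation
  pv <- c(0.01, 0.04, 0.5)
  t_direct <- mean(tan((0.5 - pv) * pi))
  expect_equal(acat_combine(pv), 0.5 - atan(t_direct) / pi, tolerance = 1e-15)

  # monotone: lowering any input never raises the output
  set.seed(62)
  for (i in 1:25) {
    pv <- runif(4, 0.01, 0.99)
    j <- sample(4, 1)
    pv2 <- pv
    pv2[j] <- pv[j] * 0.5
    expect_lte(acat_combine(pv2), acat_combine(pv))
    expect_gt(acat_combine(pv), 0)
    expect_lt(acat_combine(pv), 1)
  }

  expect_error(acat_combine(numeric()), "no p-values")
  expect_warning(acat_combine(c(0.5, 1)), "clipped")
  expect_error(acat_combine(c(0.2, 0.3), weights = c(0, 0)), "weights")
})

mk_enrich <- function(signature, cell_line, dose, time, nes, fdr = 0.01,
                      compound = "cmpA", cancer = "CT1") {
  data.frame(condition_id = paste(compound, cell_line, dose, time, sep = "|"),
             compound = compound, cell_line = cell_line, cancer_type = cancer,
             dose_um = dose, time_h = time, signature = signature, size = 10,
             es = nes / 2, nes = nes, p_perm = fdr, fdr = fdr,
             stringsAsFactors = FALSE)
}

wtab <- data.frame(cell_line = c("c1", "c2"), cancer_type = "CT1",
                   W = c(0.9, 1), stringsAsFactors = FALSE)

test_that("PGES reduces to W * NES for a single condition", {
  e1 <- mk_enrich("S1", "c2", 10, 24, nes = 2)
  expect_equal(compute_pges(e1, wtab)$pges, 2.0)
  e2 <- mk_enrich("S1", "c1", 10, 24, nes = 2)
  expect_equal(compute_pges(e2, wtab)$pges, 0.9 * 2)
})

test_that("multi-condition PGES matches hand arithmetic of the awarding term", {
  # one cell line (W = 0.9), reference NES 2.0, extra conditions NES 1.0, 3.0
  e <- rbind(mk_enrich("S1", "c1", 10, 24, nes = 2),
             mk_enrich("S1", "c1", 1, 24, nes = 1),
             mk_enrich("S1", "c1", 100, 24, nes = 3))
  pg <- compute_pges(e, wtab)
  f <- ((1 - 2) + (3 - 2)) / 2
  expect_equal(pg$pges, 0.9 * (2 + f))
  expect_equal(pg$n_conditions, 3)

  # two cell lines, each a single (reference) condition: weighted average
  e2 <- rbind(mk_enrich("S1", "c1", 10, 24, nes = 2),
              mk_enrich("S1", "c2", 10, 24, nes = -1))
  expect_equal(compute_pges(e2, wtab)$pges, (0.9 * 2 + 1 * (-1)) / 2)
})

test_that("reference selection falls back to the nearest dose/time", {
  # no (10, 24): candidates (1, 24) and (100, 24) tie in log distance;
  # the lower dose wins the tie and becomes the reference
  e <- rbind(mk_enrich("S1", "c1", 1, 24, nes = 1),
             mk_enrich("S1", "c1", 100, 24, nes = 3))
  pg <- compute_pges(e, wtab)
  f <- (3 - 1)
  expect_equal(pg$pges, 0.9 * (1 + f))
})

test_that("PGES is linear in NES and combines p-values by ACAT", {
  e <- rbind(mk_enrich("S1", "c1", 10, 24, nes = 2, fdr = 0.02),
             mk_enrich("S1", "c1", 1, 24, nes = 1, fdr = 0.3),
             mk_enrich("S1", "c2", 10, 24, nes = -1, fdr = 0.7))
  pg <- compute_pges(e, wtab)
  e3 <- e
  e3$nes <- 3 * e3$nes
  expect_equal(compute_pges(e3, wtab)$pges, 3 * pg$pges, tolerance = 1e-12)
  expect_equal(pg$p_combined, acat_combine(c(0.02, 0.3, 0.7)),
               tolerance = 1e-12)
})

test_that("cell-weight lookup falls back to the cancer-type mean, then 1", {
  expect_equal(cell_weight(wtab, "c1", "CT1"), 0.9)
  expect_equal(cell_weight(wtab, "missing", "CT1"), mean(c(0.9, 1)))
  expect_warning(w <- cell_weight(wtab, "c9", "CT9"), "using 1.0")
  expect_equal(w, 1.0)
})

test_that("boosting score is the coefficient-masked dot product over significant trios", {
  model <- make_model(c(S1 = 0.5, S2 = -0.3, S3 = 0.2, S4 = 1, S5 = 0))
  pg <- data.frame(signature = paste0("S", 1:5), cancer_type = "CT1",
                   compound = "cmpA",
                   pges = c(2, -1, 3, 0.5, 4),
                   p_combined = c(0.01, 0.2, 0.03, 0.04, 0.2),
                   n_conditions = 1, n_cell_lines = 1,
                   stringsAsFactors = FALSE)
  bs <- compute_boosting_score(pg, model)
  mask <- pg$p_combined < 0.05
  expect_equal(bs$bs, sum(c(0.5, -0.3, 0.2, 1, 0)[mask] * pg$pges[mask]))
  expect_equal(bs$n_significant, 3)

  # nothing significant -> 0; single-term case
  pg0 <- pg
  pg0$p_combined <- 0.9
  expect_equal(compute_boosting_score(pg0, model)$bs, 0)
  pg1 <- pg[1, ]
  expect_equal(compute_boosting_score(pg1, model)$bs, 0.5 * 2)

  # negating every pges negates bs exactly
  pgn <- pg
  pgn$pges <- -pgn$pges
  expect_equal(compute_boosting_score(pgn, model)$bs, -bs$bs)

  # unknown signature skipped with warning
  pg_extra <- rbind(pg, within(pg[1, ], signature <- "S99"))
  expect_warning(bs2 <- compute_boosting_score(pg_extra, model),
                 "without a model coefficient")
  expect_equal(bs2$bs, bs$bs)
})

test_that("compound ranking is dense, deterministic and percentiled", {
  one <- data.frame(compound = "only", cancer_type = "CT1", bs = 1,
                    n_significant = 1, stringsAsFactors = FALSE)
  r1 <- rank_compounds(one)
  expect_equal(r1$rank, 1)
  expect_equal(r1$percentile, 1)

  many <- data.frame(compound = sprintf("c%04d", 1:1768), cancer_type = "CT1",
                     bs = seq(1768, 1, by = -1), n_significant = 1,
                     stringsAsFactors = FALSE)
  rk <- rank_compounds(many)
  expect_equal(rk$compound, many$compound)
  expect_equal(rk$percentile[20], 20 / 1768)   # ~ top 1.2%
  expect_lt(rk$percentile[20], 0.012)

  ties <- data.frame(compound = c("b", "a"), cancer_type = "CT1", bs = c(1, 1),
                     n_significant = 1, stringsAsFactors = FALSE)
  expect_equal(rank_compounds(ties)$compound, c("a", "b"))
})

test_that("booster enrichment matches the exhaustive Wilcoxon oracle", {
  known <- c(5.2, 4.8, 6.1, 5.5)
  other <- c(3.1, 2.8, 3.9, 4.1, 3.3)
  res <- booster_enrichment_test(c(known, other),
                                 c(rep(TRUE, 4), rep(FALSE, 5)))
  expect_equal(res$effect_size, mean(known) - mean(other))
  expect_equal(res$p, oracle_wilcoxon_p(known, other), tolerance = 1e-12)
  expect_true(res$enriched)   # effect > 1 and p < 0.05

  same <- rep(2, 8)
  r2 <- suppressWarnings(
    booster_enrichment_test(same, rep(c(TRUE, FALSE), 4)))
  expect_equal(r2$effect_size, 0)
  expect_false(r2$enriched)

  # effect just above 1 but p >= 0.05 is not enriched
  r3 <- suppressWarnings(
    booster_enrichment_test(c(2.2, 1, 1, 1.2), c(TRUE, FALSE, FALSE, FALSE)))
  expect_gt(r3$effect_size, 1)
  expect_false(r3$enriched)
  expect_error(booster_enrichment_test(1:3, rep(TRUE, 3)), "non-empty")
})

test_that("direction consistency counts matching NES signs among regulated calls", {
  sigs <- sprintf("S%02d", 1:13)
  a <- data.frame(signature = sigs, nes = c(rep(2, 8), rep(-2, 5)),
                  padj = 0.01, stringsAsFactors = FALSE)
  b <- a
  expect_equal(direction_consistency(a, b), 1.0)
  b$nes <- -b$nes
  expect_equal(direction_consistency(a, b), 0.0)

  # 13 regulated, 11 concordant
  b2 <- a
  b2$nes[c(3, 9)] <- -b2$nes[c(3, 9)]
  expect_equal(direction_consistency(a, b2), 11 / 13, tolerance = 1e-12)

  a$padj <- 0.5
  expect_warning(res <- direction_consistency(a, b), "undefined")
  expect_true(is.na(res))
})

test_that("perturbation TSV round-trips through write and read", {
  spec <- simulation_spec(seed = 71, n_genes = 60, n_sets = 4,
                          genes_per_set = 10, n_null_compounds = 2,
                          cell_lines = c("c1", "c2"), cell_weights = c(0.8, 1))
  sets <- sim_gene_sets(spec)
  pt <- generate_perturbations(spec, sets, siges = "S01", riges = "S02")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_perturbations_tsv(pt$perturb, f)
  back <- read_perturbations_tsv(f)
  expect_equal(back$conditions$compound, pt$perturb$conditions$compound)
  expect_equal(back$treated, pt$perturb$treated, tolerance = 1e-9)
  expect_equal(back$control, pt$perturb$control, tolerance = 1e-9)
})
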