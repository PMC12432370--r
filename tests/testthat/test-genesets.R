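test_that("GMT parsing handles empty files, duplicates and malformed lines", {
  f <- withr::local_tempfile(fileext = ".gmt")

  writeLines(character(), f)
  expect_length(read_gmt(f), 0)

  writeLines("S1\tdesc\tg1\tg2\tg2", f)
  gs <- read_gmt(f)
  expect_equal(gs[["S1"]], c("g1", "g2"))

  writeLines("S1\tdesc", f)
  expect_error(read_gmt(f), "malformed GMT line 1")

  writeLines(c("S1\td\tg1", "S1\td\tg2"), f)
  expect_error(read_gmt(f), "duplicate")
})

test_that("write_gmt followed by read_gmt restores the collection", {
  gs <- gene_sets(list(alpha = c("g1", "g2", "g3"), beta = c("g9", "g2")),
                  description = c("first", "second"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, f)
  back <- read_gmt(f)
  expect_equal(unclass(back)[], unclass(gs)[],
               ignore_attr = TRUE)
  expect_equal(names(back), names(gs))
  expect_equal(attr(back, "description"), attr(gs, "description"))
})

test_that("gene set construction enforces invariants", {
  expect_error(gene_sets(list(A = character())), "non-empty")
  expect_error(gene_sets(list(c("g1"))), "named")
  gs <- gene_sets(list(A = c("g1", "g1", "g2")))
  expect_equal(gs[["A"]], c("g1", "g2"))
})

make_toy_expr <- function() {
  # 5 genes x 4 samples, linear scale
  m <- matrix(c(1, 2, 3, 4,
                8, 4, 2, 1,
                5, 5, 5, 5,
                0, 1, 0, 1,
                2, 9, 4, 7), 5, 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  m
}

test_that("mean_z scores equal hand-computed gene z averages", {
  expr <- make_toy_expr()
  sets <- gene_sets(list(AB = c("g1", "g2")))
  sc <- score_signatures(expr, sets, method = "mean_z")
  lg <- log2(expr + 1)
  z1 <- (lg["g1", ] - mean(lg["g1", ])) / sd(lg["g1", ])
  z2 <- (lg["g2", ] - mean(lg["g2", ])) / sd(lg["g2", ])
  expect_equal(unname(sc["AB", ]), unname((z1 + z2) / 2))
})

test_that("zero-variance genes score zero and identical samples score identically", {
  expr <- make_toy_expr()
  sc <- score_signatures(expr, gene_sets(list(flat = "g3")))
  expect_equal(unname(sc["flat", ]), rep(0, 4))

  expr2 <- expr
  expr2[, 2] <- expr2[, 1]   # duplicate sample
  sc2 <- score_signatures(expr2, gene_sets(list(S = c("g1", "g5"))))
  expect_equal(sc2[, 1], sc2[, 2], ignore_attr = TRUE)
})

test_that("scoring is invariant to gene/sample permutation and per-gene affine maps", {
  set.seed(11)
  expr <- matrix(rexp(20 * 8), 20, 8,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:8)))
  sets <- gene_sets(list(A = sprintf("g%02d", 1:5), B = sprintf("g%02d", 6:12)))
  base <- score_signatures(expr, sets)

  perm <- score_signatures(expr[sample(20), sample(8)], sets)
  expect_equal(perm[rownames(base), colnames(base)], base,
               ignore_attr = TRUE)

  # location/scale on the log scale: feed log-transformed input directly
  lg <- log2(expr + 1)
  attr(lg, "log_transformed") <- TRUE
  ref <- score_signatures(lg, sets)
  lg2 <- lg
  lg2["g01", ] <- 3 * lg2["g01", ] + 7
  attr(lg2, "log_transformed") <- TRUE
  expect_equal(score_signatures(lg2, sets), ref, ignore_attr = TRUE)
})

test_that("rank_enrichment rises when member genes dominate the sample", {
  set.seed(3)
  expr <- matrix(runif(20 * 3, 1, 10), 20, 3,
                 dimnames = list(sprintf("g%02d", 1:20), c("a", "b", "c")))
  sets <- gene_sets(list(S = sprintf("g%02d", 1:4)))
  before <- score_signatures(expr, sets, method = "rank_enrichment")
  expr2 <- expr
  expr2[1:4, ] <- expr2[1:4, ] + 100       # members above every non-member
  after <- score_signatures(expr2, sets, method = "rank_enrichment")
  expect_true(all(after > before))
  expect_true(all(after <= 1 & after >= -1))
})

test_that("missing member genes are dropped with a warning; empty sets score NA", {
  expr <- make_toy_expr()
  sets <- gene_sets(list(S = c("g1", "nope"), gone = c("nope1", "nope2")))
  sc <- suppressWarnings(score_signatures(expr, sets))
  expect_true(all(is.na(sc["gone", ])))
  expect_false(anyNA(sc["S", ]))
  w <- capture_warnings(score_signatures(expr, sets))
  expect_match(w, "dropped", all = FALSE)
  expect_match(w, "score NA", all = FALSE)
})

test_that("standardization gives per-cohort mean 0 / sd 1 and is idempotent", {
  m <- matrix(c(1, 2, 3), 1, 3, dimnames = list("S", c("a", "b", "c")))
  z <- standardize_scores(m)
  expect_equal(unname(z[1, ]), c(-1, 0, 1))
  expect_equal(standardize_scores(z), z, tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(attr(z, "standardized"))

  set.seed(5)
  scores <- matrix(rnorm(3 * 12), 3, 12,
                   dimnames = list(paste0("S", 1:3), paste0("s", 1:12)))
  scores[, 1:6] <- scores[, 1:6] + 10       # cohort-specific shift
  cohorts <- rep(c("A", "B"), each = 6)
  z2 <- standardize_scores(scores, cohorts)
  for (co in c("A", "B")) {
    sub <- z2[, cohorts == co]
    expect_equal(unname(rowMeans(sub)), rep(0, 3), tolerance = 1e-8)
    expect_equal(unname(apply(sub, 1, sd)), rep(1, 3), tolerance = 1e-6)
  }
})

test_that("constant score rows standardize to zero with a warning", {
  m <- matrix(c(2, 2, 2, 1, 5, 9), 2, 3, byrow = TRUE,
              dimnames = list(c("flat", "ok"), c("a", "b", "c")))
  expect_warning(z <- standardize_scores(m), "constant")
  expect_equal(unname(z["flat", ]), rep(0, 3))
  expect_false(anyNA(z))
})
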