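# Weighted Kolmogorov-Smirnov enrichment internals shared by the per-sample
# rank_enrichment score and by preranked GSEA of perturbation profiles.

# Enrichment score from hit positions within a ranking of `n_universe` genes.
# `pos` are the (sorted, increasing) 1-based positions of the set members in
# the ranking, `w` the non-negative weights (|metric|^1) at those positions.
# The running sum adds w_i / sum(w) at each hit and subtracts 1/(n - s) at
# each miss; ES is the signed maximum deviation, an exact tie between the
# positive and negative extremes resolving to the positive one.  A zero
# weight sum (all-tied metric) degrades to the unweighted KS statistic.
es_from_positions <- function(pos, w, n_universe) {
  s <- length(pos)
  nw <- sum(w)
  cum_hit <- if (nw > 0) cumsum(w) / nw else seq_len(s) / s
  miss_step <- 1 / (n_universe - s)
  miss_before <- (pos - seq_len(s)) * miss_step
  dev_at <- cum_hit - miss_before                 # just after each hit
  dev_before <- c(0, cum_hit[-s]) - miss_before   # just before each hit
  hi <- max(dev_at)
  lo <- min(dev_before)
  unname(if (hi >= -lo) hi else lo)
}

# Observed ES for a set of gene ids against a metric vector already sorted in
# ranking order (names = gene ids, descending metric).
es_observed <- function(metric_sorted, set_genes) {
  pos <- which(names(metric_sorted) %in% set_genes)
  es_from_positions(pos, abs(metric_sorted[pos]), length(metric_sorted))
}

# Null ES distribution under gene-label permutation: set membership is a
# uniform draw of `size` positions from the ranking, so the null depends only
# on (metric, size) and can be shared across sets of equal size.
es_null <- function(metric_sorted, size, nperm) {
  aw <- abs(metric_sorted)
  n <- length(metric_sorted)
  vapply(seq_len(nperm), function(b) {
    pos <- sort.int(sample.int(n, size))
    es_from_positions(pos, aw[pos], n)
  }, numeric(1))
}

# Sign-matched normalization and permutation p-value.
# NES = ES / mean(|null ES| of the same sign); p = (1 + #{null of that sign at
# least as extreme}) / (1 + #{null of that sign}).  Falls back to the mean of
# all |null ES| when no null value shares the observed sign.
nes_and_p <- function(es, null_es) {
  if (es == 0) return(list(nes = 0, p = 1))
  same <- if (es > 0) null_es[null_es > 0] else null_es[null_es < 0]
  denom <- if (length(same) > 0) mean(abs(same)) else mean(abs(null_es))
  if (!is.finite(denom) || denom == 0) denom <- 1
  nes <- es / denom
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  list(nes = nes, p = p)
}
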