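# shared fixtures and independent oracles

# brute-force beta-binomial upper tail, accumulated forward in log space by
# sequential log-add; independent of the implementation's reverse-cumulative
# vectorised path
bb_tail_oracle_log10 <- function(alt, depth, alpha, beta) {
  if (alt == 0) return(0)
  acc <- -Inf
  for (k in alt:depth) {
    term <- lchoose(depth, k) + lbeta(k + alpha, depth - k + beta) -
      lbeta(alpha, beta)
    m <- max(acc, term)
    acc <- m + log(exp(acc - m) + exp(term - m))
  }
  -min(acc, 0) / log(10)
}

# grid-search beta-binomial MLE over (log alpha, log beta)
bb_grid_mle <- function(alt, depth, la = seq(-8, 8, 0.1), lb = seq(-2, 14, 0.1)) {
  best <- c(NA, NA); best_ll <- -Inf
  for (a in la) for (b in lb) {
    ll <- sum(lchoose(depth, alt) + lbeta(alt + exp(a), depth - alt + exp(b)) -
                lbeta(exp(a), exp(b)))
    if (ll > best_ll) { best_ll <- ll; best <- c(exp(a), exp(b)) }
  }
  list(alpha = best[1], beta = best[2], loglik = best_ll)
}

# tiny three-pathway gene-set collection over a synthetic gene universe,
# mirroring the sizes of the PI3K-AKT/MAPK/AMPK reference sets
toy_gene_sets <- function() {
  genes <- sprintf("GENE%04d", 1:2000)
  list(
    PI3K_AKT = genes[1:341],
    MAPK = genes[200:454],   # 255 genes, overlapping PI3K_AKT
    AMPK = genes[500:623]    # 124 genes
  )
}

# deterministic multinomial sample of n draws from a 96-probability vector
draw_spectrum <- function(n, probs, seed) {
  set.seed(seed)
  counts <- as.integer(stats::rmultinom(1, n, probs))
  names(counts) <- somamosaic::channel_labels()
  structure(counts, total = sum(counts), class = "spectrum96")
}

cosine <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
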