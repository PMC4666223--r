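# Independent oracles kept deliberately naive: they re-derive the expected
# values from first principles and never call the implementation under test.

# Exact one-sided Mann-Whitney p-value by exhaustive enumeration of all
# C(n1+n2, n1) group labelings of the pooled sample: the fraction of
# labelings whose U statistic is at least the observed one.
mwu_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  labelings <- utils::combn(length(pooled), n1)
  u_all <- apply(labelings, 2, u_of)
  mean(u_all >= u_obs)
}

# Straightforward running-sum enrichment score, written directly from the
# formula with an explicit loop.
es_oracle <- function(genes, scores, gene_set, weight_p) {
  n <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  nr <- sum(abs(scores[hit])^weight_p)
  run <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- if (hit[i]) acc + abs(scores[i])^weight_p / nr
           else acc - 1 / (n - nh)
    run[i] <- acc
  }
  peak <- which.max(abs(run))
  list(ES = run[peak], peak_index = peak)
}
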