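# Independent oracles, kept deliberately naive.

# Exhaustive pairwise concordance (ties one half).
brute_auc <- function(scores, outcomes) {
  cs <- scores[outcomes]
  ct <- scores[!outcomes]
  tot <- 0
  for (x in cs) tot <- tot + sum(x > ct) + 0.5 * sum(x == ct)
  tot / (length(cs) * length(ct))
}

# Competing-processes oracle for the annual recursion: the lung-cancer
# and death processes are independent sequences of Bernoulli years; a
# subject becomes a case when the first lung-cancer year is not
# preceded by a death year (same-year collisions resolve in favour of
# the cancer diagnosis).  Integer horizons only.
oracle_recursion <- function(hlc, hm, horizon) {
  H <- as.integer(horizon)
  p_first_lc <- numeric(H + 1)
  p_first_d <- numeric(H + 1)
  sL <- 1
  sD <- 1
  for (k in seq_len(H)) {
    p_first_lc[k] <- sL * hlc[k]
    sL <- sL * (1 - hlc[k])
    p_first_d[k] <- sD * hm[k]
    sD <- sD * (1 - hm[k])
  }
  p_first_lc[H + 1] <- sL  # no cancer within horizon
  p_first_d[H + 1] <- sD   # no death within horizon
  tot <- 0
  for (a in seq_len(H)) {
    for (b in seq_len(H + 1)) {
      if (b >= a) tot <- tot + p_first_lc[a] * p_first_d[b]
    }
  }
  tot
}
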