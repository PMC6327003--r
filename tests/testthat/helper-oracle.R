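# Independent oracles and small builders used across the test files.
#
# The oracle recomputes sequence probabilities step by step from first
# principles (scalar arithmetic, no shared code with the package's vectorized
# likelihood), so likelihood tests are a genuine dual-route check.

oracle_avail <- function(n, k, r) max(n - k, 0) + r * min(k, n)

oracle_pair_weight <- function(f, m, h, bf, bm, labelA) {
  w <- if (f == m) (1 + h) / 2 else (1 - h) / 2
  if (f == labelA) w <- w * bf
  if (m == labelA) w <- w * bm
  w
}

# probability of one observed sequence of (female_class, male_class) pairs
oracle_seq_prob <- function(fs, ms, design, h, bf, bm) {
  lab <- design$labels
  kF <- c(0, 0); kM <- c(0, 0)
  names(kF) <- names(kM) <- lab
  p <- 1
  for (t in seq_along(fs)) {
    w <- matrix(0, 2, 2, dimnames = list(lab, lab))
    for (f in lab) for (m in lab) {
      w[f, m] <- oracle_avail(design$n_females, kF[f], design$r_female) *
        oracle_avail(design$n_males, kM[m], design$r_male) *
        oracle_pair_weight(f, m, h, bf, bm, lab[1])
    }
    tot <- sum(w)
    if (tot <= 0) return(0)
    p <- p * w[fs[t], ms[t]] / tot
    kF[fs[t]] <- kF[fs[t]] + 1
    kM[ms[t]] <- kM[ms[t]] + 1
  }
  p
}

# enumerate all complete sequences (length 2 * n_females) and their oracle
# probabilities; returns total probability mass
oracle_total_prob <- function(design, h, bf, bm) {
  lab <- design$labels
  recurse <- function(fs, ms, depth) {
    if (depth == 0L) return(oracle_seq_prob(fs, ms, design, h, bf, bm))
    tot <- 0
    for (f in lab) for (m in lab) {
      p <- oracle_seq_prob(c(fs, f), c(ms, m), design, h, bf, bm)
      if (p > 0) tot <- tot + recurse(c(fs, f), c(ms, m), depth - 1L)
    }
    tot
  }
  recurse(character(), character(), 2L * design$n_females)
}

events_df <- function(fs, ms, replicate = "1") {
  data.frame(replicate = replicate, order = seq_along(fs),
             female_class = fs, male_class = ms, stringsAsFactors = FALSE)
}

# two-sided Fisher p-value by direct hypergeometric enumeration
oracle_fisher_p <- function(m) {
  rs <- rowSums(m); cs <- colSums(m); N <- sum(m)
  xs <- max(0, rs[1] + cs[1] - N):min(rs[1], cs[1])
  probs <- dhyper(xs, cs[1], N - cs[1], rs[1])
  obs <- dhyper(m[1, 1], cs[1], N - cs[1], rs[1])
  sum(probs[probs <= obs * (1 + 1e-7)])
}
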