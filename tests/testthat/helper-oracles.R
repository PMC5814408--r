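# Independent oracles used to pin expected values.

# Exhaustive isotopologue enumeration: for every element, enumerate all
# heavy-isotope count combinations with multinomial probabilities, then
# combine elements by direct polynomial expansion. Independent of the
# package's binary-exponentiation convolution.
oracle_element_dist <- function(n_atoms, abundance, offsets, max_off) {
  dist <- numeric(max_off + 1L)
  heavy <- seq_along(abundance)[-1]
  rec <- function(i, counts) {
    if (i > length(heavy)) {
      off <- sum(counts * offsets[heavy])
      n0 <- n_atoms - sum(counts)
      if (off <= max_off && n0 >= 0) {
        dist[off + 1L] <<- dist[off + 1L] +
          stats::dmultinom(c(n0, counts), prob = abundance)
      }
      return(invisible())
    }
    cap <- min(n_atoms - sum(counts), max_off %/% offsets[heavy[i]])
    for (ci in 0:cap) rec(i + 1L, c(counts, ci))
  }
  rec(1L, integer(0))
  dist
}

oracle_envelope <- function(comp, n_isotopes) {
  max_off <- n_isotopes + 3L
  tab <- dynsilac:::.isotope_table
  dists <- list()
  for (e in names(tab)) {
    n_free <- comp$counts[[e]]
    if (e %in% names(comp$fixed)) n_free <- n_free - comp$fixed[[e]]
    if (n_free <= 0) next
    dists[[e]] <- oracle_element_dist(n_free, tab[[e]]$abundance,
                                      tab[[e]]$offset, max_off)
  }
  total <- c(1, numeric(max_off))
  for (d in dists) {
    new <- numeric(max_off + 1L)
    for (a in 0:max_off) {
      for (b in 0:(max_off - a)) {
        new[a + b + 1L] <- new[a + b + 1L] + total[a + 1L] * d[b + 1L]
      }
    }
    total <- new
  }
  out <- total[seq_len(n_isotopes)]
  out / sum(out)
}

# Exact one-sided rank-sum p-value by exhaustive enumeration of group
# assignments (small samples, no ties).
oracle_ranksum_p_less <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n_a)])
  combos <- utils::combn(length(pooled), n_a)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(w_all <= w_obs)
}

# Direct evaluation of the through-origin decay-rate summation.
oracle_decay_rate <- function(time_h, ratio) {
  num <- 0
  den <- 0
  for (i in seq_along(time_h)) {
    if (!is.na(ratio[i]) && time_h[i] > 0) {
      num <- num + log(ratio[i] + 1) * time_h[i]
      den <- den + time_h[i]^2
    }
  }
  num / den
}

# Brute-force q-values: try every score threshold, FDR = #decoy / #target at
# or above it, take the minimum FDR over thresholds at or below each score.
oracle_picked_q <- function(score, is_decoy) {
  fdr_at <- vapply(score, function(s) {
    sum(is_decoy & score >= s) / max(1, sum(!is_decoy & score >= s))
  }, numeric(1))
  vapply(score, function(s) min(fdr_at[score <= s]), numeric(1))
}
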