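# Independent oracles, kept deliberately naive.

# Direct product-composition oracle for the {1,2} structure: iterate every
# (g, p1, p2) triple and evaluate h = g(p1(x1), p2(x2, x3)) row by row.
oracle_composed_12 <- function() {
  rows <- 0:7
  x1 <- rows %/% 4 %% 2
  x2 <- rows %/% 2 %% 2
  x3 <- rows %% 2
  out <- numeric(0)
  for (g in 0:15) {
    for (p1 in 0:3) {
      for (p2 in 0:15) {
        y1 <- (p1 %/% 2^x1) %% 2
        y2 <- (p2 %/% 2^(2 * x2 + x3)) %% 2
        gi <- 2 * y1 + y2
        out <- c(out, sum(((g %/% 2^gi) %% 2) * 2^rows))
      }
    }
  }
  sort(unique(out))
}

# Direct-summation binomial upper tail.
oracle_binom_tail <- function(M, m_obs, f0) {
  if (m_obs == 0) return(1)
  m <- m_obs:M
  sum(choose(M, m) * f0^m * (1 - f0)^(M - m))
}

# All signed-permutation transforms of a set of bitmask values, one
# transform at a time (used to probe closure properties).
apply_signed_perm <- function(f, perm, negate) {
  g <- bf_permute(f, perm)
  for (v in which(negate == 1)) g <- bf_negate_input(g, v)
  g
}

# peak data frame row helper (0-based half-open, like read_narrowpeak output)
peak_row <- function(chrom, start, end, summit_offset, tf = "TF") {
  data.frame(chrom = chrom, start = start, end = end,
             name = "p", score = 0, strand = ".", signal_value = 1,
             p_value = -1, q_value = -1, summit_offset = summit_offset,
             tf_name = tf)
}

enh_df <- function(id, chrom, start, end) {
  data.frame(enhancer_id = id, chrom = chrom, start = start, end = end)
}

# strip class and attributes from a bf vector for value comparisons
bits <- function(f) as.numeric(unclass(f))
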