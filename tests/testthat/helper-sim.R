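# shared helpers: small deterministic fixtures built in code

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute bases at given 1-based positions (to a different base)
with_subs <- function(seq, pos) {
  s <- strsplit(seq, "")[[1]]
  for (p in pos) s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
  paste(s, collapse = "")
}

# a small, fast simulation configuration (short flanks, 2 kbp locus)
small_config <- function(seed = 1, ...) {
  sim_config(seed = seed,
             locus_length = 2000L,
             flank_length = 1500L,
             exon_layout = data.frame(start = c(100L, 400L, 700L, 1000L, 1600L),
                                      end = c(180L, 480L, 780L, 1080L, 1680L)),
             ...)
}

# full global-DP identity oracle: align whole sequences, no anchoring
full_dp_identity <- function(a, b, gap_compressed = FALSE) {
  al <- nw_align(a, b)
  alignment_identity_oracle(al, gap_compressed)
}

alignment_identity_oracle <- function(al, gap_compressed = FALSE) {
  denom <- if (gap_compressed) {
    ops <- regmatches(al$cigar, gregexpr("[=XID]", al$cigar))[[1]]
    al$matches + al$mismatches + sum(ops %in% c("I", "D"))
  } else {
    al$columns
  }
  100 * al$matches / denom
}

# brute-force two-sided Fisher p-value by hypergeometric enumeration
fisher_p_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
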