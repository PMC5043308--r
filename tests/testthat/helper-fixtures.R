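# small in-code fixtures shared across test files

# minimal valid species table
make_species <- function(n = 6, seed = 42) {
  set.seed(seed)
  logM <- seq(0, 6, length.out = n)
  logB <- log10(0.02) + 0.75 * logM + rnorm(n, 0, 0.1)
  data.frame(
    species_id = sprintf("sp%03d", seq_len(n)),
    genus = sprintf("genus%03d", seq_len(n)),
    body_mass_g = 10^logM,
    metabolic_rate_W = 10^logB,
    mass_specific_rate_Wg = 10^(logB - logM),
    genome_year = 2000L + seq_len(n),
    stringsAsFactors = FALSE
  )
}

# balanced binary Newick with pendant branches `tip_len` and internal
# branches `int_len`; n must be a power of two
balanced_newick <- function(n, tip_len = 1, int_len = 1) {
  labels <- sprintf("sp%03d", seq_len(n))
  build <- function(idx) {
    if (length(idx) == 1L) return(paste0(labels[idx], ":", tip_len))
    half <- length(idx) / 2
    paste0("(", build(idx[seq_len(half)]), ",",
           build(idx[-seq_len(half)]), "):", int_len)
  }
  half <- n / 2
  paste0("(", build(seq_len(half)), ",", build(seq(half + 1, n)), ");")
}

# exhaustive hypergeometric oracle for a 2x2 table [[a,b],[c,d]]
fisher_oracle <- function(a, b, c, d, sided = "two_sided") {
  N <- a + b + c + d
  r1 <- a + b          # first row margin
  c1 <- a + c          # first column margin
  lo <- max(0L, c1 - (N - r1))
  hi <- min(r1, c1)
  xs <- lo:hi
  probs <- stats::dhyper(xs, c1, N - c1, r1)
  p_obs <- stats::dhyper(a, c1, N - c1, r1)
  if (sided == "greater") {
    sum(probs[xs >= a])
  } else {
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
}
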