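# Independent oracles and small fixture builders used across the suite.

# Brute-force motif-position oracle: slide every concrete expansion of
# both orientation patterns over the sequence and flag the mutable slot
# of every hit. Independent of motif_site_flags' vectorised path.
brute_force_flags <- function(sequence, pair) {
  n <- nchar(sequence)
  flags <- logical(n)
  for (orient in list(pair$forward, pair$reverse)) {
    L <- nchar(orient$pattern)
    m <- orient$mutable_index
    for (e in motif_expand(orient$pattern)) {
      if (n < L) next
      for (i in seq_len(n - L + 1L)) {
        if (substr(sequence, i, i + L - 1L) == e) {
          flags[i + m - 1L] <- TRUE
        }
      }
    }
  }
  flags
}

# Closed-form two-sided Fisher p: sum of hypergeometric point
# probabilities not exceeding the observed table's.
fisher_two_sided_oracle <- function(a, b, c, d) {
  m <- a + b      # row 1 total (mutations)
  k <- a + c      # column 1 total (in motif)
  n <- c + d
  x <- 0:min(m, k)
  probs <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

random_dna <- function(n, gc = 0.4) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

# Build a mutation table directly from explicit windows (fixtures with
# hand-countable content). center gives the 1-based mutated offset.
mutations_from_windows <- function(windows, centers,
                                   alt = NULL, chrom = "chr1") {
  ref <- substr(windows, centers, centers)
  if (is.null(alt)) {
    alt <- c(A = "G", C = "T", G = "A", T = "C")[ref]
  }
  data.frame(chrom = chrom,
             pos = seq_along(windows) * 1000L,
             ref = ref, alt = unname(alt), sample_id = "S1",
             neighborhood = windows, center_index = centers,
             win_start = seq_along(windows) * 1000L - centers + 1L,
             stringsAsFactors = FALSE)
}

# Small planted dataset shared by several tests.
small_sim <- function(theta = numeric(), n_mut = 300L, len = 50000L,
                      seed = 11L, flank = 60L) {
  tr <- synthetic_truth(genome_length = len, n_mutations = n_mut,
                        theta = theta, seed = seed)
  sim <- simulate_dataset(tr)
  sim$mutations <- attach_neighborhoods(sim$mutations, sim$reference,
                                        flank = flank)
  sim
}
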