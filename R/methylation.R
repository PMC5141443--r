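# CpG methylation-mutation association: relates methylation ratios to
# motif context (hybrid WRCG vs CpG-control) at mutation positions and
# genome-wide, with read-depth filtering, a resampling mean-comparison
# test and fixed-width histogram binning.

#' Filter methylation sites by read depth
#'
#' Retains positions with strictly more than `min_reads` overlapping
#' reads (default: more than nine, i.e. depth >= 10).
#'
#' @param sites Methylation `data.frame` (see [read_methylation()]).
#' @param min_reads Exclusive lower bound on `total_reads`.
#' @return Filtered `data.frame`.
#' @export
filter_by_depth <- function(sites, min_reads = 9L) {
  sites[sites$total_reads > min_reads, , drop = FALSE]
}

#' Classify CpG sites by motif context
#'
#' Tags each site (`pos` = the forward-strand C of a CpG) as `WRCG` when
#' its CpG sits in a WRCG/CGYW occurrence on either strand, `control`
#' when it is classifiable only as YCG/SNCG context, and `other` when the
#' position is not a CpG in the reference or flanking sequence is
#' unavailable (`other` sites are excluded downstream). When mutations
#' are supplied, a site is flagged `mutated` if a mutation coincides with
#' either base of its CpG.
#'
#' @param sites Methylation `data.frame`.
#' @param reference Named sequences / FASTA path / `DNAStringSet`.
#' @param mutations Optional mutation `data.frame`.
#' @return `sites` with `context` and `mutated` columns appended.
#' @export
classify_context <- function(sites, reference, mutations = NULL) {
  seqs <- .as_reference(reference)
  context <- rep("other", nrow(sites))
  for (chrom in unique(sites$chrom)) {
    if (!chrom %in% names(seqs)) next
    s <- strsplit(seqs[[chrom]], "")[[1]]
    n <- length(s)
    sel <- which(sites$chrom == chrom)
    p <- sites$pos[sel]
    is_cpg <- p >= 1L & p + 1L <= n
    is_cpg[is_cpg] <- s[p[is_cpg]] == "C" & s[p[is_cpg] + 1L] == "G"
    fwd <- rep(NA_character_, length(p))
    ok_f <- is_cpg & p >= 3L
    fwd[ok_f] <- .classify_prefix(s[p[ok_f] - 2L], s[p[ok_f] - 1L])
    rev <- rep(NA_character_, length(p))
    ok_r <- is_cpg & p + 3L <= n
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    rev[ok_r] <- .classify_prefix(comp[s[p[ok_r] + 3L]],
                                  comp[s[p[ok_r] + 2L]])
    ctx <- ifelse(
      !is_cpg, "other",
      ifelse(!is.na(fwd) & fwd == "WRCG" | !is.na(rev) & rev == "WRCG",
             "WRCG",
             ifelse(!is.na(fwd) | !is.na(rev), "control", "other")))
    context[sel] <- ctx
  }
  sites$context <- context
  if (!is.null(mutations)) {
    hit <- unique(paste(mutations$chrom, mutations$pos))
    sites$mutated <- paste(sites$chrom, sites$pos) %in% hit |
      paste(sites$chrom, sites$pos + 1L) %in% hit
  } else {
    sites$mutated <- NA
  }
  sites
}

#' Resampling comparison of group mean methylation ratios
#'
#' Each replicate draws, without replacement, as many values from the
#' larger group as the smaller group holds and computes the sampled mean;
#' the reported probability compares the smaller group's full mean
#' against the sampled means, preserving the group-1-versus-group-2
#' orientation: with group 1 (WRCG context) the smaller, `p = P(M1 >=
#' M2_sampled)`; with group 1 the larger, `p = P(M1_sampled >= M2)`.
#' Ties count toward the probability. On equal sizes the "sample" is the
#' whole larger group, so the test degenerates to a plain mean
#' comparison.
#'
#' The p-value is calibrated (approximately uniform under no group
#' difference) when the sampled pool is much larger than the fixed
#' group, which is the procedure's intended regime; with comparable
#' group sizes the finite-population correction concentrates it towards
#' 0 and 1.
#'
#' @param group1_ratios,group2_ratios Methylation ratios (0--100) of the
#'   two groups; both non-empty.
#' @param reps Number of sampled datasets (default 10000).
#' @param seed RNG seed.
#' @return Object of class `methylation_comparison`: `m1`, `m2`, `n1`,
#'   `n2`, `p_value`, `reps`, and per-group `histogram` (see
#'   [histogram_bins()]).
#' @export
sampling_mean_test <- function(group1_ratios, group2_ratios,
                               reps = 10000L, seed = NULL) {
  stopifnot(length(group1_ratios) > 0L, length(group2_ratios) > 0L,
            reps >= 1L)
  m1 <- mean(group1_ratios)
  m2 <- mean(group2_ratios)
  n1 <- length(group1_ratios)
  n2 <- length(group2_ratios)
  group1_larger <- n1 > n2
  larger <- if (group1_larger) group1_ratios else group2_ratios
  n_small <- min(n1, n2)
  if (!is.null(seed)) set.seed(seed)
  sampled_means <- vapply(seq_len(reps), function(r) {
    mean(larger[sample.int(length(larger), n_small)])
  }, 0)
  p <- if (group1_larger) mean(sampled_means >= m2)
       else mean(m1 >= sampled_means)
  res <- list(
    m1 = m1, m2 = m2, n1 = n1, n2 = n2,
    p_value = p, reps = as.integer(reps),
    histogram = rbind(group1 = histogram_bins(group1_ratios),
                      group2 = histogram_bins(group2_ratios)),
    seed = seed
  )
  class(res) <- "methylation_comparison"
  res
}

#' @export
print.methylation_comparison <- function(x, ...) {
  cat(sprintf(
    "<methylation_comparison> M1 = %.1f (n=%d) vs M2 = %.1f (n=%d); P(M1 >= M2_sampled) = %.4g (%d reps)\n",
    x$m1, x$n1, x$m2, x$n2, x$p_value, x$reps))
  invisible(x)
}

#' Histogram fractions of methylation ratios
#'
#' Five bins of width 20 over the 0--100 ratio scale: `[0,20) [20,40)
#' [40,60) [60,80) [80,100]` (the last bin is closed so a ratio of 100 is
#' counted). Fractions sum to 1.
#'
#' @param ratios Methylation ratios in `[0, 100]`.
#' @return Named numeric vector of per-bin fractions.
#' @export
histogram_bins <- function(ratios) {
  if (any(ratios < 0 | ratios > 100)) stop("ratios must lie in [0, 100]")
  bin <- pmin(findInterval(ratios, c(0, 20, 40, 60, 80)), 5L)
  counts <- tabulate(bin, nbins = 5L)
  out <- counts / length(ratios)
  names(out) <- c("[0,20)", "[20,40)", "[40,60)", "[60,80)", "[80,100]")
  out
}

#' Methylation-motif association analysis
#'
#' Full pipeline stage: depth-filter the sites, classify their motif
#' context against the reference, and run the resampling mean test --
#' both restricted to mutated CpGs (the mutation-position comparison) and
#' on all classified sites (the mutation-agnostic variant).
#'
#' @param sites Methylation `data.frame`.
#' @param reference Reference sequences.
#' @param mutations Mutation `data.frame`.
#' @param reps,seed Passed to [sampling_mean_test()].
#' @param min_reads Depth filter bound (exclusive, default 9).
#' @return List with `mutated` and `all_sites` comparisons (either may be
#'   `NULL` when a group is empty), plus the classified `sites` table.
#' @export
methylation_association <- function(sites, reference, mutations,
                                    reps = 10000L, seed = NULL,
                                    min_reads = 9L) {
  sites <- filter_by_depth(sites, min_reads)
  sites <- classify_context(sites, reference, mutations)
  used <- sites[sites$context != "other", , drop = FALSE]
  run <- function(sub) {
    g1 <- sub$ratio[sub$context == "WRCG"]
    g2 <- sub$ratio[sub$context == "control"]
    if (length(g1) == 0L || length(g2) == 0L) return(NULL)
    sampling_mean_test(g1, g2, reps = reps, seed = seed)
  }
  list(
    mutated = run(used[used$mutated %in% TRUE, , drop = FALSE]),
    all_sites = run(used),
    sites = sites
  )
}
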