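# The Fm/Fn excess statistic: fraction of mutations at a motif's mutable
# position versus the frequency of motif positions among the un-mutated
# bases of the 120 bp DNA neighborhoods, with Fisher exact and Monte Carlo
# significance tests.

#' Excess of mutations in a motif
#'
#' The excess is the ratio `Fm / Fn`, where `Fm` is the fraction of
#' mutations whose mutated base occupies the motif's mutable position and
#' `Fn` is the frequency of motif positions among the un-mutated
#' neighborhood bases.
#'
#' @param fm,fn Fractions in `[0, 1]`; `fn` must be positive.
#' @return The excess ratio.
#' @examples
#' enrichment_excess(0.265, 0.222)  # 1.19 to 2 dp
#' @export
enrichment_excess <- function(fm, fn) {
  stopifnot(all(fm >= 0 & fm <= 1), all(fn > 0 & fn <= 1))
  fm / fn
}

#' Mask CpG dinucleotides in neighborhoods
#'
#' Replaces both bases of every CG dinucleotide in each neighborhood with
#' `N`, so CpG-context positions contribute to neither the mutation counts
#' nor the position totals. Mutations whose own center base becomes masked
#' are dropped.
#'
#' @param mutations Mutations with neighborhoods attached.
#' @return List with `mutations` (masked windows, CpG-centered records
#'   removed) and `n_dropped`.
#' @export
mask_cpg_neighborhoods <- function(mutations) {
  masked <- vapply(seq_len(nrow(mutations)), function(i) {
    s <- strsplit(mutations$neighborhood[i], "")[[1]]
    cg <- which(s[-length(s)] == "C" & s[-1L] == "G")
    if (length(cg) > 0L) s[sort(unique(c(cg, cg + 1L)))] <- "N"
    paste0(s, collapse = "")
  }, "")
  mutations$neighborhood <- masked
  center <- substr(masked, mutations$center_index, mutations$center_index)
  drop <- center == "N"
  list(mutations = mutations[!drop, , drop = FALSE],
       n_dropped = sum(drop))
}

# Per-mutation motif/position bookkeeping shared by the enrichment,
# Monte Carlo and power routines. Returns, per mutation: whether its
# center is a motif position, the count of motif positions among its
# window's other (un-mutated, non-N) bases, that total, and the
# same-ref-base Monte Carlo candidate tallies.
.enrichment_counts <- function(mutations, pair) {
  flags <- motif_flags_windows(mutations$neighborhood, pair)
  n <- nrow(mutations)
  # Monte Carlo candidates are restricted to positions whose motif status
  # is fully evaluable inside the window (enough flanking bases for both
  # orientations): edge positions would be biased towards non-motif and
  # make the reassignment test anti-conservative. The Fn totals keep the
  # whole window (the statistic's published definition).
  L <- nchar(pair$forward$pattern)
  lo <- max(pair$forward$mutable_index, pair$reverse$mutable_index)
  hi_off <- max(L - pair$forward$mutable_index,
                L - pair$reverse$mutable_index)
  center_flag <- logical(n)
  motif_pos <- integer(n)
  total_pos <- integer(n)
  mc_cand <- integer(n)
  mc_cand_motif <- integer(n)
  for (i in seq_len(n)) {
    s <- strsplit(mutations$neighborhood[i], "")[[1]]
    ci <- mutations$center_index[i]
    f <- flags[[i]]
    center_flag[i] <- f[ci]
    live <- s != "N"
    live[ci] <- FALSE
    motif_pos[i] <- sum(f & live)
    total_pos[i] <- sum(live)
    cand <- live & s == mutations$ref[i]
    if (lo > 1L) cand[seq_len(min(lo - 1L, length(s)))] <- FALSE
    if (hi_off > 0L) {
      cand[seq.int(max(1L, length(s) - hi_off + 1L), length(s))] <- FALSE
    }
    mc_cand[i] <- sum(cand)
    mc_cand_motif[i] <- sum(cand & f)
  }
  list(center_flag = center_flag, motif_pos = motif_pos,
       total_pos = total_pos, mc_cand = mc_cand,
       mc_cand_motif = mc_cand_motif)
}

#' Motif enrichment of somatic mutations versus their DNA neighborhood
#'
#' Computes the excess statistic `Fm/Fn` for one motif pair on one mutation
#' set, with a two-sided Fisher exact test on the 2x2 table
#' (mutations in/out of the motif vs un-mutated neighborhood positions
#' in/out of the motif) and an optional one-sided Monte Carlo test (see
#' [monte_carlo_test()]).
#'
#' With `mask_cpg = TRUE`, every base of every CG dinucleotide in each
#' neighborhood is masked to `N` before any counting, and mutations whose
#' center is masked are dropped: this removes CpG hypermutability from both
#' numerator and denominator.
#'
#' @param mutations Mutations with neighborhoods (see
#'   [attach_neighborhoods()]).
#' @param pair A `motif_pair`.
#' @param mask_cpg Mask CpG dinucleotides before counting.
#' @param mc_reps Monte Carlo replicates (0 disables the test).
#' @param seed RNG seed for the Monte Carlo test.
#' @return Object of class `enrichment_result`: a list with `motif_name`,
#'   `n_mutations`, `k_in_motif`, `Fm`, `motif_positions`,
#'   `total_positions`, `Fn`, `excess`, `fisher_p`, `mc_p`, `mc_reps`,
#'   `seed`, `computable`.
#' @export
compute_enrichment <- function(mutations, pair, mask_cpg = FALSE,
                               mc_reps = 1000L, seed = NULL) {
  if (nrow(mutations) == 0L) stop("empty mutation set")
  if (mask_cpg) {
    m <- mask_cpg_neighborhoods(mutations)
    mutations <- m$mutations
    if (nrow(mutations) == 0L) stop("all mutations masked by mask_cpg")
  }
  cnt <- .enrichment_counts(mutations, pair)
  n <- nrow(mutations)
  k <- sum(cnt$center_flag)
  M <- sum(cnt$motif_pos)
  Tt <- sum(cnt$total_pos)
  res <- list(
    motif_name = pair$forward$name,
    n_mutations = n, k_in_motif = k, Fm = k / n,
    motif_positions = M, total_positions = Tt,
    Fn = if (Tt > 0L) M / Tt else NA_real_,
    excess = NA_real_, fisher_p = NA_real_,
    mc_p = NA_real_, mc_reps = as.integer(mc_reps),
    seed = seed, computable = M > 0L && Tt > 0L
  )
  if (res$computable) {
    res$excess <- (k / n) / (M / Tt)
    res$fisher_p <- stats::fisher.test(
      matrix(c(k, n - k, M, Tt - M), nrow = 2L))$p.value
    if (mc_reps > 0L) {
      res$mc_p <- monte_carlo_test(mutations, pair, reps = mc_reps,
                                   seed = seed, counts = cnt)
    }
  }
  class(res) <- "enrichment_result"
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> %s: Fm = %d/%d = %.4f, Fn = %d/%d = %.4f\n",
    x$motif_name, x$k_in_motif, x$n_mutations, x$Fm,
    x$motif_positions, x$total_positions, x$Fn))
  cat(sprintf("  excess = %.3f, Fisher p = %.3g%s\n", x$excess, x$fisher_p,
              if (!is.na(x$mc_p))
                sprintf(", MC p = %.3g (%d reps)", x$mc_p, x$mc_reps)
              else ""))
  invisible(x)
}

#' Monte Carlo test for motif enrichment
#'
#' One-sided permutation test in the direction of enrichment: each
#' replicate reassigns every mutation independently to a uniformly random
#' un-mutated position within its own neighborhood whose reference base
#' equals the mutation's reference base (preserving per-window base
#' composition and the mutation count), then recounts the mutations at
#' motif positions (`k*`). The p-value uses the add-one estimator
#' `p = (1 + #\{k* >= k_obs\}) / (reps + 1)`, so its floor at 999
#' replicates is 0.001. A mutation with no same-base candidate position
#' keeps its original position.
#'
#' Drawing each mutation's candidate uniformly is realized as an
#' independent Bernoulli draw with probability (motif candidates /
#' candidates), which is distributionally identical and replicate-wise
#' exact. With `match_ref_base = FALSE`, candidates are all un-mutated
#' non-N window positions regardless of base identity (non-default
#' variant).
#'
#' @param mutations Mutations with neighborhoods.
#' @param pair A `motif_pair`.
#' @param reps Number of replicates (>= 1).
#' @param seed RNG seed.
#' @param match_ref_base Restrict reassignment to same-reference-base
#'   positions (default).
#' @param counts Internal: precomputed counts.
#' @return One-sided Monte Carlo p-value.
#' @export
monte_carlo_test <- function(mutations, pair, reps = 1000L, seed = NULL,
                             match_ref_base = TRUE, counts = NULL) {
  stopifnot(reps >= 1L)
  cnt <- counts %||% .enrichment_counts(mutations, pair)
  if (!match_ref_base) {
    cnt$mc_cand <- cnt$total_pos
    cnt$mc_cand_motif <- cnt$motif_pos
  }
  k_obs <- sum(cnt$center_flag)
  has_cand <- cnt$mc_cand > 0L
  if (any(!has_cand)) {
    message("monte_carlo_test: ", sum(!has_cand),
            " mutation(s) without same-base candidate keep their position")
  }
  k_fixed <- sum(cnt$center_flag[!has_cand])
  p_i <- cnt$mc_cand_motif[has_cand] / cnt$mc_cand[has_cand]
  if (!is.null(seed)) set.seed(seed)
  m <- length(p_i)
  exceed <- 0L
  # replicate in blocks to bound memory at large n * reps
  block <- max(1L, min(reps, ceiling(2e7 / max(m, 1L))))
  done <- 0L
  while (done < reps) {
    b <- min(block, reps - done)
    if (m > 0L) {
      u <- matrix(stats::runif(b * m), nrow = b)
      kstar <- rowSums(u < matrix(p_i, nrow = b, ncol = m, byrow = TRUE))
    } else {
      kstar <- rep(0L, b)
    }
    exceed <- exceed + sum(kstar + k_fixed >= k_obs)
    done <- done + b
  }
  (1 + exceed) / (reps + 1)
}

#' Run the enrichment analysis over a motif catalog
#'
#' Applies [compute_enrichment()] to each motif of a catalog and flags
#' Bonferroni-corrected significance across the catalog.
#'
#' @param mutations Mutations with neighborhoods.
#' @param catalog Named list of `motif_pair`s (default [motif_catalog()]).
#' @param mask_cpg,mc_reps,seed Passed to [compute_enrichment()].
#' @param alpha Family-wise significance level for the Bonferroni flag.
#' @return `data.frame` with one row per motif: `motif`, `n_mutations`,
#'   `k_in_motif`, `Fm`, `Fn`, `excess`, `fisher_p`, `mc_p`,
#'   `bonferroni_flag`.
#' @export
enrich_catalog <- function(mutations, catalog = motif_catalog(),
                           mask_cpg = FALSE, mc_reps = 1000L, seed = NULL,
                           alpha = 0.05) {
  rows <- lapply(names(catalog), function(nm) {
    r <- compute_enrichment(mutations, catalog[[nm]], mask_cpg = mask_cpg,
                            mc_reps = mc_reps, seed = seed)
    data.frame(motif = nm, n_mutations = r$n_mutations,
               k_in_motif = r$k_in_motif, Fm = r$Fm, Fn = r$Fn,
               excess = r$excess, fisher_p = r$fisher_p, mc_p = r$mc_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bonferroni_flag <- bonferroni(out$fisher_p, alpha = alpha)
  out
}

#' Bonferroni correction flags
#'
#' @param p Vector of p-values forming one test family.
#' @param alpha Family-wise level.
#' @param m Number of tests (defaults to `length(p)`).
#' @return Logical: `p <= alpha / m`.
#' @export
bonferroni <- function(p, alpha = 0.05, m = length(p)) {
  stopifnot(m >= 1L)
  !is.na(p) & p <= alpha / m
}

#' Mutation spectrum summary
#'
#' Tallies the 12 raw substitution types, the 6 strand-symmetric classes
#' (pyrimidine-referenced), transitions/transversions, and mutations at
#' G:C versus A:T pairs.
#'
#' @param mutations Mutation `data.frame` (neighborhoods not required).
#' @return Object of class `spectrum_summary`.
#' @export
spectrum_summary <- function(mutations) {
  stopifnot(nrow(mutations) > 0L)
  raw <- table(factor(paste0(mutations$ref, ">", mutations$alt),
                      levels = c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                                 "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref_n <- ifelse(mutations$ref %in% c("C", "T"), mutations$ref,
                  comp[mutations$ref])
  alt_n <- ifelse(mutations$ref %in% c("C", "T"), mutations$alt,
                  comp[mutations$alt])
  classes <- table(factor(paste0(ref_n, ">", alt_n),
                          levels = c("C>A", "C>G", "C>T",
                                     "T>A", "T>C", "T>G")))
  transitions <- sum(raw[c("A>G", "G>A", "C>T", "T>C")])
  gc <- sum(mutations$ref %in% c("C", "G"))
  res <- list(
    raw_counts = raw, class_counts = classes,
    transitions = transitions,
    transversions = nrow(mutations) - transitions,
    gc = gc, at = nrow(mutations) - gc,
    gc_at_ratio = if (nrow(mutations) - gc > 0) gc / (nrow(mutations) - gc)
      else Inf
  )
  class(res) <- "spectrum_summary"
  res
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat("<spectrum_summary>\n")
  print(x$class_counts)
  cat(sprintf("  transitions %d / transversions %d; G:C %d / A:T %d (ratio %.2f)\n",
              x$transitions, x$transversions, x$gc, x$at, x$gc_at_ratio))
  invisible(x)
}
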