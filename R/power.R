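# Subsampling power procedure: is the absence of motif enrichment in a
# small mutation set explained by its size? Compare its effect size
# (Fm - Fn) against effect sizes of size-matched subsamples of a positive
# (enriched) dataset.

#' Effect size of a motif enrichment result
#'
#' The difference between the fraction of mutations observed in the motif
#' and the frequency of motif positions in the surrounding regions:
#' `Fm - Fn`.
#'
#' @param result An `enrichment_result`, or a list with `Fm` and `Fn`.
#' @return Numeric effect size.
#' @examples
#' effect_size(list(Fm = 0.265, Fn = 0.222))  # 0.043
#' @export
effect_size <- function(result) {
  result$Fm - result$Fn
}

#' Subsampling power analysis
#'
#' Draws `reps` subsamples, without replacement and of the reference
#' dataset's size, from the positive dataset; computes each subsample's
#' effect size `Fm - Fn` (with `Fn` recomputed from that subsample's own
#' neighborhoods); and reports the fraction of subsample effects strictly
#' greater than the reference dataset's effect. A fraction near 1 means
#' size-matched draws from the positive data almost always show a larger
#' effect than the reference data, so the reference's lack of enrichment
#' is unlikely to be a sample-size artifact. Ties count as not exceeding.
#'
#' @param positive_mutations Enriched dataset (with neighborhoods).
#' @param reference_mutations Small dataset under scrutiny (with
#'   neighborhoods); must not be larger than the positive dataset.
#' @param pair A `motif_pair`.
#' @param reps Number of subsamples (default 1000).
#' @param seed RNG seed.
#' @return Object of class `power_result`: `reference_effect`,
#'   `n_subsample`, `reps`, `exceed_fraction`, and the per-replicate
#'   `effects` vector.
#' @export
subsample_power <- function(positive_mutations, reference_mutations, pair,
                            reps = 1000L, seed = NULL) {
  n_sub <- nrow(reference_mutations)
  n_pos <- nrow(positive_mutations)
  if (n_sub > n_pos) {
    stop("reference dataset larger than positive dataset (",
         n_sub, " > ", n_pos, ")")
  }
  ref <- compute_enrichment(reference_mutations, pair, mc_reps = 0L)
  ref_effect <- effect_size(ref)
  cnt <- .enrichment_counts(positive_mutations, pair)
  if (!is.null(seed)) set.seed(seed)
  effects <- vapply(seq_len(reps), function(r) {
    idx <- sample.int(n_pos, n_sub)
    sum(cnt$center_flag[idx]) / n_sub -
      sum(cnt$motif_pos[idx]) / sum(cnt$total_pos[idx])
  }, 0)
  res <- list(reference_effect = ref_effect, n_subsample = n_sub,
              reps = as.integer(reps),
              exceed_fraction = mean(effects > ref_effect),
              effects = effects, seed = seed)
  class(res) <- "power_result"
  res
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "<power_result> reference effect %.4f; %.1f%% of %d size-%d subsamples exceed it\n",
    x$reference_effect, 100 * x$exceed_fraction, x$reps, x$n_subsample))
  invisible(x)
}
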