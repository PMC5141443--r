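# Synthetic data with known ground truth: a first-order-chain reference
# with controlled GC and CpG density, mutations planted with per-motif
# rate multipliers, and CpG methylation tables with planted group means.
# Every analysis stage is verifiable against these planted parameters.

#' Ground-truth parameters for the synthetic generator
#'
#' Defaults describe the simulated study conditions: a 450 kb contig at
#' 42% GC with human-like CpG depletion (observed/expected 0.25, which
#' yields about 3,000 depth-passing CpG sites per motif-context group),
#' 10,000 somatic mutations, and high-methylation CpGs whose mean ratio
#' is 75 in WRCG contexts versus 80 in control CpG contexts (sd 20, mean
#' read depth 30).
#'
#' @param genome_length Contig length (bases).
#' @param gc_content Stationary G+C fraction.
#' @param cpg_enrichment Multiplier on the C-to-G transition probability
#'   relative to independence (1 = independent; < 1 depletes CpGs;
#'   0 removes them).
#' @param theta Named vector of per-motif mutation-rate multipliers at
#'   mutable positions (1 = null). Motifs must be catalog names; effects
#'   of overlapping motifs compose multiplicatively.
#' @param n_mutations Number of mutations to plant.
#' @param transition_bias Probability that the alternate allele is the
#'   transition partner (default 1/3 = uniform over the three
#'   alternates).
#' @param meth_mean_wrcg,meth_mean_control Mean methylation ratio of
#'   WRCG-context vs control-context CpGs.
#' @param meth_sd Site-to-site sd of the latent methylation level.
#' @param meth_depth_mean Mean read depth at CpG sites.
#' @param mutated_wrcg_delta Extra mean depression at mutated WRCG sites.
#' @param seed RNG seed recorded with the truth.
#' @return Object of class `synthetic_truth` (a validated list, JSON
#'   serializable via [write_truth()]).
#' @export
synthetic_truth <- function(genome_length = 450000L, gc_content = 0.42,
                            cpg_enrichment = 0.25, theta = numeric(),
                            n_mutations = 10000L, transition_bias = 1 / 3,
                            meth_mean_wrcg = 75, meth_mean_control = 80,
                            meth_sd = 20, meth_depth_mean = 30,
                            mutated_wrcg_delta = 0, seed = 1L) {
  theta <- unlist(theta)
  if (is.null(theta)) theta <- stats::setNames(numeric(0), character(0))
  stopifnot(genome_length >= 10L, gc_content > 0, gc_content < 1,
            cpg_enrichment >= 0, all(theta > 0),
            n_mutations >= 1L, transition_bias >= 0, transition_bias <= 1,
            meth_mean_wrcg > 0, meth_mean_wrcg < 100,
            meth_mean_control > 0, meth_mean_control < 100, meth_sd > 0,
            meth_depth_mean >= 1)
  if (length(theta) > 0L) stopifnot(!is.null(names(theta)))
  structure(
    list(genome_length = as.integer(genome_length),
         gc_content = gc_content, cpg_enrichment = cpg_enrichment,
         theta = theta, n_mutations = as.integer(n_mutations),
         transition_bias = transition_bias,
         meth_mean_wrcg = meth_mean_wrcg,
         meth_mean_control = meth_mean_control, meth_sd = meth_sd,
         meth_depth_mean = meth_depth_mean,
         mutated_wrcg_delta = mutated_wrcg_delta, seed = as.integer(seed)),
    class = "synthetic_truth")
}

#' Serialize / restore a synthetic truth
#'
#' @param truth A `synthetic_truth`.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$theta <- as.list(truth$theta)  # keep motif names in the JSON object
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(synthetic_truth, x)
}

# Base-transition matrix of the reference chain: rows = current base,
# columns = next base. Next-base distribution is the stationary base
# distribution except that P(G | C) is scaled by cpg_enrichment and the
# row renormalized.
.chain_matrix <- function(truth) {
  p <- c(A = (1 - truth$gc_content) / 2, C = truth$gc_content / 2,
         G = truth$gc_content / 2, T = (1 - truth$gc_content) / 2)
  P <- rbind(A = p, C = p, G = p, T = p)
  P["C", "G"] <- P["C", "G"] * truth$cpg_enrichment
  P["C", ] <- P["C", ] / sum(P["C", ])
  P
}

#' Expected CpG count of the synthetic reference chain
#'
#' Closed form from the chain: `(L - 1) * pi_C * P(G | C)` with `pi` the
#' stationary distribution of the transition matrix (by eigen
#' decomposition). Used as the independent expectation in generator
#' tests.
#'
#' @param truth A `synthetic_truth`.
#' @return Expected number of CG dinucleotides.
#' @export
expected_cpg_count <- function(truth) {
  P <- .chain_matrix(truth)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  pi_st <- Re(e$vectors[, i])
  pi_st <- pi_st / sum(pi_st)
  names(pi_st) <- rownames(P)
  (truth$genome_length - 1) * pi_st["C"] * P["C", "G"]
}

#' Generate a synthetic reference contig
#'
#' First-order Markov chain over `A C G T` with stationary GC content
#' `gc_content` and CpG density scaled by `cpg_enrichment`.
#' Deterministic under the truth's seed.
#'
#' @param truth A `synthetic_truth`.
#' @param contig Contig name (default `"chr1"`).
#' @return Named character vector (one contig) usable wherever a
#'   reference is expected; write with [write_reference_fasta()].
#' @export
generate_reference <- function(truth, contig = "chr1") {
  set.seed(truth$seed)
  P <- .chain_matrix(truth)
  cum <- t(apply(P, 1L, cumsum))
  bases <- c("A", "C", "G", "T")
  L <- truth$genome_length
  u <- stats::runif(L)
  x <- integer(L)
  x[1L] <- findInterval(u[1L], cumsum(c(0, (1 - truth$gc_content) / 2,
                                        truth$gc_content / 2,
                                        truth$gc_content / 2)))
  for (i in 2:L) {
    row <- cum[x[i - 1L], ]
    x[i] <- 1L + (u[i] > row[1L]) + (u[i] > row[2L]) + (u[i] > row[3L])
  }
  out <- paste0(bases[x], collapse = "")
  names(out) <- contig
  out
}

#' Write a reference as FASTA
#'
#' @param reference Named character vector of contig sequences.
#' @param path FASTA path.
#' @export
write_reference_fasta <- function(reference, path) {
  dss <- Biostrings::DNAStringSet(unlist(reference))
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

# Weighted sampling without replacement via exponential keys
# (Efraimidis-Spirakis): equivalent in distribution to successive
# weighted draws, O(n log n) instead of sample.int's O(n * k) with
# probabilities.
.weighted_sample_norepl <- function(weights, k) {
  keys <- stats::rexp(length(weights)) / weights
  order(keys)[seq_len(k)]
}

#' Plant mutations with per-motif rate multipliers
#'
#' Every position's sampling weight is the product of the multipliers of
#' the motifs (from [motif_catalog()]) whose mutable position it occupies
#' on either strand; `n_mutations` positions are drawn without
#' replacement (at most one mutation per site) and given a random
#' alternate allele (transition with probability `transition_bias`,
#' otherwise one of the two transversions).
#'
#' @param reference Named character vector from [generate_reference()].
#' @param truth A `synthetic_truth`.
#' @param catalog Motif catalog resolving `names(truth$theta)`.
#' @param sample_id Sample label for all records.
#' @return Mutation `data.frame` (`chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`), without neighborhoods.
#' @export
generate_mutations <- function(reference, truth,
                               catalog = motif_catalog(),
                               sample_id = "S1") {
  stopifnot(length(reference) == 1L)
  set.seed(truth$seed + 1L)
  s <- strsplit(reference[[1L]], "")[[1]]
  L <- length(s)
  if (truth$n_mutations > L) stop("n_mutations exceeds genome length")
  w <- rep(1, L)
  for (nm in names(truth$theta)) {
    if (truth$theta[[nm]] == 1) next
    if (!nm %in% names(catalog)) stop("theta names unknown motif: ", nm)
    fl <- motif_site_flags(s, catalog[[nm]])
    w[fl] <- w[fl] * truth$theta[[nm]]
  }
  pos <- sort(.weighted_sample_norepl(w, truth$n_mutations))
  ref <- s[pos]
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- list(A = c("C", "T"), G = c("C", "T"),
             C = c("A", "G"), T = c("A", "G"))
  is_ts <- stats::runif(length(pos)) < truth$transition_bias
  alt <- ifelse(is_ts, transition[ref],
                vapply(tv[ref], function(x) x[sample.int(2L, 1L)], ""))
  data.frame(chrom = names(reference)[1L], pos = pos, ref = ref,
             alt = unname(alt), sample_id = sample_id,
             stringsAsFactors = FALSE)
}

# Beta parameters with given mean (0-1) and sd (0-1 scale), truncated to
# keep both shapes positive.
.beta_shapes <- function(mean, sd) {
  v <- min(sd^2, mean * (1 - mean) * 0.95)
  k <- mean * (1 - mean) / v - 1
  c(a = mean * k, b = (1 - mean) * k)
}

#' Generate a per-CpG methylation table with planted group means
#'
#' Every CpG of the reference receives a read depth (1 + Poisson with
#' mean `meth_depth_mean - 1`), a latent methylation level drawn from a
#' Beta with the context-dependent mean (`meth_mean_wrcg` for
#' WRCG-context CpGs, `meth_mean_control` otherwise; mutated WRCG sites
#' additionally depressed by `mutated_wrcg_delta`) and sd `meth_sd`, and
#' binomial methylated-read counts.
#'
#' @param reference Named character vector (one contig).
#' @param truth A `synthetic_truth`.
#' @param mutations Optional mutation `data.frame` used to identify
#'   mutated WRCG sites for the delta depression.
#' @return Methylation `data.frame` (`chrom`, `pos`, `methylated_reads`,
#'   `total_reads`, `ratio`), `pos` being each CpG's forward-strand C.
#' @export
generate_methylation <- function(reference, truth, mutations = NULL) {
  stopifnot(length(reference) == 1L)
  set.seed(truth$seed + 2L)
  s <- strsplit(reference[[1L]], "")[[1]]
  n <- length(s)
  cpg <- which(s[-n] == "C" & s[-1L] == "G")
  if (length(cpg) == 0L) stop("reference contains no CpG")
  sites <- data.frame(chrom = names(reference)[1L], pos = cpg,
                      methylated_reads = 0L, total_reads = 0L,
                      stringsAsFactors = FALSE)
  cls <- classify_context(sites, reference, mutations)
  mean_r <- ifelse(cls$context == "WRCG", truth$meth_mean_wrcg,
                   truth$meth_mean_control)
  if (!is.null(mutations) && truth$mutated_wrcg_delta != 0) {
    dep <- cls$context == "WRCG" & cls$mutated %in% TRUE
    mean_r[dep] <- mean_r[dep] - truth$mutated_wrcg_delta
  }
  depth <- 1L + stats::rpois(length(cpg), truth$meth_depth_mean - 1)
  level <- vapply(mean_r, function(mu) {
    sh <- .beta_shapes(mu / 100, truth$meth_sd / 100)
    stats::rbeta(1L, sh["a"], sh["b"])
  }, 0)
  meth <- stats::rbinom(length(cpg), depth, level)
  sites$methylated_reads <- meth
  sites$total_reads <- depth
  sites$ratio <- 100 * meth / depth
  sites
}

#' Write a mutation table as TSV
#'
#' @param mutations Mutation `data.frame`.
#' @param path TSV path (five columns, no header).
#' @export
write_mutations_tsv <- function(mutations, path) {
  utils::write.table(mutations[c("chrom", "pos", "ref", "alt",
                                 "sample_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a methylation table as TSV
#'
#' @param sites Methylation `data.frame`.
#' @param path TSV path.
#' @export
write_methylation_tsv <- function(sites, path) {
  utils::write.table(sites[c("chrom", "pos", "methylated_reads",
                             "total_reads")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("chrom", "pos", "methylated_reads",
                                   "total_reads"))
  invisible(path)
}

#' Simulate a complete dataset
#'
#' Reference, mutations and methylation table from one truth; optionally
#' writes FASTA/TSV/JSON files to `outdir`.
#'
#' @param truth A `synthetic_truth`.
#' @param outdir Optional output directory.
#' @return List `reference`, `mutations`, `methylation`, `truth`.
#' @export
simulate_dataset <- function(truth, outdir = NULL) {
  reference <- generate_reference(truth)
  mutations <- generate_mutations(reference, truth)
  methylation <- generate_methylation(reference, truth, mutations)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_reference_fasta(reference, file.path(outdir, "reference.fa"))
    write_mutations_tsv(mutations, file.path(outdir, "mutations.tsv"))
    write_methylation_tsv(methylation, file.path(outdir,
                                                 "methylation.tsv"))
    write_truth(truth, file.path(outdir, "truth.json"))
  }
  list(reference = reference, mutations = mutations,
       methylation = methylation, truth = truth)
}
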