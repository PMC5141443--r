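# WRCG-versus-CpG-control contrast: are WRCG/CGYW motif occurrences
# mutated more often than CpG occurrences lacking the WRC context
# (YCG/CGR and SNCG/CGNS)? Separates AID involvement from generic CpG
# hypermutability.

W_BASES <- c("A", "T")
R_BASES <- c("A", "G")

# Classify the two upstream bases of a CpG (on the C's strand):
# WRCG iff prefix in W x R; otherwise control (YCG when the -1 base is a
# pyrimidine, SNCG when the -2 base is S) -- the two classes partition all
# defined NNCG contexts. Returns "WRCG", "control", or NA (undefined base).
.classify_prefix <- function(b2, b1) {
  ok <- b2 %in% c("A", "C", "G", "T") & b1 %in% c("A", "C", "G", "T")
  out <- ifelse(b2 %in% W_BASES & b1 %in% R_BASES, "WRCG", "control")
  out[!ok] <- NA_character_
  out
}

#' Enumerate and classify CpG occurrences
#'
#' Scans the analysis scope -- by default the union of the mutation
#' neighborhoods, deduplicated by genomic coordinate -- for CG
#' dinucleotides with two defined upstream bases, in both orientations
#' (each genomic CpG can yield a forward-strand and a reverse-strand
#' occurrence). Each occurrence is classified `WRCG` (upstream W,R on the
#' C's strand) or `control` (the YCG/SNCG union); the two classes
#' partition all classifiable contexts.
#'
#' @param mutations Mutations with neighborhoods (scope =
#'   neighborhoods), or `NULL` when `reference`+`regions` give the scope.
#' @param reference Named sequences / FASTA path (region mode).
#' @param regions `data.frame` with `chrom`, `start`, `end` (1-based,
#'   closed) delimiting explicit scan regions.
#' @return `data.frame` with one row per deduplicated occurrence:
#'   `chrom`, `cpg_pos` (1-based position of the forward-strand C),
#'   `strand` (`+`/`-`), `mutable_pos` (genomic position of that strand's
#'   C, where a hit counts), `class` (`WRCG`/`control`).
#' @export
enumerate_cpg_occurrences <- function(mutations = NULL, reference = NULL,
                                      regions = NULL) {
  if (!is.null(mutations)) {
    stopifnot(all(c("neighborhood", "win_start") %in% names(mutations)))
    windows <- mutations$neighborhood
    chroms <- mutations$chrom
    starts <- mutations$win_start
  } else {
    stopifnot(!is.null(reference), !is.null(regions))
    seqs <- .as_reference(reference)
    windows <- substring(unlist(seqs)[regions$chrom], regions$start,
                         regions$end)
    chroms <- regions$chrom
    starts <- as.integer(regions$start)
  }
  occ <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    s <- strsplit(windows[i], "")[[1]]
    n <- length(s)
    if (n < 4L) next
    p <- which(s[-n] == "C" & s[-1L] == "G")
    rows <- list()
    fwd <- p[p >= 3L]
    if (length(fwd) > 0L) {
      cls <- .classify_prefix(s[fwd - 2L], s[fwd - 1L])
      keep <- !is.na(cls)
      if (any(keep)) {
        rows[[1L]] <- data.frame(
          chrom = chroms[i], cpg_pos = starts[i] + fwd[keep] - 1L,
          strand = "+", mutable_pos = starts[i] + fwd[keep] - 1L,
          class = cls[keep], stringsAsFactors = FALSE)
      }
    }
    rev <- p[p + 3L <= n]
    if (length(rev) > 0L) {
      # reverse-strand prefix bases are the complements of the +3/+2 bases
      cls <- .classify_prefix(
        c(A = "T", C = "G", G = "C", T = "A", N = "N")[s[rev + 3L]],
        c(A = "T", C = "G", G = "C", T = "A", N = "N")[s[rev + 2L]])
      keep <- !is.na(cls)
      if (any(keep)) {
        rows[[2L]] <- data.frame(
          chrom = chroms[i], cpg_pos = starts[i] + rev[keep] - 1L,
          strand = "-", mutable_pos = starts[i] + rev[keep],
          class = cls[keep], stringsAsFactors = FALSE)
      }
    }
    occ[[i]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, occ)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), cpg_pos = integer(),
                      strand = character(), mutable_pos = integer(),
                      class = character(), stringsAsFactors = FALSE)
  }
  out <- out[!duplicated(out[c("chrom", "cpg_pos", "strand")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contrast mutability of WRCG versus CpG-control occurrences
#'
#' An occurrence is "mutated" when at least one mutation in the dataset
#' hits its mutable position (binary: occurrences, not mutations, are
#' counted). Tests the 2x2 table (mutated/unmutated) x (WRCG/control)
#' with a two-sided Fisher exact test.
#'
#' @param occurrences From [enumerate_cpg_occurrences()].
#' @param mutations Mutation `data.frame` (`chrom`, `pos`).
#' @return Object of class `contrast_result` with counts
#'   `mutated_target`, `total_target`, `mutated_control`,
#'   `total_control`, the two fractions, `fisher_p`, and `computable`.
#' @export
contrast_test <- function(occurrences, mutations) {
  hit_key <- unique(paste(mutations$chrom, mutations$pos))
  mutated <- paste(occurrences$chrom, occurrences$mutable_pos) %in% hit_key
  tgt <- occurrences$class == "WRCG"
  res <- list(
    mutated_target = sum(mutated & tgt), total_target = sum(tgt),
    mutated_control = sum(mutated & !tgt), total_control = sum(!tgt),
    fraction_target = NA_real_, fraction_control = NA_real_,
    fisher_p = NA_real_,
    computable = sum(tgt) > 0L && sum(!tgt) > 0L
  )
  if (res$computable) {
    res$fraction_target <- res$mutated_target / res$total_target
    res$fraction_control <- res$mutated_control / res$total_control
    res$fisher_p <- stats::fisher.test(matrix(
      c(res$mutated_target, res$total_target - res$mutated_target,
        res$mutated_control, res$total_control - res$mutated_control),
      nrow = 2L))$p.value
  }
  class(res) <- "contrast_result"
  res
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf(
    "<contrast_result> WRCG %d/%d (%.4f) vs control %d/%d (%.4f), Fisher p = %.3g\n",
    x$mutated_target, x$total_target, x$fraction_target,
    x$mutated_control, x$total_control, x$fraction_control, x$fisher_p))
  invisible(x)
}
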