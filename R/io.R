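# Readers/writers for mutations, reference sequence, DNA neighborhoods,
# methylation records and result tables. All file and internal coordinates
# are 1-based (VCF/TSV convention).

#' Read somatic single-base substitutions
#'
#' Accepts a five-column TSV (`chrom pos ref alt sample_id`, no header
#' required, `#` comments ignored) or a VCF. Multi-allelic VCF records are
#' split into one row per alternate allele; records that are not
#' single-base substitutions are skipped and counted in the `n_skipped`
#' attribute of the result.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param dedup Drop duplicate (chrom, pos, ref, alt) records shared across
#'   samples before analysis. Default `FALSE`: recurrent mutations are kept.
#' @return `data.frame` with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `sample_id`; attribute `n_skipped` counts rejected records.
#' @export
read_mutations <- function(path, format = c("tsv", "vcf"), dedup = FALSE) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- tryCatch(
      utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
                        colClasses = "character",
                        col.names = c("chrom", "pos", "ref", "alt",
                                      "sample_id")),
      error = function(e) stop("malformed mutation TSV '", path, "': ",
                               conditionMessage(e))
    )
    pos <- suppressWarnings(as.numeric(df$pos))
    if (anyNA(pos)) {
      stop("malformed mutation TSV '", path, "' at line ",
           which(is.na(pos))[1L], ": non-numeric position")
    }
    df$pos <- pos
    muts <- df
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
    sample_id <- if (ncol(vcf@gt) >= 2L) colnames(vcf@gt)[2L] else "sample1"
    alts <- strsplit(fix$ALT, ",", fixed = TRUE)
    reps <- lengths(alts)
    muts <- data.frame(
      chrom = rep(fix$CHROM, reps),
      pos = as.integer(rep(fix$POS, reps)),
      ref = rep(fix$REF, reps),
      alt = unlist(alts),
      sample_id = sample_id,
      stringsAsFactors = FALSE
    )
  }
  muts$ref <- toupper(muts$ref)
  muts$alt <- toupper(muts$alt)
  muts$pos <- as.integer(muts$pos)
  keep <- muts$ref %in% c("A", "C", "G", "T") &
    muts$alt %in% c("A", "C", "G", "T") & muts$ref != muts$alt
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    message("read_mutations: skipped ", n_skipped,
            " non-SNV or malformed allele record(s)")
  }
  muts <- muts[keep, , drop = FALSE]
  if (dedup) {
    muts <- muts[!duplicated(muts[c("chrom", "pos", "ref", "alt")]), ,
                 drop = FALSE]
  }
  rownames(muts) <- NULL
  attr(muts, "n_skipped") <- n_skipped
  muts
}

# Normalize a reference argument to a named list of uppercase sequence
# strings. Accepts a FASTA path, a Biostrings::DNAStringSet, or a named
# character vector/list.
.as_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    dss <- Biostrings::readDNAStringSet(reference)
    seqs <- as.list(toupper(as.character(dss)))
    names(seqs) <- sub("\\s.*$", "", names(dss))
    return(seqs)
  }
  if (methods::is(reference, "DNAStringSet")) {
    seqs <- as.list(toupper(as.character(reference)))
    names(seqs) <- sub("\\s.*$", "", names(reference))
    return(seqs)
  }
  if ((is.character(reference) || is.list(reference)) &&
      !is.null(names(reference))) {
    return(lapply(as.list(reference), toupper))
  }
  stop("reference must be a FASTA path, DNAStringSet, or named sequences")
}

#' Attach DNA neighborhoods to mutations
#'
#' For each mutation, extracts the window of `flank` bases on either side
#' of the mutated base (121 nt at the default `flank = 60`: the 120 bp
#' neighborhood plus the mutated base itself), truncated at contig ends.
#' Alternatively a pre-extracted neighborhood TSV (columns `chrom`, `pos`,
#' `center_index`, `neighborhood`) keyed by (chrom, pos) supplies the
#' windows verbatim.
#'
#' @param mutations Mutation `data.frame` from [read_mutations()].
#' @param reference FASTA path, `DNAStringSet`, or named character vector
#'   of contig sequences.
#' @param neighborhoods Optional path to a neighborhood TSV (used instead
#'   of `reference`).
#' @param flank Bases of context either side of the mutation (default 60).
#' @return The mutation `data.frame` with columns `neighborhood`,
#'   `center_index` (1-based within the window) and `win_start` (1-based
#'   genomic start of the window) appended. Errors if any window's center
#'   base does not equal the recorded `ref` allele.
#' @export
attach_neighborhoods <- function(mutations, reference = NULL,
                                 neighborhoods = NULL, flank = 60L) {
  stopifnot(nrow(mutations) > 0L)
  if (!is.null(neighborhoods)) {
    nb <- utils::read.table(neighborhoods, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "pos", "center_index", "neighborhood")
                  %in% names(nb)))
    key <- paste(mutations$chrom, mutations$pos)
    idx <- match(key, paste(nb$chrom, nb$pos))
    if (anyNA(idx)) {
      stop("neighborhood table missing loci: ",
           paste(utils::head(key[is.na(idx)], 5L), collapse = "; "))
    }
    mutations$neighborhood <- toupper(nb$neighborhood[idx])
    mutations$center_index <- as.integer(nb$center_index[idx])
    mutations$win_start <- mutations$pos - mutations$center_index + 1L
  } else {
    seqs <- .as_reference(reference)
    missing_chrom <- setdiff(unique(mutations$chrom), names(seqs))
    if (length(missing_chrom) > 0L) {
      stop("reference lacks contig(s): ",
           paste(missing_chrom, collapse = ", "))
    }
    clen <- vapply(seqs, nchar, 1L)[mutations$chrom]
    if (any(mutations$pos < 1L | mutations$pos > clen)) {
      stop("mutation position(s) outside contig bounds")
    }
    win_start <- pmax(1L, mutations$pos - as.integer(flank))
    win_end <- pmin(clen, mutations$pos + as.integer(flank))
    contigs <- unlist(seqs)[mutations$chrom]
    mutations$neighborhood <- substring(contigs, win_start, win_end)
    mutations$center_index <- mutations$pos - win_start + 1L
    mutations$win_start <- as.integer(win_start)
  }
  center <- substr(mutations$neighborhood, mutations$center_index,
                   mutations$center_index)
  bad <- which(center != mutations$ref)
  if (length(bad) > 0L) {
    stop("reference base mismatch at: ",
         paste(utils::head(paste0(mutations$chrom[bad], ":",
                                  mutations$pos[bad], " (ref ",
                                  mutations$ref[bad], ", found ",
                                  center[bad], ")"), 5L), collapse = "; "))
  }
  mutations
}

#' Write / read a neighborhood table
#'
#' @param mutations Mutations with neighborhoods attached.
#' @param path Output TSV path.
#' @export
write_neighborhoods <- function(mutations, path) {
  utils::write.table(
    mutations[c("chrom", "pos", "center_index", "neighborhood")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-CpG methylation records
#'
#' TSV columns `chrom pos methylated_reads total_reads` (header optional,
#' detected). The methylation ratio is `100 * methylated / total`, on the
#' 0--100 scale. No depth filtering happens here (see
#' [filter_by_depth()]).
#'
#' @param path Input TSV.
#' @return `data.frame` with columns `chrom`, `pos`, `methylated_reads`,
#'   `total_reads`, `ratio`.
#' @export
read_methylation <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = has_header, sep = "",
                          stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "pos", "methylated_reads", "total_reads")
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  if (any(df$total_reads <= 0L)) stop("total_reads must be positive")
  if (any(df$methylated_reads < 0L)) stop("methylated_reads must be >= 0")
  if (any(df$methylated_reads > df$total_reads)) {
    stop("methylated_reads exceeds total_reads at ",
         sum(df$methylated_reads > df$total_reads), " record(s)")
  }
  df$ratio <- 100 * df$methylated_reads / df$total_reads
  df
}

#' Write / read enrichment result tables
#'
#' Columns: `motif`, `n_mutations`, `k_in_motif`, `Fm`, `Fn`, `excess`,
#' `fisher_p`, `mc_p`, `bonferroni_flag`. Tables round-trip exactly.
#'
#' @param results Result `data.frame` (e.g. from [enrich_catalog()]).
#' @param path TSV path.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Restrict mutations to BED regions
#'
#' Optional region restriction (for example, to 5'UTR intervals). BED is
#' 0-based half-open; mutations are kept when their 1-based position falls
#' in a region.
#'
#' @param mutations Mutation `data.frame`.
#' @param bed_path BED file path.
#' @return Filtered mutation `data.frame`.
#' @export
filter_regions <- function(mutations, bed_path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("filter_regions requires the rtracklayer package")
  }
  gr <- as.data.frame(rtracklayer::import(bed_path, format = "BED"))
  keep <- vapply(seq_len(nrow(mutations)), function(i) {
    any(as.character(gr$seqnames) == mutations$chrom[i] &
          gr$start <= mutations$pos[i] & gr$end >= mutations$pos[i])
  }, TRUE)
  mutations[keep, , drop = FALSE]
}
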