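# Degenerate IUPAC motifs with a designated mutation-prone position,
# matched strand-symmetrically on double-stranded DNA.

# IUPAC code -> set of concrete bases it stands for. The base N in a
# *sequence* never matches anything (masked/unknown), so sets contain only
# concrete bases.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  W = c("A", "T"), S = c("C", "G"),
  M = c("A", "C"), K = c("G", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", W = "W", S = "S",
  M = "K", K = "M", B = "V", V = "B",
  D = "H", H = "D", N = "N"
)

#' Construct a degenerate motif
#'
#' A motif is a short pattern over the IUPAC alphabet with one designated
#' mutation-prone ("mutable") position, e.g. the C of the AID target WRC.
#'
#' @param name Short label, e.g. `"WRC"`.
#' @param pattern Pattern string over the IUPAC alphabet
#'   (`A C G T R Y W S M K B D H V N`).
#' @param mutable_index 1-based offset of the mutable base within `pattern`.
#'   The code at this position must be a concrete base or a 2-fold code
#'   (never `N`): a mutation must be attributable to a specific base class.
#' @return An object of class `degenerate_motif`.
#' @examples
#' degenerate_motif("WRC", "WRC", 3)
#' @export
degenerate_motif <- function(name, pattern, mutable_index) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nchar(pattern) >= 1L)
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0L) {
    stop("invalid IUPAC code(s) in pattern '", pattern, "': ",
         paste(bad, collapse = ", "))
  }
  mutable_index <- as.integer(mutable_index)
  if (mutable_index < 1L || mutable_index > length(chars)) {
    stop("mutable_index out of range for pattern '", pattern, "'")
  }
  deg <- length(IUPAC_SETS[[chars[mutable_index]]])
  if (deg > 2L) {
    stop("mutable position must be a concrete base or a 2-fold code, got '",
         chars[mutable_index], "'")
  }
  structure(
    list(name = name, pattern = toupper(pattern),
         mutable_index = mutable_index, both_strands = TRUE),
    class = "degenerate_motif"
  )
}

#' @export
print.degenerate_motif <- function(x, ...) {
  cat(sprintf("<degenerate_motif> %s: %s (mutable position %d)\n",
              x$name, x$pattern, x$mutable_index))
  invisible(x)
}

#' Expand a degenerate motif to its concrete sequences
#'
#' @param motif A `degenerate_motif` or a pattern string.
#' @return Character vector of all concrete DNA strings matching the
#'   pattern; its length is the product of the code degeneracies.
#' @examples
#' motif_expand("WRC")  # AAC AGC TAC TGC
#' @export
motif_expand <- function(motif) {
  pattern <- if (inherits(motif, "degenerate_motif")) motif$pattern else
    toupper(motif)
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0L) {
    stop("invalid IUPAC code(s): ", paste(bad, collapse = ", "))
  }
  sets <- IUPAC_SETS[chars]
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste0,
             collapse = ""))
}

#' Reverse complement of a degenerate motif
#'
#' Complements each IUPAC code, reverses the pattern, and remaps the
#' mutable position to `length - mutable_index + 1`.
#'
#' @param motif A `degenerate_motif`.
#' @return A `degenerate_motif` written in the reverse orientation.
#' @examples
#' motif_revcomp(degenerate_motif("WRC", "WRC", 3))  # GYW, mutable 1
#' @export
motif_revcomp <- function(motif) {
  stopifnot(inherits(motif, "degenerate_motif"))
  chars <- strsplit(motif$pattern, "")[[1]]
  rc <- paste0(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
  degenerate_motif(paste0("rc(", motif$name, ")"), rc,
                   length(chars) - motif$mutable_index + 1L)
}

#' Pair a motif with its reverse complement
#'
#' Matching on double-stranded DNA is strand-symmetric: a genomic position
#' is a motif position when it sits at the mutable slot of an occurrence of
#' the forward pattern or of its reverse-complement written form. The pair
#' carries both orientations.
#'
#' @param forward A `degenerate_motif` (or pattern string, in which case
#'   `name` and `mutable_index` must be given).
#' @param name,mutable_index Used when `forward` is a plain pattern string.
#' @return An object of class `motif_pair` with elements `forward` and
#'   `reverse`.
#' @export
motif_pair <- function(forward, name = NULL, mutable_index = NULL) {
  if (!inherits(forward, "degenerate_motif")) {
    forward <- degenerate_motif(name %||% forward, forward, mutable_index)
  }
  structure(list(forward = forward, reverse = motif_revcomp(forward)),
            class = "motif_pair")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.motif_pair <- function(x, ...) {
  cat(sprintf("<motif_pair> %s/%s (mutable %d/%d)\n",
              x$forward$pattern, x$reverse$pattern,
              x$forward$mutable_index, x$reverse$mutable_index))
  invisible(x)
}

#' Built-in motif catalog
#'
#' The deaminase/hypermutation motif set analyzed by the package: CpG
#' (`CG`), the APOBEC target `TCW`, the AID targets `WRC` and `WRCH`, the
#' hybrid AID-by-CpG motif `WRCG`, the pol-eta target `WA`, and the two
#' CpG-control motifs `YCG` and `SNCG`. Each entry is a `motif_pair`.
#'
#' Mutable positions: the deaminated C for all C-centred motifs
#' (`TCW` index 2; `WRC`, `WRCH`, `WRCG`, `SNCG` index 3; `YCG` index 2),
#' the A of `WA` (index 2), and for `CG` the C (index 1) -- because CG is
#' palindromic, strand-symmetric matching then flags both bases of every
#' CpG dinucleotide, which is the intended semantics for CpG mutability.
#'
#' @param custom Optional named list of extra/overriding `motif_pair`
#'   objects (e.g. a WRCG variant with the terminal G mutable,
#'   `motif_pair("WRCG", mutable_index = 4)`).
#' @return Named list of `motif_pair` objects.
#' @export
motif_catalog <- function(custom = NULL) {
  cat0 <- list(
    CG   = motif_pair("CG",   mutable_index = 1L),
    TCW  = motif_pair("TCW",  mutable_index = 2L),
    WRC  = motif_pair("WRC",  mutable_index = 3L),
    WRCH = motif_pair("WRCH", mutable_index = 3L),
    WRCG = motif_pair("WRCG", mutable_index = 3L),
    WA   = motif_pair("WA",   mutable_index = 2L),
    YCG  = motif_pair("YCG",  mutable_index = 2L),
    SNCG = motif_pair("SNCG", mutable_index = 3L)
  )
  if (!is.null(custom)) cat0[names(custom)] <- custom
  cat0
}

#' Read / write a motif catalog as TSV
#'
#' Columns: `name`, `pattern`, `mutable_index` (1-based).
#'
#' @param path File path.
#' @return `read_motif_catalog` returns a named list of `motif_pair`s.
#' @export
read_motif_catalog <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("name", "pattern", "mutable_index") %in% names(df)))
  out <- lapply(seq_len(nrow(df)), function(i) {
    motif_pair(df$pattern[i], name = df$name[i],
               mutable_index = df$mutable_index[i])
  })
  names(out) <- df$name
  out
}

#' @param catalog Named list of `motif_pair`s.
#' @rdname read_motif_catalog
#' @export
write_motif_catalog <- function(catalog, path) {
  df <- data.frame(
    name = names(catalog),
    pattern = vapply(catalog, function(p) p$forward$pattern, ""),
    mutable_index = vapply(catalog, function(p) p$forward$mutable_index, 1L)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Flag, for one orientation pattern, the mutable-slot positions of all its
# occurrences in `chars` (character vector of bases). Vectorised sliding
# conjunction over pattern offsets; N in the sequence matches no code.
.flag_one_orientation <- function(chars, pattern, mutable_index) {
  n <- length(chars)
  pchars <- strsplit(pattern, "")[[1]]
  L <- length(pchars)
  flags <- logical(n)
  if (n < L) return(flags)
  nstart <- n - L + 1L
  occ <- rep(TRUE, nstart)
  for (j in seq_len(L)) {
    occ <- occ & (chars[j:(j + nstart - 1L)] %in% IUPAC_SETS[[pchars[j]]])
    if (!any(occ)) return(flags)
  }
  flags[which(occ) + mutable_index - 1L] <- TRUE
  flags
}

#' Flag motif positions along a sequence
#'
#' Returns, for every position of `sequence`, whether that position is the
#' mutable position of an occurrence of the motif pair on either strand
#' (boolean occupancy: a position matching in both orientations counts
#' once). `N` bases match nothing.
#'
#' @param sequence DNA string over `A C G T N` (case-insensitive), or a
#'   character vector of single bases.
#' @param pair A `motif_pair`.
#' @return Logical vector with one element per sequence position.
#' @export
motif_site_flags <- function(sequence, pair) {
  stopifnot(inherits(pair, "motif_pair"))
  chars <- if (length(sequence) == 1L && nchar(sequence[1L]) != 1L)
    strsplit(toupper(sequence), "")[[1]] else toupper(sequence)
  .flag_one_orientation(chars, pair$forward$pattern,
                        pair$forward$mutable_index) |
    .flag_one_orientation(chars, pair$reverse$pattern,
                          pair$reverse$mutable_index)
}

#' Does a position sit at a motif's mutable slot?
#'
#' @param sequence DNA string over `A C G T N`.
#' @param position 1-based position(s) to query.
#' @param pair A `motif_pair`.
#' @return Logical, one element per queried position.
#' @examples
#' matches_at("TACG", 3, motif_catalog()$WRC)  # TRUE: TAC, C mutable
#' @export
matches_at <- function(sequence, position, pair) {
  n <- if (length(sequence) == 1L && nchar(sequence[1L]) != 1L)
    nchar(sequence) else length(sequence)
  position <- as.integer(position)
  if (any(position < 1L | position > n)) {
    stop("position out of range [1, ", n, "]")
  }
  motif_site_flags(sequence, pair)[position]
}

# Flag motif positions in many windows at once by scanning their
# N-separated concatenation (a match cannot span the separator because N
# matches no code). Returns a list of logical vectors.
motif_flags_windows <- function(windows, pair) {
  if (length(windows) == 0L) return(list())
  lens <- nchar(windows)
  joined <- paste(windows, collapse = "N")
  flags <- motif_site_flags(joined, pair)
  starts <- cumsum(c(1L, lens[-length(lens)] + 1L))
  lapply(seq_along(windows), function(i) {
    flags[starts[i]:(starts[i] + lens[i] - 1L)]
  })
}
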