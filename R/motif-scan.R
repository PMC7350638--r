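# IUPAC nucleotide code -> matched subject letters. Subject N is
# matched by pattern N only (conservative: masked subject regions do
# not produce spurious hits from degenerate codes).
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N"))

.checkIupac <- function(pattern) {
  pattern <- toupper(pattern)
  if (nchar(pattern) == 0L) .stopf("empty motif pattern")
  bad <- regexpr(paste0("[^", paste(names(.IUPAC), collapse = ""), "]"),
                 pattern)
  if (bad > 0L)
    .stopf("illegal IUPAC symbol '%s' at position %d of pattern '%s'",
           substr(pattern, bad, bad), as.integer(bad), pattern)
  pattern
}

# Regex character classes implementing .IUPAC, with lookahead so that
# overlapping matches are all reported.
.iupacRegex <- function(pattern) {
  cls <- vapply(.chars(pattern), function(sym) {
    set <- .IUPAC[[sym]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1))
  paste0("(?=", paste(cls, collapse = ""), ")")
}

.forwardStarts <- function(subject, pattern, circular) {
  k <- nchar(pattern)
  L <- nchar(subject)
  ext <- if (circular && k > 1L)
    paste0(subject, substr(subject, 1L, k - 1L)) else subject
  hits <- gregexpr(.iupacRegex(pattern), ext, perl = TRUE)[[1]]
  starts <- as.integer(hits)
  starts <- starts[starts > 0L & starts <= L]
  starts
}

#' Scan a sequence for an IUPAC consensus motif
#'
#' Finds all (including overlapping) occurrences of a degenerate IUPAC
#' pattern. On circular sequences, matches spanning the junction are
#' found and reported exactly once as wrap intervals
#' (\code{end < start}). Subject \code{N} is matched only by pattern
#' \code{N}. With \code{strands = "both"}, minus-strand matches are
#' reported in plus-strand coordinates with \code{strand = "-"} and
#' \code{matched} given as read on the minus strand.
#'
#' @param seq A [CircularSequence-class].
#' @param motif A motif name from [motifRegistry()], or an IUPAC
#'   pattern string, or a one-row registry-style data.frame.
#' @param strands \code{"both"} (default) or \code{"forward"}.
#' @return data.frame with columns \code{motif}, \code{seq_id},
#'   \code{start}, \code{end}, \code{strand}, \code{matched}, sorted
#'   by start with \code{+} before \code{-} at ties.
#' @examples
#' s <- circularSequence("x", "GGAATAAAGG")
#' scanMotif(s, "AATAAA", strands = "forward")$start  # 3
#' @export
scanMotif <- function(seq, motif, strands = c("both", "forward")) {
  stopifnot(is(seq, "CircularSequence"))
  strands <- match.arg(strands)
  if (is.data.frame(motif)) {
    name <- motif$name[1]; pattern <- motif$pattern[1]
  } else {
    reg <- motifRegistry()
    i <- match(motif, reg$name)
    if (!is.na(i)) {
      name <- reg$name[i]; pattern <- reg$pattern[i]
    } else {
      name <- motif; pattern <- motif
    }
  }
  pattern <- .checkIupac(pattern)
  k <- nchar(pattern)
  L <- length(seq)
  if (k > L) .stopf("pattern length %d exceeds sequence length %d", k, L)
  circ <- isCircular(seq)
  res <- residues(seq)
  fwd <- .forwardStarts(res, pattern, circ)
  out <- list()
  if (length(fwd)) {
    ends <- if (circ) .wrap1(fwd + k - 1L, L) else fwd + k - 1L
    out[["+"]] <- data.frame(
      motif = name, seq_id = seqId(seq), start = fwd, end = ends,
      strand = "+",
      matched = vapply(seq_along(fwd), function(i)
        .sliceWrap(res, fwd[i], ends[i], L), character(1)),
      stringsAsFactors = FALSE)
  }
  if (strands == "both") {
    rc <- revComp(res)
    rstarts <- .forwardStarts(rc, pattern, circ)
    if (length(rstarts)) {
      # a match at q..q+k-1 on the reverse strand covers plus-strand
      # positions (L - q - k + 2) .. (L - q + 1)
      ends <- .wrap1(L - rstarts + 1L, L)
      starts <- .wrap1(L - rstarts - k + 2L, L)
      out[["-"]] <- data.frame(
        motif = name, seq_id = seqId(seq), start = starts, end = ends,
        strand = "-",
        matched = vapply(seq_along(starts), function(i)
          revComp(.sliceWrap(res, starts[i], ends[i], L)), character(1)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(motif = character(), seq_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), matched = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Bundled consensus motif registry
#'
#' Loads the motif registry shipped with the package: the 17 bp
#' extended ARS consensus sequence (EACS), the 11 bp ACS core, and the
#' AATAAA hexamer common to the replicon's DNA unwinding elements.
#' Each entry carries its source citation. All patterns are validated
#' as IUPAC at load.
#'
#' @return data.frame with columns \code{name}, \code{pattern},
#'   \code{source}.
#' @export
motifRegistry <- function() {
  path <- system.file("extdata", "motifs.tsv", package = "oriScan")
  if (!nzchar(path)) .stopf("bundled motif registry not found")
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("name", "pattern", "source") %in% names(df)) ||
      nrow(df) < 1L)
    .stopf("malformed motif registry data file: %s", path)
  df$pattern <- vapply(df$pattern, .checkIupac, character(1),
                       USE.NAMES = FALSE)
  df
}

#' Export motif matches as BED
#'
#' @param matches Output of [scanMotif()].
#' @param path Output path.
#' @param seq_length Sequence length (needed for wrap matches).
#' @return \code{path}, invisibly.
#' @export
matchesToBed <- function(matches, path, seq_length = NULL) {
  iv <- data.frame(seq_id = matches$seq_id, start = matches$start,
                   end = matches$end, label = matches$motif,
                   score = 0, strand = matches$strand,
                   stringsAsFactors = FALSE)
  writeBed(iv, path, seq_length = seq_length)
}
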