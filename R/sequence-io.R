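#' Construct a CircularSequence
#'
#' Normalizes case, validates the alphabet and wraps the sequence with
#' its identifier and topology flag.
#'
#' @param id Sequence identifier.
#' @param residues DNA string over A/C/G/T/N (case-insensitive).
#' @param circular Logical, circular topology (default \code{FALSE}).
#' @return A [CircularSequence-class] object.
#' @examples
#' circularSequence("x", "acgt", circular = TRUE)
#' @export
circularSequence <- function(id, residues, circular = FALSE) {
  res <- toupper(as.character(residues))
  bad <- regexpr("[^ACGTN]", res)
  if (bad > 0L)
    .stopf("record '%s': illegal residue '%s' at offset %d",
           id, substr(res, bad, bad), as.integer(bad))
  new("CircularSequence", id = as.character(id), residues = res,
      circular = isTRUE(circular))
}

#' Read DNA sequences from a FASTA file
#'
#' Reads one [CircularSequence-class] per FASTA record. Lowercase is
#' normalized to uppercase; residues outside A/C/G/T/N raise an error
#' naming the record and offset. The topology flag is taken from a
#' \code{circular=true} / \code{circular=false} token on the
#' description line when present, otherwise from \code{circular}.
#'
#' @param path Path to a FASTA file.
#' @param circular Default topology for records without a token.
#' @return A list of [CircularSequence-class] objects in file order.
#' @seealso [writeFasta()]
#' @export
readFasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) .stopf("FASTA file '%s' contains no records", path)
  lapply(seq_along(set), function(i) {
    desc <- names(set)[i]
    id <- sub("\\s.*$", "", desc)
    circ <- circular
    if (grepl("circular=true", desc, ignore.case = TRUE)) circ <- TRUE
    if (grepl("circular=false", desc, ignore.case = TRUE)) circ <- FALSE
    circularSequence(id, as.character(set[[i]]), circ)
  })
}

#' Write sequences to a FASTA file
#'
#' The topology is recorded as a \code{circular=true|false} token on
#' the description line so that [readFasta()] round-trips it.
#'
#' @param seqs A [CircularSequence-class] or list of them.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (is(seqs, "CircularSequence")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, residues, character(1)))
  names(set) <- vapply(seqs, function(s) {
    sprintf("%s circular=%s", seqId(s), tolower(isCircular(s)))
  }, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Extract a region from a sequence
#'
#' Coordinates are 1-based inclusive. On circular sequences
#' \code{end < start} denotes a region wrapping across the junction,
#' with length \code{L - start + 1 + end}; on linear sequences a wrap
#' is an error.
#'
#' @param seq A [CircularSequence-class].
#' @param start,end 1-based inclusive coordinates in \code{[1, L]}.
#' @return The region as a character string.
#' @examples
#' s <- circularSequence("x", "ACGT", circular = TRUE)
#' extractRegion(s, 2, 3)  # "CG"
#' extractRegion(s, 4, 1)  # "TA" (wraps the junction)
#' @export
extractRegion <- function(seq, start, end) {
  stopifnot(is(seq, "CircularSequence"))
  L <- length(seq)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > L ||
      end < 1L || end > L)
    .stopf("coordinates (%s, %s) outside [1, %d]", start, end, L)
  if (end < start && !isCircular(seq))
    .stopf("wrap region (%d..%d) requested on linear sequence '%s'",
           start, end, seqId(seq))
  .sliceWrap(residues(seq), start, end, L)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' @param s DNA string over A/C/G/T/N (case-insensitive).
#' @return The reverse complement, uppercase. \code{N} maps to
#'   \code{N}; the empty string maps to itself.
#' @examples
#' revComp("AATAAA")  # "TTTATT"
#' @export
revComp <- function(s) {
  s <- toupper(as.character(s))
  if (nchar(s) == 0L) return(s)
  if (grepl("[^ACGTN]", s))
    .stopf("illegal residue in '%s'", substr(s, 1, 30))
  ch <- .COMPLEMENT[rev(.chars(s))]
  paste(ch, collapse = "")
}

#' Write intervals as BED
#'
#' Converts the package's 1-based inclusive intervals to standard BED
#' (0-based half-open, 6 columns). An interval wrapping the circular
#' junction (\code{end < start}) is emitted as two lines whose names
#' carry \code{|wrap5} and \code{|wrap3} suffixes; the convention is
#' documented in a leading comment so that [readBed()] can reassemble
#' the interval.
#'
#' @param intervals data.frame with columns \code{seq_id},
#'   \code{start}, \code{end} and optionally \code{label},
#'   \code{score}, \code{strand}.
#' @param path Output path.
#' @param seq_length Sequence length, required to emit wrap intervals.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(intervals, path, seq_length = NULL) {
  stopifnot(is.data.frame(intervals),
            all(c("seq_id", "start", "end") %in% names(intervals)))
  lab <- if ("label" %in% names(intervals)) intervals$label else
    paste0("iv", seq_len(nrow(intervals)))
  score <- if ("score" %in% names(intervals)) intervals$score else 0
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# BED 0-based half-open; produced from 1-based inclusive intervals.",
    "# A circular wrap interval is split into two lines named NAME|wrap5",
    "# (origin-proximal part starting at 0) and NAME|wrap3 (end part)."),
    con)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    if (e >= s) {
      writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", intervals$seq_id[i],
                         s - 1L, e, lab[i], score[i], strand[i]), con)
    } else {
      if (is.null(seq_length))
        .stopf("wrap interval %d..%d needs seq_length", s, e)
      writeLines(sprintf("%s\t%d\t%d\t%s|wrap3\t%s\t%s",
                         intervals$seq_id[i], s - 1L, seq_length,
                         lab[i], score[i], strand[i]), con)
      writeLines(sprintf("%s\t%d\t%d\t%s|wrap5\t%s\t%s",
                         intervals$seq_id[i], 0L, e, lab[i],
                         score[i], strand[i]), con)
    }
  }
  invisible(path)
}

#' Read a BED file written by [writeBed()]
#'
#' Restores 1-based inclusive intervals, reassembling wrap intervals
#' from their \code{|wrap5}/\code{|wrap3} line pairs.
#'
#' @param path Path to a BED file.
#' @return data.frame with columns \code{seq_id}, \code{start},
#'   \code{end}, \code{label}, \code{score}, \code{strand}.
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), label = character(),
                      score = numeric(), strand = character()))
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  df <- data.frame(seq_id = f[, 1], start = as.integer(f[, 2]) + 1L,
                   end = as.integer(f[, 3]),
                   label = if (ncol(f) >= 4) f[, 4] else "",
                   score = if (ncol(f) >= 5) as.numeric(f[, 5]) else 0,
                   strand = if (ncol(f) >= 6) f[, 6] else ".",
                   stringsAsFactors = FALSE)
  is3 <- grepl("\\|wrap3$", df$label)
  is5 <- grepl("\\|wrap5$", df$label)
  if (any(is3)) {
    base3 <- sub("\\|wrap3$", "", df$label[is3])
    base5 <- sub("\\|wrap5$", "", df$label[is5])
    m <- match(base3, base5)
    out3 <- df[is3, , drop = FALSE]
    out5 <- df[is5, , drop = FALSE][m, , drop = FALSE]
    merged <- out3
    merged$end <- out5$end
    merged$label <- base3
    df <- rbind(df[!(is3 | is5), , drop = FALSE], merged)
    df <- df[order(df$seq_id, df$start), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}
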