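#' Load the bundled nearest-neighbor free-energy table
#'
#' @return A [ThermoTable-class] with the unified dinucleotide
#'   deltaG(37C) values (kcal/mol) and initiation terms.
#' @export
thermoTable <- function() {
  path <- system.file("extdata", "nn_deltaG.csv", package = "oriScan")
  if (!nzchar(path)) .stopf("bundled thermodynamic table not found")
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  if (!all(c("dinucleotide", "deltaG") %in% names(df)))
    .stopf("malformed thermodynamic data file: %s", path)
  g <- stats::setNames(df$deltaG, df$dinucleotide)
  init <- g[startsWith(names(g), "init_")]
  g <- g[!startsWith(names(g), "init_")]
  if (!all(.DINUCS %in% names(g)))
    .stopf("thermodynamic table is missing dinucleotides")
  new("ThermoTable", deltaG = g[.DINUCS], initiation = init,
      source = "unified nearest-neighbor set (SantaLucia 1998)")
}

# Per-base A/T indicator (N and gaps count as non-AT).
.atIndicator <- function(seq) {
  ch <- .chars(residues(seq))
  as.numeric(ch == "A" | ch == "T")
}

# Maximal-scoring contiguous subsegment of (x - min_at); returns
# c(start, end) offsets within x (leftmost maximal segment), or NULL
# if every subsegment scores <= 0.
.maxScoringSegment <- function(x, min_at) {
  s <- x - min_at
  best <- 0; bs <- NA_integer_; be <- NA_integer_
  cur <- 0; cs <- 1L
  for (i in seq_along(s)) {
    if (cur <= 0) { cur <- 0; cs <- i }
    cur <- cur + s[i]
    if (cur > best + 1e-12) { best <- cur; bs <- cs; be <- i }
  }
  if (is.na(bs)) NULL else c(bs, be)
}

#' Find A+T-rich segments (DUE candidates)
#'
#' Deterministic detector for DNA-unwinding-element candidates:
#' \enumerate{
#'   \item mark every \code{min_len}-bp window (step 1, wrapping on
#'     circular sequences) whose A+T fraction is at least
#'     \code{min_at};
#'   \item merge overlapping/adjacent marked windows into maximal
#'     regions;
#'   \item recursively split any region longer than \code{max_len} at
#'     its lowest-A+T valley (centered \code{min_len}-bp smoothed A+T,
#'     split points constrained so both pieces keep at least
#'     \code{min_len} bp where possible; ties go to the leftmost
#'     position);
#'   \item trim each piece to its leftmost maximal-scoring subsegment
#'     under the per-base score \code{[base is A or T] - min_at}, so
#'     reported boundaries hug the A+T-rich core rather than the
#'     marked-window envelope; pieces shorter than \code{min_len}
#'     after trimming are re-expanded to \code{min_len} within the
#'     piece;
#'   \item report pieces of length \code{min_len..max_len} whose
#'     realized A+T fraction is at least \code{min_at}, sorted by
#'     start.
#' }
#' N residues count as non-A+T.
#'
#' @param seq A [CircularSequence-class].
#' @param min_len,max_len Length band in bp (defaults 30 and 100, the
#'   canonical DUE size range).
#' @param min_at Minimum A+T fraction (default 0.60, just below the
#'   weakest reported replicon DUE at 0.62).
#' @return data.frame with columns \code{seq_id}, \code{start},
#'   \code{end}, \code{length}, \code{at_fraction}. Wrap segments on
#'   circular sequences have \code{end < start}.
#' @seealso [annotateDUE()], [instabilityProfile()]
#' @export
findATRichSegments <- function(seq, min_len = 30, max_len = 100,
                               min_at = 0.60) {
  stopifnot(is(seq, "CircularSequence"))
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  L <- length(seq)
  if (min_at <= 0 || min_at > 1) .stopf("min_at must be in (0, 1]")
  if (min_len > max_len || max_len > L)
    .stopf("need min_len <= max_len <= sequence length")
  x <- .atIndicator(seq)
  circ <- isCircular(seq)
  xe <- if (circ) c(x, x[seq_len(min_len - 1L)]) else x
  roll <- .rollsum(xe, min_len)
  starts <- which(roll / min_len >= min_at - 1e-12)
  if (!circ) starts <- starts[starts <= L - min_len + 1L]
  empty <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      at_fraction = numeric())
  if (!length(starts)) return(empty)
  # union of marked windows via a difference array on [1, L] (wrapped)
  d <- integer(L + 1L)
  for (s in starts) {
    e <- s + min_len - 1L
    if (e <= L) {
      d[s] <- d[s] + 1L; d[e + 1L] <- d[e + 1L] - 1L
    } else {
      d[s] <- d[s] + 1L
      d[1L] <- d[1L] + 1L; d[e - L + 1L] <- d[e - L + 1L] - 1L
    }
  }
  covered <- cumsum(d[seq_len(L)]) > 0L
  r <- rle(covered)
  ends2 <- cumsum(r$lengths)
  starts2 <- ends2 - r$lengths + 1L
  regions <- cbind(starts2[r$values], ends2[r$values])
  # merge a run touching both ends of a circular sequence into a wrap
  wrapped <- FALSE
  if (circ && nrow(regions) > 1L && regions[1, 1] == 1L &&
      regions[nrow(regions), 2] == L) {
    regions[1, 1] <- regions[nrow(regions), 1]
    regions <- regions[-nrow(regions), , drop = FALSE]
    wrapped <- TRUE
  }
  # valley score: centered min_len-bp smoothed A+T over the sequence
  h <- min_len %/% 2L
  sm_w <- 2L * h + 1L
  xs <- if (circ) c(x[(L - h + 1L):L], x, x[seq_len(h)]) else
    c(rep(NA, h), x, rep(NA, h))
  sm <- .rollsum(ifelse(is.na(xs), 0, xs), sm_w) /
    .rollsum(as.numeric(!is.na(xs)), sm_w)
  pieces <- list()
  splitRegion <- function(s, e) {  # s<=e in unwrapped coords (may exceed L)
    len <- e - s + 1L
    if (len <= max_len) {
      pieces[[length(pieces) + 1L]] <<- c(s, e)
      return(invisible())
    }
    offs <- if (len >= 2L * min_len) seq.int(min_len, len - min_len) else
      seq.int(1L, len - 1L)
    pos <- .wrap1(s + offs - 1L, L)
    v <- sm[pos]
    p <- offs[which.min(v)]  # which.min is leftmost on ties
    splitRegion(s, s + p - 1L)
    splitRegion(s + p, e)
  }
  for (i in seq_len(nrow(regions))) {
    s <- regions[i, 1]; e <- regions[i, 2]
    if (wrapped && i == 1L && s > e) e <- e + L  # unwrap
    splitRegion(s, e)
  }
  out <- list()
  for (p in pieces) {
    idx <- .wrap1(seq.int(p[1], p[2]), L)
    seg <- .maxScoringSegment(x[idx], min_at)
    if (is.null(seg)) next
    if (seg[2] - seg[1] + 1L < min_len) {
      # re-expand the trimmed core to min_len within the piece
      need <- min_len - (seg[2] - seg[1] + 1L)
      lo <- max(1L, seg[1] - need %/% 2L)
      hi <- min(length(idx), lo + min_len - 1L)
      lo <- max(1L, hi - min_len + 1L)
      seg <- c(lo, hi)
    }
    if (seg[2] - seg[1] + 1L < min_len) next
    at <- mean(x[idx[seg[1]:seg[2]]])
    if (at < min_at - 1e-12) next
    out[[length(out) + 1L]] <- data.frame(
      seq_id = seqId(seq), start = idx[seg[1]], end = idx[seg[2]],
      length = seg[2] - seg[1] + 1L, at_fraction = at,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  df <- do.call(rbind, out)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Helical instability profile
#'
#' Per-position helical instability: the sum of nearest-neighbor
#' duplex deltaG over the \code{window}-bp window centered at each
#' position (kcal/mol; higher, i.e. less negative, means more easily
#' unwound). Wraps on circular sequences; \code{NA} near the ends of
#' linear sequences. Steps containing N score \code{NA} and propagate.
#'
#' @param seq A [CircularSequence-class].
#' @param window Window size in bp (default 41, the scale of the
#'   reported DUEs).
#' @param table A [ThermoTable-class] (default: bundled unified set).
#' @return Numeric vector of length \code{length(seq)}.
#' @export
instabilityProfile <- function(seq, window = 41, table = thermoTable()) {
  stopifnot(is(seq, "CircularSequence"), is(table, "ThermoTable"))
  window <- as.integer(window)
  L <- length(seq)
  if (window > L) .stopf("window (%d) exceeds sequence length", window)
  ch <- .chars(residues(seq))
  circ <- isCircular(seq)
  che <- if (circ) c(ch, ch[1L]) else ch
  steps <- paste0(che[-length(che)], che[-1L])
  g <- unname(table@deltaG[steps])  # NA for steps containing N
  h <- window %/% 2L
  nstep <- window - 1L  # steps spanned by a window of `window` bases
  ge <- if (circ) c(g, g[seq_len(max(0L, nstep - 1L))]) else g
  rs <- .rollsum(ge, nstep)
  out <- rep(NA_real_, L)
  # window centered at i covers bases (i-h)..(i-h+window-1),
  # i.e. steps starting at i-h
  if (circ) {
    out[] <- rs[.wrap1(seq_len(L) - h, L)]
  } else {
    i <- (h + 1L):(L - (window - h - 1L))
    out[i] <- rs[i - h]
  }
  out
}

#' Annotate a DUE candidate segment
#'
#' Fills the reported attributes of a DUE call: observed A+T fraction,
#' helical-instability score (sum of nearest-neighbor deltaG over the
#' segment's internal steps), presence of AATAAA on either strand, and
#' the shorter-arc edge-to-edge distance to the nearest ACS/EACS
#' match (\code{NA} when no matches are supplied).
#'
#' @param segment One-row data.frame with \code{start}, \code{end}
#'   (1-based inclusive; \code{end < start} wraps on circular input).
#' @param seq A [CircularSequence-class].
#' @param acs_matches Optional [scanMotif()] output for the ACS/EACS.
#' @param table A [ThermoTable-class].
#' @return One-row data.frame: \code{seq_id}, \code{start},
#'   \code{end}, \code{length}, \code{at_fraction},
#'   \code{instability}, \code{has_aataaa}, \code{dist_to_nearest_acs}.
#' @export
annotateDUE <- function(segment, seq, acs_matches = NULL,
                        table = thermoTable()) {
  stopifnot(is(seq, "CircularSequence"))
  L <- length(seq)
  s <- as.integer(segment$start[1]); e <- as.integer(segment$end[1])
  dna <- extractRegion(seq, s, e)
  ch <- .chars(dna)
  len <- length(ch)
  at <- mean(ch == "A" | ch == "T")
  steps <- paste0(ch[-len], ch[-1L])
  instab <- sum(table@deltaG[steps])
  has <- grepl("AATAAA", dna, fixed = TRUE) ||
    grepl("TTTATT", dna, fixed = TRUE)
  dist <- NA_real_
  if (!is.null(acs_matches) && nrow(acs_matches) > 0L) {
    dist <- min(vapply(seq_len(nrow(acs_matches)), function(i)
      .edgeDistance(s, e, acs_matches$start[i], acs_matches$end[i], L,
                    circular = isCircular(seq)), numeric(1)))
  }
  data.frame(seq_id = seqId(seq), start = s, end = e, length = len,
             at_fraction = at, instability = unname(instab),
             has_aataaa = has, dist_to_nearest_acs = dist,
             stringsAsFactors = FALSE)
}
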