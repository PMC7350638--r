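#' Build an origin-caller configuration
#'
#' Defaults: association distance 250 bp (on the scale of the 256 bp
#' locus holding the EACS and both DUEs), report window 256 bp,
#' composite-score weights 0.4/0.3/0.2/0.1 for the EACS match, the
#' DUE count, the local A+T enrichment and the bend term.
#'
#' @param assoc_distance Maximum edge-to-edge distance (bp) for a DUE
#'   to be associated with an EACS match.
#' @param report_window Report window size in bp.
#' @param weights Named numeric (\code{acs}, \code{due}, \code{at},
#'   \code{bend}); nonnegative, summing to 1.
#' @param due List overriding DUE-detector defaults (\code{min_len},
#'   \code{max_len}, \code{min_at}).
#' @param curvature List overriding curvature defaults
#'   (\code{params}, \code{half_window}, \code{quantile},
#'   \code{reference}).
#' @return A [CallerConfig-class].
#' @export
callerConfig <- function(assoc_distance = 250, report_window = 256,
                         weights = c(acs = 0.4, due = 0.3, at = 0.2,
                                     bend = 0.1),
                         due = list(), curvature = list()) {
  d <- utils::modifyList(list(min_len = 30L, max_len = 100L,
                              min_at = 0.60), due)
  cv <- utils::modifyList(list(params = "atract", half_window = 7L,
                               quantile = 0.95, reference = 1 / 42.8),
                          curvature)
  new("CallerConfig", assoc_distance = as.integer(assoc_distance),
      report_window = as.integer(report_window), weights = weights,
      due = d, curvature = cv)
}

.clamp01 <- function(x) pmin(1, pmax(0, x))

# Composite candidate score; monotone non-decreasing in n_dues, at50
# and bend_norm by construction.
.originScore <- function(w, n_dues, at50, bend_norm) {
  unname(w["acs"] +
         w["due"] * min(1, n_dues / 2) +
         w["at"] * .clamp01((at50 - 0.5) / 0.3) +
         w["bend"] * .clamp01(if (is.na(bend_norm)) 0 else bend_norm))
}

# 50 bp A+T fraction centered on the midpoint of a (possibly
# wrapping) interval.
.centeredAT <- function(seq, start, end, width = 50L) {
  L <- length(seq)
  w <- .intervalWidth(start, end, L)
  mid <- .wrap1(start + (w - 1L) %/% 2L, L)
  ws <- mid - (width - 1L) %/% 2L
  we <- ws + width - 1L
  if (!isCircular(seq)) {
    ws <- max(1L, ws); we <- min(L, ws + width - 1L)
    ws <- max(1L, we - width + 1L)
  }
  dna <- .sliceWrap(residues(seq), .wrap1(ws, L), .wrap1(we, L), L)
  ch <- .chars(dna)
  called <- ch != "N"
  if (!any(called)) return(NA_real_)
  sum(ch == "A" | ch == "T") / sum(called)
}

#' Call replication-origin candidates
#'
#' Integrates the signals the replicon analysis rests on: one
#' candidate per EACS consensus match, annotated with the A+T-rich
#' DUE candidates within the association distance, the A+T fraction
#' of the 50 bp window centered on the EACS, and the wedge-model bend
#' structure of the report window. The composite score is
#' \deqn{w_{acs} + w_{due}\min(1, n_{DUE}/2) +
#'       w_{at}\,\mathrm{clamp}((AT_{50} - 0.5)/0.3) +
#'       w_{bend}\,\mathrm{clamp}(\bar\kappa/\kappa_{ref})}
#' and orders candidates deterministically (descending score, ties to
#' the leftmost EACS).
#'
#' The report window is centered on the joint span of the EACS and
#' its associated DUEs (so that, as on the replicon, a 256 bp window
#' holds the EACS and both upstream DUEs); when that span exceeds the
#' window, it is centered on the EACS instead.
#'
#' @param seq A [CircularSequence-class].
#' @param config A [CallerConfig-class].
#' @param motif Motif name scanned for the ACS signal (default
#'   \code{"EACS"}).
#' @param dues Optional precomputed [findATRichSegments()] output;
#'   computed from \code{seq} when \code{NULL}.
#' @return List of [OriginCandidate-class], sorted by score; empty
#'   when the sequence has no EACS match.
#' @seealso [regionReport()], [callerConfig()]
#' @export
callOrigins <- function(seq, config = callerConfig(), motif = "EACS",
                        dues = NULL) {
  stopifnot(is(seq, "CircularSequence"), is(config, "CallerConfig"))
  L <- length(seq)
  matches <- scanMotif(seq, motif, strands = "both")
  if (nrow(matches) == 0L) return(list())
  if (is.null(dues))
    dues <- findATRichSegments(seq, min_len = config@due$min_len,
                               max_len = config@due$max_len,
                               min_at = config@due$min_at)
  thermo <- thermoTable()
  params <- loadWedgeParams(config@curvature$params)
  w <- config@weights
  cands <- lapply(seq_len(nrow(matches)), function(i) {
    m <- matches[i, , drop = FALSE]
    near <- if (nrow(dues)) which(vapply(seq_len(nrow(dues)), function(j)
      .edgeDistance(m$start, m$end, dues$start[j], dues$end[j], L,
                    circular = isCircular(seq)), numeric(1)) <=
        config@assoc_distance) else integer(0)
    ann <- if (length(near)) do.call(rbind, lapply(near, function(j)
      annotateDUE(dues[j, , drop = FALSE], seq, acs_matches = m,
                  table = thermo))) else
      annotateDUE(data.frame(start = 1, end = 1), seq)[0, ]
    # report window: placed so the EACS end sits at ~65% of the
    # window, leaving most of the span upstream where DUEs canonically
    # lie relative to an ACS (this mirrors the geometry of the
    # replicon's 256 bp origin window, where the consensus match sits
    # right of center with both unwinding elements upstream)
    wlen <- min(config@report_window, L)
    m_end_unwrapped <- m$start + .intervalWidth(m$start, m$end, L) - 1L
    ws <- m_end_unwrapped - as.integer(ceiling(0.65 * wlen)) + 1L
    if (isCircular(seq)) {
      ws <- .wrap1(ws, L)
    } else {
      ws <- max(1L, min(ws, L - wlen + 1L))
    }
    we <- if (isCircular(seq)) .wrap1(ws + wlen - 1L, L) else
      ws + wlen - 1L
    dna <- extractRegion(seq, ws, we)
    bend_mean <- NA_real_
    bends <- data.frame(position = integer(), curvature = numeric(),
                        rank = integer())
    if (!grepl("N", dna, fixed = TRUE) &&
        nchar(dna) > 2L * config@curvature$half_window) {
      prof <- curvatureProfile(helicalPath(dna, params),
                               half_window = config@curvature$half_window,
                               circular = FALSE,
                               reference = config@curvature$reference)
      bend_mean <- mean(prof@values, na.rm = TRUE)
      bends <- callBends(prof, quantile = config@curvature$quantile)
      if (nrow(bends))
        bends$position <- .wrap1(ws + bends$position - 1L, L)
    }
    at50 <- .centeredAT(seq, m$start, m$end)
    score <- .originScore(w, nrow(ann), at50,
                          bend_mean / config@curvature$reference)
    new("OriginCandidate", seq_id = seqId(seq), acs = m, dues = ann,
        at_50bp = at50, window = c(ws, we),
        mean_curvature = bend_mean, bends = bends, score = score)
  })
  ord <- order(-vapply(cands, candidateScore, numeric(1)),
               matches$start)
  cands[ord]
}

#' Summary table of origin candidates
#'
#' @param candidates List of [OriginCandidate-class] from
#'   [callOrigins()].
#' @return data.frame with one row per candidate.
#' @export
candidateTable <- function(candidates) {
  if (!length(candidates))
    return(data.frame(seq_id = character(), acs_start = integer(),
                      acs_end = integer(), strand = character(),
                      n_dues = integer(), at_50bp = numeric(),
                      window_start = integer(), window_end = integer(),
                      mean_curvature = numeric(), score = numeric()))
  do.call(rbind, lapply(candidates, function(x)
    data.frame(seq_id = x@seq_id, acs_start = x@acs$start,
               acs_end = x@acs$end, strand = x@acs$strand,
               n_dues = nrow(x@dues), at_50bp = x@at_50bp,
               window_start = x@window[1], window_end = x@window[2],
               mean_curvature = x@mean_curvature, score = x@score,
               stringsAsFactors = FALSE)))
}

# Genomic (possibly wrapping) interval -> window-local 1..wlen span,
# clipped to the window; NULL if disjoint.
.toLocal <- function(s, e, ws, wlen, L) {
  off <- function(p) (((p - ws) %% L)) + 1L
  ls <- off(s); le <- off(e)
  if (ls > wlen && le > wlen) return(NULL)
  if (ls > wlen) ls <- 1L
  if (le > wlen) le <- wlen
  if (le < ls) { ls <- 1L }  # span wraps the window itself: clip
  c(ls, le)
}

#' Structured report for an origin candidate
#'
#' Assembles the report-window sequence with all annotated spans
#' (EACS, each associated DUE, every AATAAA occurrence in the window,
#' bend positions) in both window-local and genomic 1-based
#' coordinates, plus the candidate's composition and score. The
#' \code{text} element renders the window with annotation lines
#' (\code{E} = EACS, \code{D} = DUE, \code{a} = AATAAA, \code{^} =
#' bend apex).
#'
#' @param candidate An [OriginCandidate-class].
#' @param seq The [CircularSequence-class] it was called on.
#' @return A list (JSON-serializable) with elements \code{seq_id},
#'   \code{window}, \code{sequence}, \code{annotations},
#'   \code{at_50bp}, \code{score}, \code{text}.
#' @seealso [writeReport()]
#' @export
regionReport <- function(candidate, seq) {
  stopifnot(is(candidate, "OriginCandidate"),
            is(seq, "CircularSequence"))
  L <- length(seq)
  ws <- candidate@window[1]; we <- candidate@window[2]
  dna <- extractRegion(seq, ws, we)
  wlen <- nchar(dna)
  ann <- list()
  addSpan <- function(kind, s, e, strand = ".") {
    loc <- .toLocal(s, e, ws, wlen, L)
    if (is.null(loc)) return()
    ann[[length(ann) + 1L]] <<- list(
      kind = kind, start = s, end = e,
      local_start = loc[1], local_end = loc[2], strand = strand)
  }
  addSpan("EACS", candidate@acs$start, candidate@acs$end,
          candidate@acs$strand)
  if (nrow(candidate@dues))
    for (j in seq_len(nrow(candidate@dues)))
      addSpan("DUE", candidate@dues$start[j], candidate@dues$end[j])
  wseq <- circularSequence(seqId(seq), dna, circular = FALSE)
  aat <- scanMotif(wseq, "AATAAA", strands = "both")
  if (nrow(aat))
    for (j in seq_len(nrow(aat)))
      addSpan("AATAAA", .wrap1(ws + aat$start[j] - 1L, L),
              .wrap1(ws + aat$end[j] - 1L, L), aat$strand[j])
  if (nrow(candidate@bends))
    for (j in seq_len(nrow(candidate@bends)))
      addSpan("BEND", candidate@bends$position[j],
              candidate@bends$position[j])
  # plain-text rendering, 60 columns per line
  mark <- function(kinds, sym) {
    row <- rep(" ", wlen)
    for (a in ann) if (a$kind %in% kinds)
      row[a$local_start:a$local_end] <- sym
    paste(row, collapse = "")
  }
  rows <- c(seqline = dna, eacs = mark("EACS", "E"),
            due = mark("DUE", "D"), aataaa = mark("AATAAA", "a"),
            bend = mark("BEND", "^"))
  txt <- character()
  for (o in seq.int(1L, wlen, by = 60L)) {
    e <- min(o + 59L, wlen)
    txt <- c(txt,
             sprintf("%9d %s", .wrap1(ws + o - 1L, L),
                     substr(rows["seqline"], o, e)),
             sprintf("%9s %s", "EACS", substr(rows["eacs"], o, e)),
             sprintf("%9s %s", "DUE", substr(rows["due"], o, e)),
             sprintf("%9s %s", "AATAAA", substr(rows["aataaa"], o, e)),
             sprintf("%9s %s", "bend", substr(rows["bend"], o, e)), "")
  }
  list(seq_id = seqId(seq),
       window = list(start = ws, end = we, length = wlen),
       sequence = dna, annotations = ann,
       at_50bp = candidate@at_50bp,
       mean_curvature = candidate@mean_curvature,
       score = candidate@score,
       text = paste(txt, collapse = "\n"))
}

#' Write an origin-candidate report
#'
#' @param report Output of [regionReport()].
#' @param json_path Path for the JSON report (skipped when
#'   \code{NULL}).
#' @param txt_path Path for the plain-text rendering (skipped when
#'   \code{NULL}).
#' @return Invisibly, \code{report}.
#' @export
writeReport <- function(report, json_path = NULL, txt_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (!is.null(txt_path)) writeLines(report$text, txt_path)
  invisible(report)
}
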