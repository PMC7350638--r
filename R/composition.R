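#' Windowed A+T / G+C content track
#'
#' Tiles the sequence with windows of \code{window} bp every
#' \code{step} bp, starting at position 1, and reports the A+T and G+C
#' fraction of each window. Fractions are computed over called bases
#' (N is excluded from numerator and denominator; an all-N window has
#' \code{NA} fractions, and \code{n_count} is always reported). On a
#' linear sequence the trailing window may be shorter than
#' \code{window}; on a circular sequence the final window instead
#' wraps across the junction to full size, so that with
#' \code{step == window} and \code{window} dividing the length every
#' base is covered exactly once.
#'
#' @param seq A [CircularSequence-class].
#' @param window Window size in bp (default 50).
#' @param step Step between window starts in bp (defaults to
#'   \code{window}, i.e. sequential non-overlapping windows).
#' @return A [WindowTrack-class].
#' @examples
#' s <- circularSequence("x", "GCGCGAATTC")
#' trackRecords(windowContent(s, window = 5))$at  # 0.0 0.8
#' @export
windowContent <- function(seq, window = 50, step = window) {
  stopifnot(is(seq, "CircularSequence"))
  L <- length(seq)
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1L || window > L)
    .stopf("window (%d) must be in [1, %d]", window, L)
  if (step < 1L) .stopf("step must be >= 1")
  ch <- .chars(residues(seq))
  isAT <- ch == "A" | ch == "T"
  isGC <- ch == "G" | ch == "C"
  isN <- ch == "N"
  circ <- isCircular(seq)
  if (circ && window > 1L) {
    ext <- seq_len(window - 1L)
    isAT <- c(isAT, isAT[ext]); isGC <- c(isGC, isGC[ext])
    isN <- c(isN, isN[ext])
  }
  starts <- seq.int(1L, L, by = step)
  atc <- .rollsum(isAT, window)
  gcc <- .rollsum(isGC, window)
  nc <- .rollsum(isN, window)
  rows <- lapply(starts, function(s) {
    if (s <= length(atc)) {
      e <- s + window - 1L
      c(s, if (circ) .wrap1(e, L) else e, atc[s], gcc[s], nc[s],
        window)
    } else {
      # trailing short window on a linear sequence
      idx <- s:L
      c(s, L, sum(isAT[idx]), sum(isGC[idx]), sum(isN[idx]),
        length(idx))
    }
  })
  m <- do.call(rbind, rows)
  called <- m[, 6] - m[, 5]
  rec <- data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
                    at = ifelse(called > 0, m[, 3] / called, NA_real_),
                    gc = ifelse(called > 0, m[, 4] / called, NA_real_),
                    n_count = as.integer(m[, 5]))
  new("WindowTrack", seq_id = seqId(seq), window = window, step = step,
      circular = circ, records = rec)
}

#' Global base composition
#'
#' @param seq A [CircularSequence-class].
#' @return Named numeric: \code{at}, \code{gc} and \code{n} fractions
#'   over all residues (summing to 1).
#' @examples
#' globalContent(circularSequence("x", "ACGT"))  # 0.5 0.5 0.0
#' @export
globalContent <- function(seq) {
  stopifnot(is(seq, "CircularSequence"))
  ch <- .chars(residues(seq))
  L <- length(ch)
  c(at = sum(ch == "A" | ch == "T") / L,
    gc = sum(ch == "G" | ch == "C") / L,
    n = sum(ch == "N") / L)
}

#' Composition shift scores at window boundaries
#'
#' Descriptive score for "sharp" composition changes: the absolute
#' difference in A+T fraction between adjacent windows, one score per
#' boundary (including the junction boundary between the last and
#' first window on circular tracks). Boundaries involving an all-N
#' window score \code{NA}.
#'
#' @param track A [WindowTrack-class] with at least two records.
#' @return data.frame with columns \code{boundary} (1-based position
#'   of the first base of the right-hand window) and \code{delta_at}.
#' @export
shiftScore <- function(track) {
  stopifnot(is(track, "WindowTrack"))
  rec <- trackRecords(track)
  n <- nrow(rec)
  if (n < 2L) .stopf("shiftScore needs a track with >= 2 windows")
  left <- seq_len(n - 1L); right <- left + 1L
  out <- data.frame(boundary = rec$start[right],
                    delta_at = abs(rec$at[right] - rec$at[left]))
  if (track@circular)
    out <- rbind(out, data.frame(
      boundary = rec$start[1],
      delta_at = abs(rec$at[1] - rec$at[n])))
  rownames(out) <- NULL
  out
}

#' Export a composition track
#'
#' Always writes a CSV of \code{(start, end, at, gc, n_count)}.
#' Optionally renders the track (linear profile or a circular layout
#' approximating a Circos-style ring) to an SVG or PDF file.
#'
#' @param track A [WindowTrack-class].
#' @param path Output CSV path.
#' @param plot_path Optional plot path (extension .svg or .pdf).
#' @param layout \code{"linear"} or \code{"circular"} plot layout.
#' @return \code{path}, invisibly.
#' @seealso [plotTrack()]
#' @export
exportTrack <- function(track, path, plot_path = NULL,
                        layout = c("linear", "circular")) {
  stopifnot(is(track, "WindowTrack"))
  layout <- match.arg(layout)
  utils::write.csv(trackRecords(track), path, row.names = FALSE)
  if (!is.null(plot_path)) {
    ext <- tolower(tools::file_ext(plot_path))
    if (ext == "svg" && capabilities("cairo")) {
      grDevices::svg(plot_path)
    } else {
      if (ext == "svg") plot_path <- sub("\\.svg$", ".pdf", plot_path)
      grDevices::pdf(plot_path)
    }
    on.exit(grDevices::dev.off())
    plotTrack(track, layout)
  }
  invisible(path)
}

#' Plot a composition track
#'
#' Linear layout: A+T fraction against window start. Circular layout:
#' windows on a ring, radial bars proportional to A+T fraction.
#'
#' @param track A [WindowTrack-class].
#' @param layout \code{"linear"} or \code{"circular"}.
#' @return Invisibly, \code{NULL}.
#' @export
plotTrack <- function(track, layout = c("linear", "circular")) {
  stopifnot(is(track, "WindowTrack"))
  layout <- match.arg(layout)
  rec <- trackRecords(track)
  at <- rec$at
  if (layout == "linear") {
    plot(rec$start, at, type = "l", xlab = "position (bp)",
         ylab = "A+T fraction", main = seqId(track), ylim = c(0, 1))
    graphics::abline(h = mean(at, na.rm = TRUE), lty = 2, col = "grey50")
  } else {
    theta <- 2 * pi * (rec$start - 1) / max(rec$end, rec$start)
    r0 <- 0.6
    r1 <- r0 + 0.35 * ifelse(is.na(at), 0, at)
    plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1, axes = FALSE,
         xlab = "", ylab = "", main = seqId(track))
    graphics::segments(r0 * cos(theta), r0 * sin(theta),
                       r1 * cos(theta), r1 * sin(theta),
                       col = grDevices::grey(0.2), lwd = 0.3)
    graphics::symbols(0, 0, circles = r0, inches = FALSE, add = TRUE,
                      fg = "grey40")
  }
  invisible(NULL)
}
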