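#' Construct a synthetic-replicon blueprint
#'
#' @param length Replicon length in bp (default 400,000).
#' @param background_at Background A+T fraction (default 0.66).
#' @param locus_start 1-based start of the planted origin locus.
#' @param elements data.frame with columns \code{kind} (\code{DUE},
#'   \code{EACS}, \code{ATRACT}, \code{SPACER}), \code{length},
#'   \code{target_at} (used for DUE), \code{label}; placed
#'   consecutively from \code{locus_start}.
#' @param seed Integer seed; generation is fully deterministic given
#'   the blueprint.
#' @param markov Use a first-order AT-class persistence chain for the
#'   background instead of i.i.d. draws.
#' @return A [RepliconSpec-class].
#' @seealso [defaultRepliconSpec()], [generateReplicon()]
#' @export
repliconSpec <- function(length = 400000, background_at = 0.66,
                         locus_start = 287484, elements, seed = 1,
                         markov = FALSE) {
  new("RepliconSpec", length = as.integer(length),
      background_at = background_at,
      locus_start = as.integer(locus_start), elements = elements,
      seed = as.integer(seed), markov = isTRUE(markov))
}

#' Default origin-locus blueprint
#'
#' The default layout mirrors the replicon's reported origin
#' architecture: two A+T-rich DUEs (43 bp at 0.73 and 41 bp at 0.62,
#' each carrying an AATAAA hexamer) upstream of a single 17 bp EACS
#' realization, with phased A-tract arrays immediately before and
#' after the EACS; the whole locus spans 185 bp and fits inside a
#' 256 bp report window. Background is i.i.d. with
#' \code{P(A) = P(T) = background_at / 2}.
#'
#' @inheritParams repliconSpec
#' @return A [RepliconSpec-class].
#' @export
defaultRepliconSpec <- function(length = 400000, background_at = 0.66,
                                locus_start = NULL, seed = 1,
                                markov = FALSE) {
  # default locus coordinate matches the replicon report window when
  # the sequence is long enough, else a proportional position
  if (is.null(locus_start))
    locus_start <- if (length >= 288000) 287484L else
      as.integer(floor(length * 0.72))
  elements <- data.frame(
    kind = c("DUE", "SPACER", "DUE", "SPACER", "ATRACT", "SPACER",
             "EACS", "SPACER", "ATRACT"),
    length = c(43L, 12L, 41L, 8L, 27L, 5L, 17L, 5L, 27L),
    target_at = c(0.73, NA, 0.62, NA, NA, NA, NA, NA, NA),
    label = c("DUE1", "", "DUE2", "", "ATRACT1", "", "EACS", "",
              "ATRACT2"),
    stringsAsFactors = FALSE)
  repliconSpec(length = length, background_at = background_at,
               locus_start = locus_start, elements = elements,
               seed = seed, markov = markov)
}

# DUE realization with exact A+T counts: a forced AATAAA insertion
# plus combinatorial placement of the remaining A/T letters, so the
# realized fraction is round(target_at * len) / len.
.realizeDUE <- function(len, target_at) {
  n_at <- round(target_at * len)
  off <- sample.int(len - 6L + 1L, 1L)
  rest_at <- max(0L, n_at - 6L)
  n_rest <- len - 6L
  letters <- c(sample(c("A", "T"), rest_at, replace = TRUE),
               sample(c("G", "C"), n_rest - rest_at, replace = TRUE))
  letters <- sample(letters)
  out <- character(len)
  out[off:(off + 5L)] <- .chars("AATAAA")
  out[-(off:(off + 5L))] <- letters
  out
}

# Concrete realization of an IUPAC pattern (subject-N never emitted).
.realizePattern <- function(pattern) {
  vapply(.chars(toupper(pattern)), function(sym) {
    set <- setdiff(.IUPAC[[sym]], "N")
    if (length(set) == 1L) set else sample(set, 1L)
  }, character(1), USE.NAMES = FALSE)
}

# Phased A-tract array: A tracts repeating every 10 bp (in phase with
# the ~10 bp helical repeat, so per-tract wedges add coherently), G/C
# linkers (so the array itself is not DUE-like). The second tract is
# A6 rather than A5, giving each array a unique curvature apex.
.realizeAtract <- function(len) {
  out <- character(0)
  k <- 0L
  while (length(out) < len) {
    k <- k + 1L
    tract <- rep("A", if (k == 2L) 6L else 5L)
    linker <- sample(c("G", "C"), 10L - length(tract), replace = TRUE)
    out <- c(out, tract, linker)
  }
  out[seq_len(len)]
}

.backgroundChars <- function(L, at, markov) {
  if (!markov)
    return(sample(c("A", "T", "G", "C"), L, replace = TRUE,
                  prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)))
  # first-order chain on the AT/GC class with persistence rho = 0.3,
  # stationary at the target A+T fraction
  rho <- 0.3
  p_stay <- at + rho * (1 - at)   # P(AT | AT)
  p_gain <- at * (1 - rho)        # P(AT | GC)
  u <- stats::runif(L)
  cls <- logical(L)
  cls[1] <- u[1] < at
  for (i in 2:L) cls[i] <- u[i] < (if (cls[i - 1]) p_stay else p_gain)
  ifelse(cls, sample(c("A", "T"), L, replace = TRUE),
         sample(c("G", "C"), L, replace = TRUE))
}

#' Generate a synthetic circular replicon with ground truth
#'
#' Draws the background sequence, plants the blueprint's elements
#' consecutively from \code{locus_start}, and verifies that the
#' planted EACS realization occurs exactly once on either strand of
#' the final circle; on a collision the whole sequence is re-drawn
#' with a deterministically shifted seed. Identical blueprints and
#' seeds produce identical output (R's Mersenne-Twister stream).
#'
#' @param spec A [RepliconSpec-class].
#' @param id Sequence identifier (default \code{"synthetic_replicon"};
#'   the name marks the sequence as generated, not a published one).
#' @return List with elements \code{sequence}
#'   (a circular [CircularSequence-class]), \code{truth} (data.frame:
#'   \code{label}, \code{kind}, \code{start}, \code{end},
#'   \code{length}, \code{target_at}, \code{realized_at}) and
#'   \code{spec}.
#' @export
generateReplicon <- function(spec, id = "synthetic_replicon") {
  stopifnot(is(spec, "RepliconSpec"))
  L <- spec@length
  for (attempt in 0:24) {
    set.seed(spec@seed + attempt * 9973L)
    ch <- .backgroundChars(L, spec@background_at, spec@markov)
    cursor <- spec@locus_start
    truth <- list()
    eacs_string <- NULL
    for (i in seq_len(nrow(spec@elements))) {
      el <- spec@elements[i, ]
      idx <- .wrap1(seq.int(cursor, cursor + el$length - 1L), L)
      if (el$kind != "SPACER") {
        piece <- switch(el$kind,
          DUE = .realizeDUE(el$length, el$target_at),
          EACS = .realizePattern(motifRegistry()$pattern[
            match("EACS", motifRegistry()$name)]),
          ATRACT = .realizeAtract(el$length),
          .stopf("unknown element kind '%s'", el$kind))
        ch[idx] <- piece
        if (el$kind == "EACS") eacs_string <- paste(piece, collapse = "")
        truth[[length(truth) + 1L]] <- data.frame(
          label = el$label, kind = el$kind, start = idx[1],
          end = idx[length(idx)], length = el$length,
          target_at = el$target_at,
          realized_at = mean(piece == "A" | piece == "T"),
          stringsAsFactors = FALSE)
      }
      cursor <- cursor + el$length
    }
    seqobj <- circularSequence(id, paste(ch, collapse = ""),
                               circular = TRUE)
    if (is.null(eacs_string)) return(list(sequence = seqobj,
      truth = do.call(rbind, truth), spec = spec))
    # uniqueness is enforced at the consensus-pattern level: a scan of
    # the finished circle for the EACS must yield exactly the planted
    # site, so chance background matches to the degenerate pattern
    # trigger a deterministic re-draw
    hits <- scanMotif(seqobj, "EACS", strands = "both")
    if (nrow(hits) == 1L)
      return(list(sequence = seqobj, truth = do.call(rbind, truth),
                  spec = spec))
  }
  .stopf("could not generate a replicon with a unique EACS in 25 attempts")
}

#' Interval recovery metrics against a truth set
#'
#' Matches calls to truth intervals of each kind greedily by Jaccard
#' index (circular-aware); a pair is a hit at Jaccard >=
#' \code{threshold}. If calls carry a \code{kind} column, each kind is
#' evaluated against calls of that kind only; otherwise all calls are
#' candidates for every kind.
#'
#' @param calls data.frame with \code{seq_id}, \code{start},
#'   \code{end} (and optionally \code{kind}).
#' @param truth Truth data.frame from [generateReplicon()].
#' @param seq_length Length of the (circular) sequence.
#' @param threshold Jaccard threshold for a hit (default 0.5).
#' @return data.frame per kind: \code{kind}, \code{n_truth},
#'   \code{n_calls}, \code{matched}, \code{precision} (NA when there
#'   are no calls), \code{recall}, \code{mean_jaccard}.
#' @export
evaluateCalls <- function(calls, truth, seq_length, threshold = 0.5) {
  if (nrow(calls) && nrow(truth) &&
      "seq_id" %in% names(calls) &&
      !all(calls$seq_id %in% truth$seq_id) &&
      "seq_id" %in% names(truth))
    .stopf("calls and truth refer to different sequences")
  kinds <- unique(truth$kind)
  out <- lapply(kinds, function(k) {
    tr <- truth[truth$kind == k, , drop = FALSE]
    cl <- if ("kind" %in% names(calls))
      calls[calls$kind == k, , drop = FALSE] else calls
    if (!nrow(cl))
      return(data.frame(kind = k, n_truth = nrow(tr), n_calls = 0L,
                        matched = 0L, precision = NA_real_, recall = 0,
                        mean_jaccard = NA_real_))
    J <- outer(seq_len(nrow(tr)), seq_len(nrow(cl)),
               Vectorize(function(i, j)
                 .intervalJaccard(tr$start[i], tr$end[i], cl$start[j],
                                  cl$end[j], seq_length)))
    matched <- 0L; jacc <- numeric(0)
    while (TRUE) {
      m <- which.max(J)  # leftmost max: deterministic
      if (!length(m) || J[m] < threshold) break
      i <- (m - 1) %% nrow(tr) + 1; j <- (m - 1) %/% nrow(tr) + 1
      matched <- matched + 1L
      jacc <- c(jacc, J[m])
      J[i, ] <- -1; J[, j] <- -1
    }
    data.frame(kind = k, n_truth = nrow(tr), n_calls = nrow(cl),
               matched = matched, precision = matched / nrow(cl),
               recall = matched / nrow(tr),
               mean_jaccard = if (matched) mean(jacc) else NA_real_)
  })
  do.call(rbind, out)
}

#' Export a truth set as GFF3 and BED
#'
#' @param truth Truth data.frame from [generateReplicon()].
#' @param seq A [CircularSequence-class] (for id and length).
#' @param gff_path,bed_path Output paths (either may be \code{NULL}).
#' @return Invisibly, \code{NULL}.
#' @export
writeTruth <- function(truth, seq, gff_path = NULL, bed_path = NULL) {
  L <- length(seq)
  if (!is.null(gff_path)) {
    lines <- c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", seqId(seq), L))
    for (i in seq_len(nrow(truth))) {
      s <- truth$start[i]; e <- truth$end[i]
      ivs <- if (e >= s) list(c(s, e)) else list(c(s, L), c(1L, e))
      for (iv in ivs)
        lines <- c(lines, sprintf(
          "%s\toriScan\t%s\t%d\t%d\t.\t+\t.\tID=%s;kind=%s",
          seqId(seq), tolower(truth$kind[i]), iv[1], iv[2],
          truth$label[i], truth$kind[i]))
    }
    writeLines(lines, gff_path)
  }
  if (!is.null(bed_path)) {
    iv <- data.frame(seq_id = seqId(seq), start = truth$start,
                     end = truth$end, label = truth$label, score = 0,
                     strand = "+", stringsAsFactors = FALSE)
    writeBed(iv, bed_path, seq_length = L)
  }
  invisible(NULL)
}
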