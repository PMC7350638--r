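#' @import methods
NULL

#' CircularSequence: a DNA sequence with topology
#'
#' Container for a single DNA sequence over the alphabet \{A,C,G,T,N\}
#' together with an identifier and a circular/linear topology flag.
#' Residues are stored uppercase; lowercase input is normalized on
#' construction. All coordinates used with this class are 1-based
#' inclusive.
#'
#' @slot id Character scalar, sequence identifier.
#' @slot residues Character scalar, the sequence (uppercase A/C/G/T/N).
#' @slot circular Logical scalar, \code{TRUE} for circular topology.
#'
#' @seealso [circularSequence()], [extractRegion()], [readFasta()]
#' @export
setClass("CircularSequence",
  representation(id = "character", residues = "character",
                 circular = "logical"))

setValidity("CircularSequence", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id))
    msg <- c(msg, "'id' must be a single non-NA string")
  if (length(object@residues) != 1L || is.na(object@residues))
    msg <- c(msg, "'residues' must be a single non-NA string")
  else {
    if (nchar(object@residues) < 1L)
      msg <- c(msg, "sequence must contain at least one residue")
    bad <- regexpr("[^ACGTN]", object@residues)
    if (bad > 0L)
      msg <- c(msg, sprintf(
        "illegal residue '%s' at offset %d (allowed: A, C, G, T, N)",
        substr(object@residues, bad, bad), as.integer(bad)))
  }
  if (length(object@circular) != 1L || is.na(object@circular))
    msg <- c(msg, "'circular' must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' WindowTrack: per-window base-composition track
#'
#' Windowed A+T and G+C fractions over a sequence. Each record is one
#' window with 1-based inclusive coordinates; on circular sequences the
#' final window may wrap (\code{end < start}). Fractions are computed
#' over called bases only (N excluded from numerator and denominator);
#' an all-N window has \code{NA} fractions.
#'
#' @slot seq_id Character scalar.
#' @slot window,step Integer scalars, window and step size in bp.
#' @slot circular Logical scalar, topology of the source sequence.
#' @slot records data.frame with columns \code{start}, \code{end},
#'   \code{at}, \code{gc}, \code{n_count}.
#'
#' @seealso [windowContent()], [shiftScore()], [exportTrack()]
#' @export
setClass("WindowTrack",
  representation(seq_id = "character", window = "integer",
                 step = "integer", circular = "logical",
                 records = "data.frame"))

setValidity("WindowTrack", function(object) {
  need <- c("start", "end", "at", "gc", "n_count")
  if (!all(need %in% names(object@records)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  ok <- stats::complete.cases(object@records[, c("at", "gc")])
  s <- object@records$at[ok] + object@records$gc[ok]
  if (length(s) && any(abs(s - 1) > 1e-12))
    return("at + gc must equal 1 for every fully called window")
  TRUE
})

#' ThermoTable: nearest-neighbor duplex free energies
#'
#' Dinucleotide stacking free energies (kcal/mol, 37C) plus duplex
#' initiation terms, used to score helical instability of candidate
#' DNA unwinding elements. The bundled default is the unified
#' nearest-neighbor set.
#'
#' @slot deltaG Named numeric of length 16, one value per dinucleotide.
#' @slot initiation Named numeric, initiation terms (\code{init_AT},
#'   \code{init_GC}).
#' @slot source Character scalar, citation for the values.
#'
#' @seealso [thermoTable()], [instabilityProfile()]
#' @export
setClass("ThermoTable",
  representation(deltaG = "numeric", initiation = "numeric",
                 source = "character"))

.DINUCS <- c(t(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)))

setValidity("ThermoTable", function(object) {
  if (!all(.DINUCS %in% names(object@deltaG)))
    return("deltaG must name all 16 dinucleotides")
  if (any(!is.finite(object@deltaG))) return("deltaG values must be finite")
  TRUE
})

#' WedgeParameterSet: dinucleotide wedge-model geometry
#'
#' Per-dinucleotide roll, tilt and twist angles (degrees) plus the rise
#' per step (Angstrom) that drive the wedge-model helical axis
#' construction. Parameter sets are bundled as cited CSV files; a
#' \code{"zero"} set (straight axis) is always available.
#'
#' @slot name Character scalar, set name.
#' @slot roll,tilt,twist Named numeric of length 16 (degrees).
#' @slot rise Numeric scalar, Angstrom per step.
#' @slot source Character scalar, citation.
#'
#' @seealso [loadWedgeParams()], [helicalPath()]
#' @export
setClass("WedgeParameterSet",
  representation(name = "character", roll = "numeric", tilt = "numeric",
                 twist = "numeric", rise = "numeric", source = "character"))

setValidity("WedgeParameterSet", function(object) {
  for (s in c("roll", "tilt", "twist"))
    if (!all(.DINUCS %in% names(slot(object, s))) ||
        any(!is.finite(slot(object, s))))
      return(sprintf("'%s' must be finite and name all 16 dinucleotides", s))
  if (length(object@rise) != 1L || !is.finite(object@rise) ||
      object@rise <= 0)
    return("'rise' must be a single positive number")
  TRUE
})

#' Path3D: wedge-model helical axis trajectory
#'
#' The 3D helical axis path of a DNA segment: one point per base
#' (Angstrom) and one orthonormal local frame per base. Consecutive
#' points are spaced exactly one rise apart along the mid-step axis.
#'
#' @slot points Numeric matrix, n x 3, axis coordinates in Angstrom.
#' @slot frames Numeric array, 3 x 3 x n, local frames (columns x,y,z;
#'   z is the local helix axis).
#' @slot rise Numeric scalar, Angstrom per step.
#'
#' @seealso [helicalPath()], [curvatureProfile()], [writePDB()]
#' @export
setClass("Path3D",
  representation(points = "matrix", frames = "array", rise = "numeric"))

setValidity("Path3D", function(object) {
  n <- nrow(object@points)
  if (ncol(object@points) != 3L) return("points must be an n x 3 matrix")
  if (!identical(dim(object@frames), c(3L, 3L, n)))
    return("frames must be a 3 x 3 x n array matching points")
  if (n >= 2L) {
    d <- sqrt(rowSums((object@points[-1, , drop = FALSE] -
                       object@points[-n, , drop = FALSE])^2))
    if (any(abs(d - object@rise) > 1e-9))
      return("consecutive points must be spaced exactly one rise apart")
  }
  TRUE
})

#' CurvatureProfile: per-position curvature of an axis path
#'
#' Curvature (1/Angstrom) at each base, computed as the reciprocal
#' circumradius of the triangle formed by the axis points at
#' \code{i - h}, \code{i}, \code{i + h}. Values are \code{NA} within
#' \code{h} of the ends on linear input and defined everywhere on
#' circular input. \code{normalized} is the ratio to a reference
#' curvature (default: a 42.8 Angstrom-radius circle).
#'
#' @slot values Numeric, per-position curvature in 1/Angstrom.
#' @slot half_window Integer scalar, h in bases.
#' @slot circular Logical scalar.
#' @slot reference Numeric scalar, reference curvature (1/Angstrom).
#' @slot normalized Numeric, \code{values / reference}.
#'
#' @seealso [curvatureProfile()], [callBends()]
#' @export
setClass("CurvatureProfile",
  representation(values = "numeric", half_window = "integer",
                 circular = "logical", reference = "numeric",
                 normalized = "numeric"))

setValidity("CurvatureProfile", function(object) {
  v <- object@values
  if (any(v[!is.na(v)] < 0)) return("defined curvature values must be >= 0")
  if (length(object@reference) != 1L || object@reference <= 0)
    return("'reference' must be a single positive number")
  TRUE
})

#' CallerConfig: origin-caller configuration
#'
#' Tunable parameters of [callOrigins()]: the DUE association distance,
#' the report window size, the composite-score weights and the
#' sub-configurations of the DUE detector and the curvature engine.
#' Construct with [callerConfig()].
#'
#' @slot assoc_distance Integer scalar, bp; DUEs whose edge-to-edge
#'   distance to the EACS match is at most this are associated.
#' @slot report_window Integer scalar, bp, size of the report window.
#' @slot weights Named numeric (\code{acs}, \code{due}, \code{at},
#'   \code{bend}); nonnegative, summing to 1.
#' @slot due List: \code{min_len}, \code{max_len}, \code{min_at}.
#' @slot curvature List: \code{params}, \code{half_window},
#'   \code{quantile}, \code{reference}.
#'
#' @seealso [callerConfig()], [callOrigins()]
#' @export
setClass("CallerConfig",
  representation(assoc_distance = "integer", report_window = "integer",
                 weights = "numeric", due = "list", curvature = "list"))

setValidity("CallerConfig", function(object) {
  w <- object@weights
  if (!all(c("acs", "due", "at", "bend") %in% names(w)))
    return("weights must name acs, due, at, bend")
  if (any(w < 0)) return("weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-12) return("weights must sum to 1")
  if (object@assoc_distance < 1L) return("assoc_distance must be positive")
  if (object@report_window < 1L) return("report_window must be positive")
  TRUE
})

#' OriginCandidate: a scored replication-origin candidate
#'
#' One EACS consensus match together with its associated DNA unwinding
#' elements, local composition, bend structure within the report
#' window, and a composite score in [0, 1].
#'
#' @slot seq_id Character scalar.
#' @slot acs One-row data.frame, the EACS match (see [scanMotif()]).
#' @slot dues data.frame of associated DUE calls (see [annotateDUE()]).
#' @slot at_50bp Numeric scalar, A+T fraction of the 50 bp window
#'   centered on the EACS midpoint.
#' @slot window Integer length-2, 1-based start/end of the report
#'   window (wrap allowed on circular sequences).
#' @slot mean_curvature Numeric scalar, mean defined curvature in the
#'   report window (1/Angstrom).
#' @slot bends data.frame of bend calls within the report window
#'   (positions in genomic coordinates).
#' @slot score Numeric scalar in [0, 1].
#'
#' @seealso [callOrigins()], [regionReport()]
#' @export
setClass("OriginCandidate",
  representation(seq_id = "character", acs = "data.frame",
                 dues = "data.frame", at_50bp = "numeric",
                 window = "integer", mean_curvature = "numeric",
                 bends = "data.frame", score = "numeric"))

setValidity("OriginCandidate", function(object) {
  if (length(object@score) != 1L || is.na(object@score) ||
      object@score < 0 || object@score > 1)
    return("score must be a single value in [0, 1]")
  if (length(object@window) != 2L) return("window must be (start, end)")
  TRUE
})

#' RepliconSpec: synthetic circular-replicon blueprint
#'
#' Parameters of the synthetic-data generator: total length, background
#' A+T bias, the ordered element layout planted at \code{locus_start},
#' and the random seed. The default blueprint (see
#' [defaultRepliconSpec()]) emulates a ~400 kb eccDNA replicon with
#' 0.66 global A+T, two upstream A+T-rich DUEs carrying AATAAA, a
#' single 17 bp EACS realization, and phased A-tract arrays flanking
#' the EACS.
#'
#' @slot length Integer scalar, replicon length in bp.
#' @slot background_at Numeric scalar in (0, 1), background A+T.
#' @slot locus_start Integer scalar, 1-based start of the planted locus.
#' @slot elements data.frame with columns \code{kind} (EACS, DUE,
#'   ATRACT, SPACER), \code{length}, \code{target_at}, \code{label};
#'   elements are placed consecutively from \code{locus_start}.
#' @slot seed Integer scalar.
#' @slot markov Logical scalar; if \code{TRUE} the background is a
#'   first-order chain with AT-class persistence instead of i.i.d.
#'
#' @seealso [repliconSpec()], [defaultRepliconSpec()],
#'   [generateReplicon()]
#' @export
setClass("RepliconSpec",
  representation(length = "integer", background_at = "numeric",
                 locus_start = "integer", elements = "data.frame",
                 seed = "integer", markov = "logical"))

setValidity("RepliconSpec", function(object) {
  if (object@length < 1L) return("length must be positive")
  if (object@background_at <= 0 || object@background_at >= 1)
    return("background_at must be in (0, 1)")
  need <- c("kind", "length", "target_at", "label")
  if (!all(need %in% names(object@elements)))
    return(paste("elements must have columns:", paste(need, collapse = ", ")))
  span <- sum(object@elements$length)
  if (span >= object@length)
    return("planted elements do not fit inside the replicon")
  if (object@locus_start < 1L || object@locus_start > object@length)
    return("locus_start out of range")
  TRUE
})
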