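#' @describeIn circularSequence Sequence identifier.
#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))

#' @describeIn circularSequence Residue string (uppercase).
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @describeIn circularSequence Circular topology flag.
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))

#' @describeIn windowContent Window records as a data.frame.
#' @export
setGeneric("trackRecords", function(x) standardGeneric("trackRecords"))

#' @describeIn curvatureProfile Per-position curvature values (1/A).
#' @export
setGeneric("curvatureValues", function(x) standardGeneric("curvatureValues"))

#' @describeIn callOrigins Composite score of a candidate.
#' @export
setGeneric("candidateScore", function(x) standardGeneric("candidateScore"))

setMethod("seqId", "CircularSequence", function(x) x@id)
setMethod("residues", "CircularSequence", function(x) x@residues)
setMethod("isCircular", "CircularSequence", function(x) x@circular)
setMethod("length", "CircularSequence", function(x) nchar(x@residues))
setMethod("seqId", "WindowTrack", function(x) x@seq_id)
setMethod("trackRecords", "WindowTrack", function(x) x@records)
setMethod("length", "Path3D", function(x) nrow(x@points))
setMethod("curvatureValues", "CurvatureProfile", function(x) x@values)
setMethod("candidateScore", "OriginCandidate", function(x) x@score)

setMethod("show", "CircularSequence", function(object) {
  L <- length(object)
  preview <- if (L <= 40) object@residues else
    paste0(substr(object@residues, 1, 20), "...",
           substr(object@residues, L - 16, L))
  cat(sprintf("CircularSequence '%s': %d bp, %s\n  %s\n", object@id, L,
              if (object@circular) "circular" else "linear", preview))
})

setMethod("show", "WindowTrack", function(object) {
  cat(sprintf(
    "WindowTrack '%s': %d windows of %d bp (step %d, %s)\n",
    object@seq_id, nrow(object@records), object@window, object@step,
    if (object@circular) "circular" else "linear"))
  at <- object@records$at
  cat(sprintf("  A+T fraction: mean %.3f, range [%.3f, %.3f]\n",
              mean(at, na.rm = TRUE), min(at, na.rm = TRUE),
              max(at, na.rm = TRUE)))
})

setMethod("show", "ThermoTable", function(object) {
  cat(sprintf("ThermoTable (%s): 16 dinucleotide deltaG, range [%.2f, %.2f] kcal/mol\n",
              object@source, min(object@deltaG), max(object@deltaG)))
})

setMethod("show", "WedgeParameterSet", function(object) {
  cat(sprintf(
    "WedgeParameterSet '%s': rise %.2f A, twist %.1f-%.1f deg, max wedge %.2f deg\n",
    object@name, object@rise, min(object@twist), max(object@twist),
    max(sqrt(object@roll^2 + object@tilt^2))))
})

setMethod("show", "Path3D", function(object) {
  ee <- sqrt(sum((object@points[nrow(object@points), ] -
                  object@points[1, ])^2))
  cat(sprintf("Path3D: %d points, rise %.2f A, end-to-end %.1f A\n",
              length(object), object@rise, ee))
})

setMethod("show", "CurvatureProfile", function(object) {
  v <- object@values
  cat(sprintf(
    "CurvatureProfile: %d positions (%d defined), half-window %d bp\n",
    length(v), sum(!is.na(v)), object@half_window))
  if (any(!is.na(v)))
    cat(sprintf("  curvature: mean %.4g, max %.4g 1/A (reference %.4g)\n",
                mean(v, na.rm = TRUE), max(v, na.rm = TRUE),
                object@reference))
})

setMethod("show", "CallerConfig", function(object) {
  w <- object@weights
  cat(sprintf(
    "CallerConfig: assoc %d bp, report window %d bp, weights acs/due/at/bend = %.2f/%.2f/%.2f/%.2f\n",
    object@assoc_distance, object@report_window,
    w["acs"], w["due"], w["at"], w["bend"]))
})

setMethod("show", "OriginCandidate", function(object) {
  cat(sprintf(
    "OriginCandidate on '%s': score %.3f\n  EACS at %d-%d (%s), %d associated DUE(s), A+T(50 bp) %.2f\n  report window %d-%d, mean curvature %.4g 1/A, %d bend call(s)\n",
    object@seq_id, object@score, object@acs$start, object@acs$end,
    object@acs$strand, nrow(object@dues), object@at_50bp,
    object@window[1], object@window[2], object@mean_curvature,
    nrow(object@bends)))
})

setMethod("show", "RepliconSpec", function(object) {
  cat(sprintf(
    "RepliconSpec: %d bp circular, background A+T %.2f, %d planted element(s) at %d, seed %d\n",
    object@length, object@background_at,
    sum(object@elements$kind != "SPACER"), object@locus_start,
    object@seed))
})
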