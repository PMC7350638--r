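# Elementary rotations (right-handed, angles in radians).
.Rz <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}
.Ry <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

# Rotation by angle about a unit axis (Rodrigues).
.axisAngle <- function(axis, angle) {
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Principal square root of a rotation matrix (half-angle rotation
# about the same axis), via the quaternion representation.
.sqrtRot <- function(R) {
  tr <- sum(diag(R))
  angle <- acos(max(-1, min(1, (tr - 1) / 2)))
  if (angle < 1e-12) return(diag(3))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(angle))
  .axisAngle(ax, angle / 2)
}

# Per-dinucleotide step rotation of the wedge model. The twist is
# split symmetrically around the wedge so that the construction is
# strand-symmetric: R = Rz(tw/2) . Rz(delta) Ry(sigma) Rz(-delta) .
# Rz(tw/2), with wedge magnitude sigma = sqrt(roll^2 + tilt^2) and
# direction delta = atan2(tilt, roll).
.stepRotation <- function(roll, tilt, twist) {
  d2r <- pi / 180
  sigma <- sqrt(roll^2 + tilt^2) * d2r
  delta <- atan2(tilt, roll)
  H <- .Rz(twist * d2r / 2)
  W <- .Rz(delta) %*% .Ry(sigma) %*% .Rz(-delta)
  H %*% W %*% H
}

#' Load a bundled wedge-model parameter set
#'
#' Parameter sets are shipped as cited CSV files under
#' \code{extdata/wedge_<name>.csv}. The \code{"zero"} set (all wedge
#' angles 0, twist 36.0 degrees) is always available and produces a
#' straight axis; the \code{"atract"} set carries the classic A-tract
#' wedge (8.7 degrees at AA/TT steps).
#'
#' @param name Set name (default \code{"atract"}).
#' @return A [WedgeParameterSet-class].
#' @export
loadWedgeParams <- function(name = "atract") {
  dir <- system.file("extdata", package = "oriScan")
  avail <- sub("^wedge_(.*)\\.csv$", "\\1",
               list.files(dir, pattern = "^wedge_.*\\.csv$"))
  path <- file.path(dir, sprintf("wedge_%s.csv", name))
  if (!file.exists(path))
    .stopf("unknown wedge parameter set '%s' (available: %s)", name,
           paste(avail, collapse = ", "))
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  need <- c("dinucleotide", "roll", "tilt", "twist", "rise")
  if (!all(need %in% names(df)) || !all(.DINUCS %in% df$dinucleotide))
    .stopf("malformed wedge parameter file: %s", path)
  rownames(df) <- df$dinucleotide
  df <- df[.DINUCS, ]
  src <- grep("^#", readLines(path, n = 5), value = TRUE)
  new("WedgeParameterSet", name = name,
      roll = stats::setNames(df$roll, .DINUCS),
      tilt = stats::setNames(df$tilt, .DINUCS),
      twist = stats::setNames(df$twist, .DINUCS),
      rise = df$rise[1],
      source = paste(sub("^#\\s?", "", src), collapse = " "))
}

#' Wedge-model helical axis path
#'
#' Propagates a local helical frame along the sequence, one
#' dinucleotide step at a time. Each step rotates the frame by the
#' dinucleotide's twist (split symmetrically) and wedge (roll/tilt
#' combined into a single rotation about an in-plane axis), and
#' advances one rise along the mid-step axis, so that consecutive
#' points are spaced exactly one rise apart and the construction is
#' invariant under reading the complementary strand. The first point
#' is at the origin with the identity frame.
#'
#' @param s DNA string over A/C/G/T, length >= 2. N is rejected: a
#'   caller must substitute or trim ambiguous positions explicitly.
#' @param params A [WedgeParameterSet-class].
#' @return A [Path3D-class].
#' @examples
#' p <- helicalPath("ACGTACGTAC", loadWedgeParams("zero"))
#' length(p)  # 10 collinear points
#' @export
helicalPath <- function(s, params = loadWedgeParams()) {
  stopifnot(is(params, "WedgeParameterSet"))
  s <- toupper(as.character(s))
  n <- nchar(s)
  if (n < 2L) .stopf("helicalPath needs at least 2 bases")
  if (grepl("[^ACGT]", s))
    .stopf("helicalPath requires fully called A/C/G/T sequence (offset %d)",
           as.integer(regexpr("[^ACGT]", s)))
  ch <- .chars(s)
  steps <- paste0(ch[-n], ch[-1L])
  Rs <- lapply(.DINUCS, function(d)
    .stepRotation(params@roll[d], params@tilt[d], params@twist[d]))
  names(Rs) <- .DINUCS
  halfRs <- lapply(Rs, .sqrtRot)
  rise <- params@rise
  pts <- matrix(0, n, 3)
  frames <- array(0, c(3, 3, n))
  F <- diag(3)
  frames[, , 1] <- F
  for (i in seq_len(n - 1L)) {
    d <- steps[i]
    axis_mid <- F %*% halfRs[[d]][, 3]
    pts[i + 1L, ] <- pts[i, ] + rise * axis_mid
    F <- F %*% Rs[[d]]
    frames[, , i + 1L] <- F
  }
  new("Path3D", points = pts, frames = frames, rise = rise)
}

#' Curvature profile of an axis path
#'
#' Curvature at position i is the reciprocal circumradius of the
#' triangle formed by the points at \code{i - h}, \code{i} and
#' \code{i + h} (\code{kappa = 4 * Area / (a * b * c)}). Collinear
#' triples give 0; coincident points are an error. On linear input
#' positions within \code{h} of the ends are \code{NA}; with
#' \code{circular = TRUE} indices wrap and every position is defined.
#'
#' @param path A [Path3D-class].
#' @param half_window Offset h in bases (default 7, about 1.5 helical
#'   turns across the 2h window).
#' @param circular Treat the path index as circular (default FALSE).
#' @param reference Reference curvature for the normalized track
#'   (default: a 42.8 Angstrom-radius circle).
#' @return A [CurvatureProfile-class].
#' @export
curvatureProfile <- function(path, half_window = 7, circular = FALSE,
                             reference = 1 / 42.8) {
  stopifnot(is(path, "Path3D"))
  h <- as.integer(half_window)
  n <- length(path)
  if (n <= 2L * h) .stopf("path length %d needs > 2 * half_window", n)
  pts <- path@points
  idx <- seq_len(n)
  if (circular) {
    ia <- .wrap1(idx - h, n); ic <- .wrap1(idx + h, n)
    defined <- idx
  } else {
    defined <- (h + 1L):(n - h)
    ia <- defined - h; ic <- defined + h
  }
  A <- pts[ia, , drop = FALSE]
  B <- pts[if (circular) idx else defined, , drop = FALSE]
  C <- pts[ic, , drop = FALSE]
  ab <- B - A; acv <- C - A; bc <- C - B
  la <- sqrt(rowSums(ab^2)); lb <- sqrt(rowSums(bc^2))
  lc <- sqrt(rowSums(acv^2))
  if (any(la < 1e-12 | lb < 1e-12 | lc < 1e-12))
    .stopf("degenerate (coincident) points in path")
  cr <- cbind(ab[, 2] * acv[, 3] - ab[, 3] * acv[, 2],
              ab[, 3] * acv[, 1] - ab[, 1] * acv[, 3],
              ab[, 1] * acv[, 2] - ab[, 2] * acv[, 1])
  kappa <- 2 * sqrt(rowSums(cr^2)) / (la * lb * lc)
  values <- rep(NA_real_, n)
  values[if (circular) idx else defined] <- kappa
  new("CurvatureProfile", values = values, half_window = h,
      circular = circular, reference = reference,
      normalized = values / reference)
}

#' Call bend sites from a curvature profile
#'
#' Bend calls are strict local maxima of the curvature profile whose
#' value is at least the given quantile of all defined values, ranked
#' by curvature (descending; ties broken by leftmost position).
#' Maxima within \code{min_separation} bases of a stronger call are
#' suppressed: two maxima closer than the curvature measurement
#' window describe the same physical bend, so the default separation
#' is \code{2 * half_window}.
#'
#' @param profile A [CurvatureProfile-class].
#' @param quantile Quantile threshold in [0, 1] (default 0.95).
#' @param min_separation Non-maximum-suppression radius in bases;
#'   0 disables suppression.
#' @return data.frame with columns \code{position} (1-based index
#'   into the path), \code{curvature} (1/Angstrom) and \code{rank}.
#' @export
callBends <- function(profile, quantile = 0.95,
                      min_separation = 2 * profile@half_window) {
  stopifnot(is(profile, "CurvatureProfile"))
  v <- profile@values
  n <- length(v)
  def <- which(!is.na(v))
  if (!length(def)) .stopf("profile has no defined values")
  thr <- stats::quantile(v[def], quantile, names = FALSE)
  prev <- if (profile@circular) v[.wrap1(seq_len(n) - 1L, n)] else
    c(NA, v[-n])
  nxt <- if (profile@circular) v[.wrap1(seq_len(n) + 1L, n)] else
    c(v[-1], NA)
  ismax <- !is.na(v) & !is.na(prev) & !is.na(nxt) &
    v > prev & v > nxt & v >= thr
  pos <- which(ismax)
  if (!length(pos))
    return(data.frame(position = integer(), curvature = numeric(),
                      rank = integer()))
  ord <- order(-v[pos], pos)
  pos <- pos[ord]
  if (min_separation > 0 && length(pos) > 1L) {
    kept <- integer(0)
    sep <- function(a, b) {
      d <- abs(a - b)
      if (profile@circular) pmin(d, n - d) else d
    }
    for (p in pos)
      if (!length(kept) || all(sep(p, kept) > min_separation))
        kept <- c(kept, p)
    pos <- kept
  }
  data.frame(position = pos, curvature = v[pos],
             rank = seq_along(pos))
}

#' Write an axis path as a PDB file
#'
#' One pseudo-atom (CA) per base on a single chain, fixed-width ATOM
#' records per the PDB 3.3 specification, no CONECT records,
#' terminated by END. Suitable for molecular viewers.
#'
#' @param path3d A [Path3D-class].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writePDB <- function(path3d, path) {
  stopifnot(is(path3d, "Path3D"))
  n <- length(path3d)
  if (n > 99999L) .stopf("PDB serial numbers are limited to 99,999 atoms")
  pts <- path3d@points
  lines <- sprintf(
    "ATOM  %5d  CA   DN A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n), ((seq_len(n) - 1L) %% 9999L) + 1L,
    pts[, 1], pts[, 2], pts[, 3], 1, 0)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
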