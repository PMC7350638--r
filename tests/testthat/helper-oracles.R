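# Independent brute-force oracles. These deliberately re-derive every
# quantity with a different formalism or a naive algorithm so that the
# package implementation is checked against code that shares nothing
# with it beyond the definitions.

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# -- circular slicing via materialized doubled string ------------------
brute_region <- function(res, start, end, circular) {
  L <- nchar(res)
  doubled <- paste0(res, res)
  if (end >= start) substr(res, start, end)
  else if (circular) substr(doubled, start, L + end)
  else stop("wrap on linear")
}

# -- naive window letter counting --------------------------------------
brute_window_fracs <- function(res, window, step, circular) {
  L <- nchar(res)
  sub <- if (circular) paste0(res, substr(res, 1, window - 1)) else res
  starts <- seq(1, L, by = step)
  t(vapply(starts, function(s) {
    e <- min(s + window - 1, nchar(sub))
    w <- strsplit(substr(sub, s, e), "")[[1]]
    called <- sum(w != "N")
    c(at = if (called) sum(w %in% c("A", "T")) / called else NA_real_,
      gc = if (called) sum(w %in% c("G", "C")) / called else NA_real_)
  }, c(at = 0, gc = 0)))
}

# -- position-by-position IUPAC comparison -----------------------------
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N"))
ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

brute_scan <- function(res, pattern, circular, strands = "both") {
  L <- nchar(res)
  k <- nchar(pattern)
  pch <- strsplit(pattern, "")[[1]]
  sub <- strsplit(if (circular) paste0(res, substr(res, 1, k - 1)) else
    res, "")[[1]]
  out <- list()
  for (s in seq_len(if (circular) L else max(0, L - k + 1))) {
    w <- sub[s:(s + k - 1)]
    if (all(mapply(function(b, p) b %in% ORACLE_IUPAC[[p]], w, pch))) {
      out[[length(out) + 1]] <- data.frame(
        start = ((s - 1) %% L) + 1, end = ((s + k - 2) %% L) + 1,
        strand = "+")
    }
    if (strands == "both") {
      wrc <- ORACLE_COMP[rev(w)]
      if (all(mapply(function(b, p) b %in% ORACLE_IUPAC[[p]], wrc,
                     pch))) {
        out[[length(out) + 1]] <- data.frame(
          start = ((s - 1) %% L) + 1, end = ((s + k - 2) %% L) + 1,
          strand = "-")
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character()))
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$strand), ]
  rownames(df) <- NULL
  df
}

# -- quaternion reimplementation of the wedge-model path ---------------
qmul <- function(a, b) {
  c(a[1] * b[1] - sum(a[-1] * b[-1]),
    a[1] * b[-1] + b[1] * a[-1] +
      c(a[3] * b[4] - a[4] * b[3],
        a[4] * b[2] - a[2] * b[4],
        a[2] * b[3] - a[3] * b[2]))
}
qaxis <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-15) return(c(1, 0, 0, 0))
  c(cos(angle / 2), sin(angle / 2) * axis / n)
}
qrot <- function(q, v) {
  qv <- c(0, v)
  qmul(qmul(q, qv), c(q[1], -q[-1]))[-1]
}
qsqrt <- function(q) {
  vn <- sqrt(sum(q[-1]^2))
  if (vn < 1e-15) return(c(1, 0, 0, 0))
  angle <- 2 * atan2(vn, q[1])
  qaxis(q[-1], angle / 2)
}

quat_path <- function(s, roll, tilt, twist, rise) {
  d2r <- pi / 180
  ch <- strsplit(toupper(s), "")[[1]]
  n <- length(ch)
  steps <- paste0(ch[-n], ch[-1])
  ez <- c(0, 0, 1)
  stepq <- function(d) {
    sigma <- sqrt(roll[d]^2 + tilt[d]^2) * d2r
    delta <- atan2(tilt[d], roll[d])
    h <- qaxis(ez, twist[d] * d2r / 2)
    w <- qmul(qmul(qaxis(ez, delta), qaxis(c(0, 1, 0), sigma)),
              qaxis(ez, -delta))
    qmul(qmul(h, w), h)
  }
  pts <- matrix(0, n, 3)
  qtot <- c(1, 0, 0, 0)
  for (i in seq_len(n - 1)) {
    qd <- stepq(steps[i])
    dir <- qrot(qmul(qtot, qsqrt(qd)), ez)
    pts[i + 1, ] <- pts[i, ] + rise * dir
    qtot <- qmul(qtot, qd)
  }
  pts
}

# -- circumradius via Heron's formula (Kahan's numerically stable
#    arrangement: sides sorted a >= b >= c) ----------------------------
brute_curvature <- function(p1, p2, p3) {
  s <- sort(c(sqrt(sum((p2 - p1)^2)), sqrt(sum((p3 - p2)^2)),
              sqrt(sum((p3 - p1)^2))), decreasing = TRUE)
  a <- s[1]; b <- s[2]; cc <- s[3]
  t <- (a + (b + cc)) * (cc - (a - b)) * (cc + (a - b)) * (a + (b - cc))
  if (t <= 0) return(0)
  area <- sqrt(t) / 4
  4 * area / (a * b * cc)
}

# -- interval helpers on a circle --------------------------------------
circ_cover <- function(s, e, L) {
  if (e >= s) s:e else c(s:L, 1:e)
}
brute_edge_distance <- function(a, b, L) {
  ca <- circ_cover(a[1], a[2], L)
  cb <- circ_cover(b[1], b[2], L)
  if (length(intersect(ca, cb))) return(0)
  d <- outer(ca, cb, function(i, j) {
    x <- abs(i - j)
    pmin(x, L - x)
  })
  min(d) - 1
}
brute_jaccard <- function(a, b, L) {
  ca <- circ_cover(a[1], a[2], L)
  cb <- circ_cover(b[1], b[2], L)
  length(intersect(ca, cb)) / length(union(ca, cb))
}
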