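# Internal helpers shared across modules. All coordinates 1-based inclusive.

# Wrap a 1-based position onto [1, L].
.wrap1 <- function(i, L) ((i - 1L) %% L) + 1L

# Split a residue string into a character vector.
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Rolling sum of x over windows of width k: result[i] = sum(x[i:(i+k-1)]).
.rollsum <- function(x, k) {
  cs <- cumsum(c(0, x))
  n <- length(x)
  if (k > n) return(numeric(0))
  cs[(k + 1):(n + 1)] - cs[1:(n - k + 1)]
}

# Width of a (possibly wrapping) 1-based inclusive interval.
.intervalWidth <- function(start, end, L) {
  ifelse(end >= start, end - start + 1L, L - start + 1L + end)
}

# Shorter-arc edge-to-edge distance between two intervals; 0 if they
# overlap. Intervals may wrap on circular sequences.
.edgeDistance <- function(a_start, a_end, b_start, b_end, L,
                          circular = TRUE) {
  expand <- function(s, e) if (e >= s) c(s, e) else c(s, e + L)
  a <- expand(a_start, a_end); b <- expand(b_start, b_end)
  gap <- function(a, b) {
    if (a[1] > b[2]) a[1] - b[2] - 1 else if (b[1] > a[2]) b[1] - a[2] - 1
    else 0
  }
  if (!circular) return(gap(a, b))
  # consider b shifted by -L, 0, +L around a
  min(vapply(c(-L, 0, L), function(off) gap(a, b + off), numeric(1)))
}

# Jaccard index of two (possibly wrapping) intervals on a circle.
.intervalJaccard <- function(a_start, a_end, b_start, b_end, L,
                             circular = TRUE) {
  cover <- function(s, e) {
    if (e >= s) seq.int(s, e) else c(seq.int(s, L), seq.int(1L, e))
  }
  a <- cover(a_start, a_end); b <- cover(b_start, b_end)
  length(intersect(a, b)) / length(union(a, b))
}

# Extract residues start..end with circular wrap (no validation).
.sliceWrap <- function(res, start, end, L) {
  if (end >= start) substr(res, start, end)
  else paste0(substr(res, start, L), substr(res, 1, end))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
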