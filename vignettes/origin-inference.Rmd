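---
title: "Inferring replication origins on circular DNA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring replication origins on circular DNA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriScan)
```

## The problem

Large extrachromosomal circular DNAs (eccDNAs) — such as the ~400 kb
glyphosate-resistance replicon of *Amaranthus palmeri* — replicate
autonomously, which implies at least one functional origin of
replication. When the only available material is the sequence itself,
origin inference rests on a small set of classical signals:

* **Composition.** Origins sit in A+T-rich neighborhoods; the duplex
  must open there. Windowed A+T / G+C tracks over the circle expose
  both the global bias and sharp local shifts.
* **An ARS consensus match.** In *S. cerevisiae* and several plants,
  origins contain an 11 bp ARS consensus sequence (ACS) embedded in a
  17 bp extended consensus (EACS). A single exact EACS match on a
  large circle is a strong anchor.
* **DNA unwinding elements (DUEs).** A+T-rich, helically unstable
  segments of roughly 30–100 bp found near origins, where unwinding
  initiates.
* **Intrinsic curvature.** Origins are associated with bent DNA —
  phased A-tracts produce macroscopic curvature of the helical axis —
  typically with sharper bends flanking the consensus element.

`oriScan` computes each signal from sequence alone and integrates them
into ranked origin candidates. A synthetic replicon generator with
planted ground truth makes the whole pipeline testable without any
proprietary sequence.

## Composition tracks

`windowContent()` tiles the sequence with sequential 50 bp windows
(both window and step configurable; the step defaults to the window,
i.e. non-overlapping). Fractions are computed over called bases: N is
excluded from numerator and denominator, so `at + gc == 1` holds for
every fully called window, and `n_count` is reported separately. An
all-N window has `NA` fractions.

On a circular sequence windows may wrap across the junction; the final
window wraps to full size rather than being truncated, because a
circle has no natural end. On a linear sequence the trailing short
window is emitted as-is. `shiftScore()` reports the absolute change in
A+T fraction at each window boundary — a descriptive measure of how
"punctuated" the composition landscape is, not a change-point test.

## Consensus scanning

`scanMotif()` performs degenerate IUPAC matching with three fixed
semantics:

* all occurrences are reported, including overlapping ones;
* on circular sequences, matches spanning the junction are found
  exactly once and reported as wrap intervals (`end < start`);
* `N` in the subject is matched only by `N` in the pattern, so masked
  regions cannot produce spurious hits from degenerate codes.

Both strands are scanned by default; the EACS is asymmetric and a
biologist expects either-strand hits. The bundled registry
(`motifRegistry()`) ships the 17 bp extended ACS consensus
(`WWWWTTTAYRTTTWGTT`), the 11 bp ACS core, and the AATAAA hexamer,
each with its source citation in the data file. The consensus is a
literature consensus: tests deliberately pin only its length and IUPAC
validity, not the particular string.

## DUE detection

`findATRichSegments()` is a deterministic five-step detector:

1. every 30 bp window (step 1) with A+T ≥ 0.60 is marked;
2. marked windows are merged into maximal regions;
3. regions longer than 100 bp are split recursively at their
   lowest-A+T valley (a centered 30 bp smoothed track; split points
   are constrained so both pieces keep ≥ 30 bp where possible; ties go
   leftmost);
4. each piece is trimmed to its leftmost maximal-scoring subsegment
   under the per-base score `[base is A/T] − min_at`, which moves the
   reported boundaries from the marked-window envelope toward the
   composition change-points; pieces trimmed below 30 bp are
   re-expanded to 30 bp within the piece;
5. pieces within the 30–100 bp band at ≥ 0.60 A+T are reported.

The defaults encode the biology: 30–100 bp is the canonical DUE size
range, and 0.60 sits just below the weakest reported replicon DUE
(62% A+T). The threshold applies to 30 bp windows, not merged regions,
so a strong core is not diluted by merging.

Two consequences are worth stating plainly. First, on a background
whose composition is itself close to the threshold (a 0.50 i.i.d.
background, let alone a 0.66 one), windows exceeding 0.60 arise by
chance constantly, so the detector reports many background segments;
it is a *candidate* generator, and association with an EACS (below)
does the discrimination. Second, boundary localization is limited by
the information in the sequence: a 43 bp element at ~0.72 A+T against
a 0.50 background differs by ~0.22 in a Bernoulli rate observed for
only 43 positions, and no estimator can place both edges within a few
bases most of the time. The acceptance script measures this directly:
recovery of the planted 43 bp element is high at Jaccard ≥ 0.5 but
modest at Jaccard ≥ 0.8. We report both rather than pretending to a
precision the data cannot support.

`instabilityProfile()` and `annotateDUE()` score helical instability
as the sum of unified nearest-neighbor duplex free energies
(kcal/mol, 37 °C; shipped as a cited CSV). Instability is reported,
never used as a detection gate — DUE identification is
composition-based.

## The wedge-model curvature engine

`helicalPath()` builds the helical axis by composing one rotation per
dinucleotide step. Each step applies half the twist, then a single
wedge rotation of magnitude `sqrt(roll² + tilt²)` about an axis in the
base-pair plane at direction `atan2(tilt, roll)`, then the second half
of the twist; the point advances one rise (3.38 Å) along the mid-step
axis. This symmetric convention was chosen deliberately: it makes the
construction exactly invariant under reading the complementary strand
(for any parameter set satisfying `roll(rc) = roll`,
`tilt(rc) = −tilt`), keeps consecutive points exactly one rise apart,
and agrees with naive twist-then-wedge orderings to second order in
the angles. The implementation is pinned by a dual-formalism oracle: a
quaternion reimplementation must agree to 10⁻⁶ Å.

Curvature (`curvatureProfile()`) at position *i* is the reciprocal
circumradius of the triangle formed by the axis points at *i − h*,
*i*, *i + h*, with *h* = 7 by default (the 14 bp span is ~1.5 helical
turns). The circumradius is closed-form, local, and testable against
analytic circles (a 100 Å circle must read 0.0100 Å⁻¹ everywhere) and
against rigid motions (invariance to 10⁻⁹). The optional normalized
track divides by the curvature of a 42.8 Å-radius circle — a
convention for cross-sequence comparison, not a physical claim.

`callBends()` reports strict local maxima above a quantile threshold
(default 0.95), ranked by curvature with leftmost tie-break. Maxima
closer than `2 h` to a stronger call are suppressed: two peaks inside
one measurement window describe the same physical bend.

Two wedge parameter sets are bundled: `"zero"` (straight axis, for
tests and as a null) and `"atract"`, the classic A-tract wedge — an
8.7° wedge at AA/TT steps (roll 8.4°, tilt 2.4°), all other steps
straight, twist 36°/step. The engine is parameter-set-agnostic by
design, and every test exercises geometry, limits and oracles rather
than particular angle values, so replacing the CSV with any other
published set changes no code. `writePDB()` emits one CA pseudo-atom
per base in fixed-width PDB 3.3 records for molecular viewers.

## The origin caller

`callOrigins()` produces one candidate per EACS match:

* DUE candidates whose edge-to-edge (shorter-arc) distance to the
  match is ≤ 250 bp are associated — 250 bp is the scale of the
  replicon's 256 bp origin window;
* `at_50bp` is the A+T fraction of the 50 bp window centered on the
  EACS midpoint ("surrounding" read symmetrically);
* a 256 bp report window is placed so the EACS *end* sits at 65% of
  the window. The asymmetry is deliberate: DUEs lie upstream of an
  ACS in canonical origin architecture, and in the replicon's own
  256 bp window the consensus sits right of center with both DUEs
  upstream. Centering on the EACS would clip the upstream DUEs;
  anchoring on detected DUEs would inherit their background noise;
* the window's wedge-model curvature yields a mean curvature and bend
  calls;
* the composite score is
  `0.4·[EACS] + 0.3·min(1, n_DUE/2) + 0.2·clamp((AT₅₀ − 0.5)/0.3) +
  0.1·clamp(κ̄/κ_ref)`.

The score is an ordering device, not a probability: the underlying
study ranks nothing, but a tool must order candidates
deterministically and ablatably (each term is monotone, so removing a
signal can only lower the score). Weights are configuration with
documented defaults. `regionReport()` renders the window with every
annotated span (EACS, DUEs, AATAAA occurrences, bend apexes) in both
window-local and genomic 1-based coordinates, as JSON and plain text.

## The synthetic replicon generator

`defaultRepliconSpec()` encodes the study conditions: a 400 kb circle
at 0.66 global A+T with one planted origin locus, by default at
coordinate 287,484 — the replicon's reported origin window. The locus
is, in order: DUE1 (43 bp, target A+T 0.73), a 12 bp spacer, DUE2
(41 bp, 0.62), an 8 bp spacer, a 27 bp phased A-tract array, 5 bp, the
17 bp EACS realization, 5 bp, and a second 27 bp A-tract array —
185 bp in all, inside one 256 bp window, with both DUEs upstream of
the EACS and A-tract arrays immediately flanking it.

Generator decisions, all deterministic given the seed (R's
Mersenne-Twister):

* **Background** is i.i.d. with `P(A) = P(T) = background_at/2`; a
  first-order Markov option (`markov = TRUE`, AT-class persistence
  0.3) exists for sensitivity checks. i.i.d. keeps false-positive
  rates analyzable.
* **DUEs** are realized with exact A+T counts (`round(target·len)`)
  plus a forced AATAAA at a random offset, so realized compositions
  sit within rounding of their targets (31/43 = 0.721, 25/41 = 0.610).
* **The EACS** is a uniform random realization of the consensus. After
  assembly the whole circle is scanned for the *consensus pattern*;
  if background produced a second match, the sequence is re-drawn
  with a deterministically shifted seed. This makes "exactly one EACS
  match" a generator contract rather than a probabilistic hope.
* **A-tract arrays** place A₅ tracts every 10 bp — in phase with the
  36°/step twist so per-tract wedges add coherently — with G/C linkers
  (so the arrays are not themselves DUE-like); the second tract is A₆,
  giving each array a single dominant curvature apex rather than a
  plateau of tied maxima.

What the generator does *not* emulate: repeats, genes, transposons,
strand asymmetries, long-range composition structure, or the
replicon's 59-gene architecture. Tests passing on this generator
demonstrate that the machinery recovers planted signals under
controlled noise — not that real replicons are this clean.

## Problem sizes and runtime envelopes

The test suite and the acceptance script size their simulations to
what the statistics require and no more: oracle-equivalence suites run
on 1.5–10 kb sequences; recovery is measured over 50 seeds of 100 kb
replicons (the signals under test are local, so 100 kb gives the same
per-seed answer as 400 kb at a quarter of the cost); the generator
calibration uses the full default 400 kb once. A full pipeline run on
a 400 kb circle takes a few seconds.

## Known limitations

* The wedge parameter set shipped as default is the minimal A-tract
  model; it reproduces A-tract-phased bending, not the finer
  sequence-dependence of a full 16-dinucleotide fit, and curvature
  magnitudes should be read comparatively, not absolutely.
* DUE boundary precision is information-limited (see above); treat
  reported DUE edges as ±5–10 bp under weak contrast.
* The composite score's weights are conventions. They order candidates
  sensibly and make ablations testable; they are not calibrated
  probabilities of origin function.
* Circular-junction handling assumes a single circular topology; no
  support for multimeric or branched forms.
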