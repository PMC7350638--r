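test_that("generation is deterministic in the seed", {
  sp <- defaultRepliconSpec(length = 20000, seed = 9)
  g1 <- generateReplicon(sp)
  g2 <- generateReplicon(sp)
  expect_identical(residues(g1$sequence), residues(g2$sequence))
  expect_identical(g1$truth, g2$truth)
  g3 <- generateReplicon(defaultRepliconSpec(length = 20000, seed = 10))
  expect_false(identical(residues(g1$sequence), residues(g3$sequence)))
})

test_that("planted elements satisfy the blueprint contract", {
  g <- generateReplicon(defaultRepliconSpec(length = 30000, seed = 12))
  tr <- g$truth
  d1 <- tr[tr$label == "DUE1", ]
  expect_equal(d1$length, 43L)
  expect_equal(d1$end - d1$start + 1L, 43L)
  expect_lt(abs(d1$realized_at - 0.73), 0.05)
  d2 <- tr[tr$label == "DUE2", ]
  expect_equal(d2$length, 41L)
  expect_lt(abs(d2$realized_at - 0.62), 0.05)
  # both DUEs carry the AATAAA hexamer
  for (lab in c("DUE1", "DUE2")) {
    row <- tr[tr$label == lab, ]
    dna <- extractRegion(g$sequence, row$start, row$end)
    expect_true(grepl("AATAAA", dna) || grepl("TTTATT", dna))
  }
  eacs <- tr[tr$kind == "EACS", ]
  expect_equal(eacs$length, 17L)
  # DUEs sit upstream of the EACS, inside a 256 bp locus
  expect_true(all(tr$start[tr$kind == "DUE"] < eacs$start))
  expect_lte(max(tr$end) - min(tr$start) + 1L, 256L)
})

test_that("the planted EACS is the unique consensus match", {
  for (seed in 1:5) {
    g <- generateReplicon(defaultRepliconSpec(length = 50000,
                                              seed = seed))
    hits <- scanMotif(g$sequence, "EACS")
    eacs <- g$truth[g$truth$kind == "EACS", ]
    expect_equal(nrow(hits), 1)
    expect_equal(hits$start, eacs$start)
  }
})

test_that("realized composition concentrates on the target with length", {
  devs <- vapply(c(5000L, 50000L, 200000L), function(L) {
    g <- generateReplicon(defaultRepliconSpec(length = L, seed = 31))
    abs(unname(globalContent(g$sequence)["at"]) - 0.66)
  }, numeric(1))
  expect_lt(devs[2], 0.02)
  expect_lt(devs[3], 0.01)
})

test_that("the Markov background option holds its stationary composition", {
  g <- generateReplicon(defaultRepliconSpec(length = 50000, seed = 2,
                                            markov = TRUE))
  at <- unname(globalContent(g$sequence)["at"])
  expect_lt(abs(at - 0.66), 0.02)
  # persistence: same-class transition frequency above i.i.d. value
  ch <- strsplit(residues(g$sequence), "")[[1]]
  cls <- ch %in% c("A", "T")
  stay <- mean(cls[-1] == cls[-length(cls)])
  expect_gt(stay, 0.6)
})

test_that("recovery metrics are exact on perfect and empty call sets", {
  g <- generateReplicon(defaultRepliconSpec(length = 20000, seed = 4))
  tr <- g$truth
  calls <- data.frame(seq_id = seqId(g$sequence), start = tr$start,
                      end = tr$end, kind = tr$kind)
  m <- evaluateCalls(calls, tr, length(g$sequence))
  expect_true(all(m$precision == 1))
  expect_true(all(m$recall == 1))
  expect_true(all(m$mean_jaccard == 1))
  empty <- calls[0, ]
  m0 <- evaluateCalls(empty, tr, length(g$sequence))
  expect_true(all(m0$recall == 0))
  expect_true(all(is.na(m0$precision)))
})

test_that("greedy matching agrees with brute-force all-pairs matching", {
  set.seed(91)
  L <- 1000
  for (rep in 1:10) {
    tr <- data.frame(kind = "DUE", seq_id = "x",
                     start = s <- sample(900, 4), end = s + sample(20:60, 4),
                     label = paste0("t", 1:4))
    calls <- data.frame(seq_id = "x", start = cs <- sample(900, 6),
                        end = cs + sample(10:70, 6))
    m <- evaluateCalls(calls, tr, L, threshold = 0.3)
    # oracle: greedy over the explicit jaccard matrix
    J <- outer(1:4, 1:6, Vectorize(function(i, j)
      brute_jaccard(c(tr$start[i], tr$end[i]),
                    c(calls$start[j], calls$end[j]), L)))
    matched <- 0
    repeat {
      best <- which.max(J)
      if (J[best] < 0.3) break
      matched <- matched + 1
      J[(best - 1) %% 4 + 1, ] <- -1
      J[, (best - 1) %/% 4 + 1] <- -1
    }
    expect_equal(m$matched, matched)
  }
})

test_that("truth sets export to GFF3 and BED and read back", {
  g <- generateReplicon(defaultRepliconSpec(length = 20000, seed = 6))
  gff <- withr::local_tempfile(fileext = ".gff3")
  bed <- withr::local_tempfile(fileext = ".bed")
  writeTruth(g$truth, g$sequence, gff_path = gff, bed_path = bed)
  lines <- readLines(gff)
  expect_equal(lines[1], "##gff-version 3")
  expect_equal(sum(grepl("\teacs\t", lines)), 1)
  back <- readBed(bed)
  expect_setequal(back$label, g$truth$label)
  expect_equal(sort(back$start), sort(g$truth$start))
})

test_that("infeasible blueprints are rejected", {
  expect_error(repliconSpec(length = 100, elements = data.frame(
    kind = "DUE", length = 200L, target_at = 0.7, label = "x")),
    "fit")
  expect_error(repliconSpec(length = 1000, background_at = 1.2,
                            elements = data.frame(kind = "SPACER",
                                                  length = 1L,
                                                  target_at = NA,
                                                  label = "")),
               "background_at")
})
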