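test_that("caller configuration enforces its invariants", {
  cfg <- callerConfig()
  expect_equal(cfg@assoc_distance, 250L)
  expect_equal(cfg@report_window, 256L)
  expect_equal(sum(cfg@weights), 1)
  expect_error(callerConfig(weights = c(acs = 0.5, due = 0.5, at = 0.5,
                                        bend = 0.5)), "sum to 1")
  expect_error(callerConfig(assoc_distance = 0), "positive")
})

test_that("a sequence without an EACS yields no candidates", {
  s <- circularSequence("x", strrep("GC", 500), circular = TRUE)
  expect_length(callOrigins(s), 0)
})

test_that("the planted origin is called once with both DUEs in its window", {
  g <- generateReplicon(defaultRepliconSpec(length = 100000, seed = 7))
  cands <- callOrigins(g$sequence)
  expect_length(cands, 1)
  cand <- cands[[1]]
  tr <- g$truth
  eacs <- tr[tr$kind == "EACS", ]
  expect_equal(cand@acs$start, eacs$start)
  expect_equal(diff(cand@window) + 1L, 256L)
  inside <- function(s, e) {
    ws <- cand@window[1]; we <- cand@window[2]
    s >= ws && e <= we
  }
  for (i in which(tr$kind == "DUE"))
    expect_true(inside(tr$start[i], tr$end[i]))
  expect_gte(cand@score, 0.5)
  expect_gte(nrow(cand@dues), 2)
})

test_that("the two strongest bends flank the EACS on the default layout", {
  g <- generateReplicon(defaultRepliconSpec(length = 100000, seed = 2))
  cand <- callOrigins(g$sequence)[[1]]
  eacs <- g$truth[g$truth$kind == "EACS", ]
  top2 <- cand@bends$position[cand@bends$rank <= 2]
  expect_length(top2, 2)
  expect_lt(min(top2), eacs$start)
  expect_gt(max(top2), eacs$end)
})

test_that("removing the planted DUEs strictly lowers the score", {
  # fixed GC backbone so the only DUE signal is the planted one
  due1 <- paste0("AATAAA", strrep("AT", 15), strrep("GC", 3), "G")  # 43 bp
  due2 <- paste0("AATAAA", strrep("TA", 13), strrep("GC", 4), "G")  # 41 bp
  eacs <- "AATTTTTATGTTTTGTT"
  gap <- strrep("GC", 12)
  mk <- function(d1, d2) circularSequence("t", paste0(
    strrep("GC", 1000), d1, gap, d2, gap, eacs, strrep("GC", 1000)),
    circular = TRUE)
  full <- callOrigins(mk(due1, due2))
  bare <- callOrigins(mk(paste0(strrep("GC", 21L), "G"),
                         paste0(strrep("GC", 20L), "G")))
  expect_length(full, 1)
  expect_length(bare, 1)
  expect_equal(nrow(full[[1]]@dues), 2)
  expect_equal(nrow(bare[[1]]@dues), 0)
  expect_lt(candidateScore(bare[[1]]), candidateScore(full[[1]]))
})

test_that("the composite score is monotone in each signal", {
  w <- callerConfig()@weights
  base <- oriScan:::.originScore(w, 1, 0.6, 0.4)
  expect_gte(oriScan:::.originScore(w, 2, 0.6, 0.4), base)
  expect_gte(oriScan:::.originScore(w, 1, 0.7, 0.4), base)
  expect_gte(oriScan:::.originScore(w, 1, 0.6, 0.6), base)
  # saturation: beyond 2 DUEs and full clamps nothing changes
  expect_equal(oriScan:::.originScore(w, 5, 2, 9),
               oriScan:::.originScore(w, 2, 1, 1))
  expect_true(all(vapply(1:50, function(i)
    oriScan:::.originScore(w, sample(0:4, 1), runif(1), runif(1, -1, 2)),
    numeric(1)) <= 1))
})

test_that("region reports annotate only inside the window and round-trip", {
  g <- generateReplicon(defaultRepliconSpec(length = 60000, seed = 3))
  cand <- callOrigins(g$sequence)[[1]]
  rep <- regionReport(cand, g$sequence)
  expect_equal(rep$window$length, 256)
  expect_equal(nchar(rep$sequence), 256)
  kinds <- vapply(rep$annotations, `[[`, character(1), "kind")
  expect_true("EACS" %in% kinds)
  expect_true(sum(kinds == "DUE") >= 2)
  expect_true("AATAAA" %in% kinds)
  for (a in rep$annotations) {
    expect_gte(a$local_start, 1)
    expect_lte(a$local_end, 256)
    expect_lte(a$local_start, a$local_end)
  }
  # the text rendering marks exactly the EACS columns with E
  eacs_ann <- rep$annotations[[which(kinds == "EACS")[1]]]
  txt <- strsplit(rep$text, "\n")[[1]]
  eacs_rows <- grep("^     EACS", txt, value = TRUE)
  marked <- unlist(lapply(seq_along(eacs_rows), function(r)
    which(strsplit(substr(eacs_rows[r], 11, 80), "")[[1]] == "E") +
      (r - 1) * 60))
  expect_equal(marked, seq(eacs_ann$local_start, eacs_ann$local_end))
  # JSON round-trip preserves the structure
  f <- withr::local_tempfile(fileext = ".json")
  writeReport(rep, json_path = f)
  back <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_equal(back$window$start, rep$window$start)
  expect_equal(back$sequence, rep$sequence)
  expect_equal(length(back$annotations), length(rep$annotations))
  expect_equal(back$score, rep$score)
})
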