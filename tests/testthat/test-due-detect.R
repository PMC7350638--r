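test_that("thermodynamic table is complete and strand-symmetric", {
  tt <- thermoTable()
  expect_setequal(names(tt@deltaG),
                  as.vector(outer(c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T"), paste0)))
  for (d in names(tt@deltaG)) {
    rc <- revComp(d)
    expect_equal(tt@deltaG[[d]], tt@deltaG[[rc]], info = d)
  }
  expect_true(all(tt@deltaG < 0))
  expect_true(all(tt@initiation > 0))
})

test_that("no A+T-rich segments are reported on a GC-only sequence", {
  s <- circularSequence("x", strrep("G", 1000))
  expect_equal(nrow(findATRichSegments(s)), 0)
})

test_that("a long A run is split into covering pieces within the band", {
  res <- paste0(strrep("G", 200), strrep("A", 200), strrep("G", 200))
  s <- circularSequence("x", res)
  seg <- findATRichSegments(s, max_len = 100)
  expect_gte(nrow(seg), 2)
  expect_true(all(seg$length <= 100))
  expect_true(all(seg$length >= 30))
  covered <- unique(unlist(mapply(seq, seg$start, seg$end)))
  expect_true(all(201:400 %in% covered))
  # calls stay inside the marked-window envelope around the run
  expect_true(all(covered >= 201 - 12 & covered <= 400 + 12))
})

test_that("raising the composition threshold never adds segments", {
  set.seed(41)
  for (rep in 1:5) {
    s <- circularSequence("x", rand_dna(3000,
      c(rep(c("A", "T"), 3), "C", "G")), circular = rep %% 2 == 0)
    prev_n <- Inf; prev_bp <- Inf
    for (th in c(0.6, 0.7, 0.8, 0.9)) {
      seg <- findATRichSegments(s, min_at = th)
      bp <- sum(seg$length)
      expect_lte(nrow(seg), prev_n)
      expect_lte(bp, prev_bp)
      prev_n <- nrow(seg); prev_bp <- bp
      # every reported call satisfies its own invariants
      if (nrow(seg)) {
        expect_true(all(seg$length >= 30 & seg$length <= 100))
        expect_true(all(seg$at_fraction >= th - 1e-12))
      }
    }
  }
  expect_error(findATRichSegments(
    circularSequence("x", "ACGT"), min_len = 2, max_len = 4,
    min_at = 1.5), "min_at")
})

test_that("a planted DUE is recovered on a neutral background", {
  # 43 bp at A+T 0.73 on an i.i.d. 0.50 background; boundary
  # localization of so small a composition contrast is inherently
  # noisy, so recovery is gated at the interval-matching threshold
  hits <- 0; meds <- numeric(0)
  for (seed in 1:25) {
    sp <- repliconSpec(length = 10000, background_at = 0.50,
                       locus_start = 5000, seed = seed,
                       elements = data.frame(kind = "DUE", length = 43L,
                                             target_at = 0.73,
                                             label = "DUE1"))
    g <- generateReplicon(sp)
    seg <- findATRichSegments(g$sequence)
    j <- max(vapply(seq_len(nrow(seg)), function(i)
      brute_jaccard(c(g$truth$start, g$truth$end),
                    c(seg$start[i], seg$end[i]), 10000), numeric(1)))
    meds <- c(meds, j)
    if (j >= 0.5) hits <- hits + 1
  }
  expect_gte(hits / 25, 0.7)
  expect_gte(median(meds), 0.6)
})

test_that("instability profile matches brute-force dinucleotide sums", {
  tt <- thermoTable()
  set.seed(43)
  res <- rand_dna(200)
  s <- circularSequence("x", res, circular = TRUE)
  prof <- instabilityProfile(s, window = 21, table = tt)
  ch <- strsplit(res, "")[[1]]
  for (i in sample(200, 12)) {
    idx <- ((i - 10):(i + 10) - 1) %% 200 + 1  # bases i-10 .. i+10
    steps <- paste0(ch[idx[1:20]], ch[idx[2:21]])
    expect_equal(prof[i], unname(sum(tt@deltaG[steps])))
  }
})

test_that("instability is higher for AT-rich than GC-rich DNA and
           constant on uniform sequence", {
  at <- circularSequence("x", strrep("AT", 50), circular = TRUE)
  gc <- circularSequence("x", strrep("GC", 50), circular = TRUE)
  expect_true(min(instabilityProfile(at, 41)) >
              max(instabilityProfile(gc, 41)))
  u <- instabilityProfile(circularSequence("x", strrep("A", 60),
                                           circular = TRUE), 41)
  expect_equal(length(unique(round(u, 9))), 1)
})

test_that("DUE annotation reports composition, motif and distance", {
  set.seed(47)
  res <- paste0(strrep("G", 40), "AAATAAATTTTAAATTTT", strrep("G", 30),
                "AATTTTTATGTTTTGTT", strrep("G", 20))
  s <- circularSequence("x", res, circular = TRUE)
  seg <- data.frame(start = 41, end = 58)
  acs <- scanMotif(s, "EACS")
  ann <- annotateDUE(seg, s, acs_matches = acs)
  expect_true(ann$has_aataaa)
  expect_equal(ann$at_fraction, 1)
  expect_equal(ann$length, 18L)
  expect_equal(ann$dist_to_nearest_acs, 30)
  expect_lt(ann$instability, 0)
  # no ACS matches supplied -> missing distance
  expect_true(is.na(annotateDUE(seg, s)$dist_to_nearest_acs))
  # reverse-strand AATAAA (TTTATT) counts too
  s2 <- circularSequence("x", paste0("GG", "TTTATT", "GG"))
  expect_true(annotateDUE(data.frame(start = 1, end = 10), s2)$has_aataaa)
})

test_that("circular distances take the shorter arc (oracle-checked)", {
  set.seed(53)
  L <- 100
  for (rep in 1:40) {
    a <- sort(sample(L, 2)); b <- sort(sample(L, 2))
    if (runif(1) < 0.3) a <- rev(a)  # wrap interval
    if (runif(1) < 0.3) b <- rev(b)
    expect_equal(
      oriScan:::.edgeDistance(a[1], a[2], b[1], b[2], L, TRUE),
      brute_edge_distance(a, b, L),
      info = paste(a[1], a[2], b[1], b[2]))
  }
})
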