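test_that("bundled wedge parameter sets load and validate", {
  z <- loadWedgeParams("zero")
  expect_true(all(z@roll == 0) && all(z@tilt == 0))
  expect_true(all(z@twist == 36.0))
  expect_equal(z@rise, 3.38)
  a <- loadWedgeParams("atract")
  expect_length(a@roll, 16)
  expect_match(a@source, "wedge", ignore.case = TRUE)
  expect_error(loadWedgeParams("nope"), "zero")  # lists available sets
})

test_that("zero wedge gives a straight axis at exact rise spacing", {
  p <- helicalPath(rand_dna(10), loadWedgeParams("zero"))
  pts <- p@points
  expect_equal(nrow(pts), 10)
  d <- sqrt(rowSums((pts[-1, ] - pts[-10, ])^2))
  expect_equal(d, rep(3.38, 9), tolerance = 1e-12)
  expect_equal(sqrt(sum((pts[10, ] - pts[1, ])^2)), 9 * 3.38,
               tolerance = 1e-9)
  # collinearity: curvature identically zero
  prof <- curvatureProfile(p, half_window = 2)
  expect_equal(max(curvatureValues(prof), na.rm = TRUE), 0)
})

test_that("helicalPath rejects N and too-short input", {
  expect_error(helicalPath("ACGNTT", loadWedgeParams("zero")), "A/C/G/T")
  expect_error(helicalPath("A", loadWedgeParams("zero")), "2 bases")
})

test_that("path agrees with an independent quaternion formalism", {
  set.seed(61)
  a <- loadWedgeParams("atract")
  for (rep in 1:4) {
    s <- rand_dna(60)
    got <- helicalPath(s, a)@points
    want <- quat_path(s, a@roll, a@tilt, a@twist, a@rise)
    expect_lt(max(abs(got - want)), 1e-6)
  }
  # also for a dense random parameter set (every step bent)
  dinucs <- as.vector(outer(c("A", "C", "G", "T"),
                            c("A", "C", "G", "T"), paste0))
  roll <- stats::setNames(runif(16, -10, 10), dinucs)
  tilt <- stats::setNames(runif(16, -5, 5), dinucs)
  twist <- stats::setNames(runif(16, 30, 40), dinucs)
  pset <- new("WedgeParameterSet", name = "rand", roll = roll,
              tilt = tilt, twist = twist, rise = 3.38, source = "test")
  s <- rand_dna(80)
  expect_lt(max(abs(helicalPath(s, pset)@points -
                    quat_path(s, roll, tilt, twist, 3.38))), 1e-6)
})

test_that("phased A-tracts bend: shorter end-to-end than shuffles", {
  set.seed(67)
  a <- loadWedgeParams("atract")
  tract <- paste(rep(c(strrep("A", 5), "GCGCG"), 20), collapse = "")
  ee <- function(s) {
    p <- helicalPath(s, a)@points
    sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  }
  e0 <- ee(tract)
  shuffles <- replicate(100, ee(paste(
    sample(strsplit(tract, "")[[1]]), collapse = "")))
  expect_lt(e0, mean(shuffles))
})

test_that("reverse-complement symmetry of the axis construction", {
  set.seed(71)
  a <- loadWedgeParams("atract")  # rc-symmetric by construction
  for (rep in 1:5) {
    s <- rand_dna(120)
    p1 <- helicalPath(s, a)@points
    p2 <- helicalPath(revComp(s), a)@points
    ee <- function(p) sqrt(sum((p[nrow(p), ] - p[1, ])^2))
    expect_lt(abs(ee(p1) - ee(p2)), 1e-6)
  }
})

test_that("analytic circle yields its exact curvature everywhere", {
  R <- 100; n <- 64
  theta <- 2 * pi * seq_len(n) / n
  pts <- cbind(R * cos(theta), R * sin(theta), 0)
  rise <- sqrt(sum((pts[2, ] - pts[1, ])^2))
  p <- new("Path3D", points = pts,
           frames = array(rep(diag(3), n), c(3, 3, n)), rise = rise)
  v <- curvatureValues(curvatureProfile(p, half_window = 7,
                                        circular = TRUE))
  expect_equal(v, rep(0.01, n), tolerance = 1e-9)
  # linear indexing leaves the ends undefined
  vl <- curvatureValues(curvatureProfile(p, half_window = 7))
  expect_true(all(is.na(vl[1:7])) && all(is.na(vl[(n - 6):n])))
  expect_equal(unname(vl[8]), 0.01, tolerance = 1e-9)
})

test_that("profile equals the brute-force circumradius at every position", {
  set.seed(73)
  p <- helicalPath(rand_dna(100), loadWedgeParams("atract"))
  h <- 7
  prof <- curvatureValues(curvatureProfile(p, half_window = h))
  pts <- p@points
  for (i in (h + 1):(100 - h))
    expect_lt(abs(prof[i] -
                  brute_curvature(pts[i - h, ], pts[i, ], pts[i + h, ])),
              1e-8)
})

test_that("curvature is invariant under rigid motions of the path", {
  set.seed(79)
  p <- helicalPath(rand_dna(80), loadWedgeParams("atract"))
  v0 <- curvatureValues(curvatureProfile(p))
  for (rep in 1:5) {
    ax <- runif(3) - 0.5
    R <- oriScan:::.axisAngle(ax / sqrt(sum(ax^2)), runif(1, 0, 2 * pi))
    shift <- matrix(runif(3, -50, 50), 80, 3, byrow = TRUE)
    moved <- new("Path3D", points = p@points %*% t(R) + shift,
                 frames = p@frames, rise = p@rise)
    v1 <- curvatureValues(curvatureProfile(moved))
    expect_lt(max(abs(v1 - v0), na.rm = TRUE), 1e-9)
  }
})

test_that("doubling the rise doubles distances and halves curvature", {
  s <- rand_dna(60)
  a <- loadWedgeParams("atract")
  a2 <- a; a2@rise <- 2 * a@rise
  p1 <- helicalPath(s, a); p2 <- helicalPath(s, a2)
  expect_equal(p2@points, 2 * p1@points, tolerance = 1e-9)
  v1 <- curvatureValues(curvatureProfile(p1))
  v2 <- curvatureValues(curvatureProfile(p2))
  expect_equal(v2, v1 / 2, tolerance = 1e-9)
})

test_that("bend calling finds spikes, not plateaus, and suppresses
           near-duplicates", {
  mk <- function(v) new("CurvatureProfile", values = v,
                        half_window = 2L, circular = FALSE,
                        reference = 1 / 42.8, normalized = v * 42.8)
  expect_equal(nrow(callBends(mk(rep(0.01, 50)))), 0)
  spike <- rep(0.001, 50); spike[25] <- 0.02
  b <- callBends(mk(spike))
  expect_equal(b$position, 25)
  two <- rep(0.001, 50); two[20] <- 0.02; two[23] <- 0.019
  expect_equal(callBends(mk(two), min_separation = 4)$position, 20)
  expect_equal(callBends(mk(two), min_separation = 0)$position,
               c(20, 23))
})

test_that("PDB output is fixed-width, parseable and round-trips", {
  p <- helicalPath(rand_dna(10), loadWedgeParams("atract"))
  f <- withr::local_tempfile(fileext = ".pdb")
  writePDB(p, f)
  lines <- readLines(f)
  expect_equal(length(lines), 11)
  expect_equal(lines[11], "END")
  atoms <- lines[1:10]
  expect_true(all(startsWith(atoms, "ATOM  ")))
  expect_true(all(nchar(atoms) <= 80))
  coords <- t(vapply(atoms, function(l)
    as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                 substr(l, 47, 54))), numeric(3)))
  expect_equal(unname(coords), unname(p@points), tolerance = 1e-3)
  skip_if_not_installed("bio3d")
  pdb <- bio3d::read.pdb(f)
  expect_equal(unname(matrix(pdb$xyz, ncol = 3, byrow = TRUE)),
               unname(p@points), tolerance = 1e-3)
})

test_that("oversized paths are refused by the PDB writer", {
  big <- matrix(0, 100000, 3); big[, 3] <- (0:99999) * 3.38
  p <- new("Path3D", points = big,
           frames = array(rep(diag(3), 100000), c(3, 3, 100000)),
           rise = 3.38)
  expect_error(writePDB(p, tempfile()), "99,999")
})
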