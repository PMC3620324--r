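uniform_pfm <- function(positions) {
  positionFrequencyMatrix(positions,
    matrix(0.25, length(positions), 4,
           dimnames = list(NULL, c("A", "C", "G", "T"))))
}

pure_pfm <- function(positions, base) {
  base <- rep_len(base, length(positions))
  f <- matrix(0, length(positions), 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  f[cbind(seq_along(positions), match(base, colnames(f)))] <- 1
  positionFrequencyMatrix(positions, f)
}

test_that("mismatch probability follows 1 - prod(P(predator base))", {
  a <- anchorWindow(1, 4, "TCTT")
  expect_equal(mismatchProbability(pure_pfm(1:4, c("T", "C", "T", "T")), a), 0)
  expect_equal(mismatchProbability(uniform_pfm(1:4), a), 1 - 0.25^4)  # 0.99609375
  expect_error(mismatchProbability(uniform_pfm(2:5), a), "not covered")
})

test_that("mismatch probability decreases as the predator base gets commoner", {
  set.seed(61)
  for (i in 1:20) {
    p1 <- stats::runif(1, 0.05, 0.45)
    p2 <- p1 + stats::runif(1, 0.05, 0.4)
    make <- function(pt) positionFrequencyMatrix(1:2, matrix(
      c(pt, (1 - pt) / 3, (1 - pt) / 3, (1 - pt) / 3,
        0.25, 0.25, 0.25, 0.25), 2, 4, byrow = TRUE,
      dimnames = list(NULL, c("T", "A", "C", "G"))))
    a <- anchorWindow(1, 2, "TT")
    expect_gt(mismatchProbability(make(p1), a),
              mismatchProbability(make(p2), a))
  }
})

test_that("estimated frequencies reproduce the analytic mismatch probability", {
  pfms <- anchorSiteFrequencies()
  a <- anchorWindow(640, 643, "TCTT")
  aln <- genAlignmentFromPfm(pfms$decapod, n = 4000, seed = 99)
  emp <- columnFrequencies(aln, positions = 1:4)
  emp@positions <- 640:643
  rownames(emp@freqs) <- 640:643
  expect_equal(mismatchProbability(emp, a),
               mismatchProbability(pfms$decapod, a), tolerance = 0.03)
})

test_that("selectAnchor ranks windows by worst-case group probability", {
  # 6 columns; predator row TTTTTT; group g1 has T common at cols 1-2 (low
  # mismatch prob) and rare at 4-5 (high prob); g2 uniform everywhere
  f1 <- matrix(c(0.9, 0.03, 0.04, 0.03,
                 0.9, 0.03, 0.04, 0.03,
                 0.5, 0.2, 0.2, 0.1,
                 0.05, 0.4, 0.3, 0.25,
                 0.05, 0.4, 0.3, 0.25,
                 0.5, 0.2, 0.2, 0.1), 6, 4, byrow = TRUE,
               dimnames = list(NULL, c("T", "A", "C", "G")))
  pfms <- list(g1 = positionFrequencyMatrix(1:6, f1), g2 = uniform_pfm(1:6))
  ent <- entropyProfile(uniform_pfm(1:6))
  ranked <- selectAnchor(ent, pfms, "TTTTTT", k = 2, searchRange = c(1, 6))
  # windows over columns 3-6 are capped by the uniform group (min over
  # groups), tie on entropy too -> smallest start first; the common-T
  # window (1,2) ranks last
  expect_equal(ranked$start[1L], 3L)
  expect_equal(ranked$start[nrow(ranked)], 1L)
  expect_true(all(diff(ranked$minProb) <= 1e-12))
  expect_equal(ranked$minProb[1L], 1 - 0.25^2)
  # a floor no window can meet empties the ranking
  none <- selectAnchor(ent, pfms, "TTTTTT", k = 2, searchRange = c(1, 6),
                       minProb = 0.9999)
  expect_equal(nrow(none), 0L)
  # single admissible window is returned alone
  one <- selectAnchor(ent, pfms, "TTTTTT", k = 2, searchRange = c(4, 5))
  expect_equal(nrow(one), 1L)
  expect_error(selectAnchor(ent, pfms, "TTTTTT", k = 2, searchRange = c(5, 5)),
               "search range")
})

test_that("anchor ties break by higher mean entropy, then smaller start", {
  pfms <- list(g = uniform_pfm(1:6))      # every window: same probability
  hx <- positionFrequencyMatrix(1:6, matrix(
    c(rep(0.25, 8),
      1, 0, 0, 0,
      1, 0, 0, 0,
      0.25, 0.25, 0.25, 0.25,
      0.25, 0.25, 0.25, 0.25), 6, 4, byrow = TRUE,
    dimnames = list(NULL, c("A", "C", "G", "T"))))
  ent <- entropyProfile(hx)    # high at 1-2 and 5-6, zero at 3-4
  ranked <- selectAnchor(ent, pfms, "AAAAAA", k = 2, searchRange = c(1, 6))
  expect_equal(ranked$start[1L], 1L)   # entropy tie between 1 and 5 -> smaller
  expect_equal(ranked$start[2L], 5L)
})

test_that("buildBlockingPrimer constructs the toy reverse-orientation design", {
  set.seed(62)
  row <- random_acgt(40)
  anchor <- anchorWindow(25, 28, substr(row, 25, 28))
  d <- buildBlockingPrimer(row, c(31, 40), anchor, overlap = 10)
  expect_equal(nchar(d@primerSeq), 16L)
  expect_identical(d@orientation, "reverse")
  expect_identical(d@primerSeq, revComp(substr(row, 25, 40)))
  # 3'-terminal tetramer equals the anchor bases on the template orientation
  expect_identical(revComp(substr(d@primerSeq, 13, 16)), anchor@predatorBases)
  expect_equal(d@overlapLen, 10L)
  expect_identical(d@threePrimeMod, "SpacerC3")
})

test_that("primer construction enforces length, gaps and geometry", {
  set.seed(63)
  row <- random_acgt(60)
  expect_error(
    buildBlockingPrimer(row, c(41, 60), anchorWindow(15, 18, substr(row, 15, 18)),
                        overlap = 10),
    "exceeds maxLen")
  gapped <- paste0(substr(row, 1, 27), "-", substr(row, 29, 60))
  expect_error(
    buildBlockingPrimer(gapped, c(31, 40), anchorWindow(25, 26, substr(row, 25, 26)),
                        overlap = 10),
    "gap")
  expect_error(
    buildBlockingPrimer(row, c(24, 33), anchorWindow(25, 28, substr(row, 25, 28))),
    "overlap the anchor")
  # mirrored geometry: versatile region on the 5' side -> forward primer
  d <- buildBlockingPrimer(row, c(1, 10), anchorWindow(20, 23, substr(row, 20, 23)),
                           overlap = 6)
  expect_identical(d@orientation, "forward")
  expect_identical(d@primerSeq, substr(row, 5, 23))
  expect_identical(substr(d@primerSeq, 16, 19),
                   substr(row, 20, 23))   # 3' end at the anchor
})

test_that("the primer always ends in the anchor bases with the stated overlap", {
  set.seed(64)
  for (i in 1:20) {
    row <- random_acgt(80)
    k <- sample(3:5, 1L)
    astart <- sample(20:40, 1L)
    anchor <- anchorWindow(astart, astart + k - 1L,
                           substr(row, astart, astart + k - 1L))
    vstart <- astart + k + sample(0:5, 1L)
    overlap <- sample(3:8, 1L)
    d <- tryCatch(
      buildBlockingPrimer(row, c(vstart, vstart + 14L), anchor,
                          overlap = overlap, maxLen = 40),
      error = function(e) NULL)
    if (is.null(d)) next
    expect_identical(revComp(substr(d@primerSeq, nchar(d@primerSeq) - k + 1L,
                                    nchar(d@primerSeq))),
                     anchor@predatorBases)
    inRegion <- sum(seq.int(d@spanStart, d@spanEnd) >= vstart)
    expect_equal(inRegion, overlap)
  }
})

test_that("profileMismatches applies IUPAC-aware comparison per column", {
  set.seed(65)
  row <- random_acgt(40)
  anchor <- anchorWindow(25, 28, substr(row, 25, 28))
  d <- buildBlockingPrimer(row, c(31, 40), anchor, overlap = 10)
  prey_same <- row
  prey_anchor1 <- row
  b <- substr(row, 25, 25)
  substr(prey_anchor1, 25, 25) <- setdiff(c("A", "C", "G", "T"), b)[1L]
  prey_n <- row
  substr(prey_n, 26, 26) <- "N"
  prey <- seqLibrary(c(same = prey_same, anch = prey_anchor1, amb = prey_n),
                     aligned = TRUE)
  pm <- profileMismatches(d, prey)
  expect_equal(pm$nMismatches[pm$seqId == "same"], 0L)
  expect_equal(pm$mismatchesFirstK[pm$seqId == "anch"], 1L)
  expect_equal(pm$mismatchPositions[pm$seqId == "anch"], "25")
  expect_equal(pm$nMismatches[pm$seqId == "amb"], 0L)   # N intersects T
  expect_error(profileMismatches(d, prey, window = c(20, 41)), "outside|beyond")
})

test_that("the predator's own row profiles all-zero against its design", {
  set.seed(66)
  for (i in 1:10) {
    row <- random_acgt(50)
    anchor <- anchorWindow(30, 33, substr(row, 30, 33))
    d <- buildBlockingPrimer(row, c(36, 45), anchor, overlap = 8)
    pm <- profileMismatches(d, seqLibrary(c(self = row), aligned = TRUE))
    expect_equal(pm$nMismatches, 0L)
    expect_equal(pm$mismatchesFirstK, 0L)
  }
})

test_that("published blocking primers satisfy the design constraints", {
  bp <- readFasta(system.file("extdata", "blocking_primers.fasta",
                              package = "preyblock"))
  for (s in as.character(bp)) {
    v <- validateBlockingPrimer(s, maxLen = 30)
    expect_true(v$ok)
    expect_lt(v$length, 30)
    expect_true(v$alphabetACGT)
    expect_identical(v$threePrimeMod, "SpacerC3")
  }
  expect_false(validateBlockingPrimer(strrep("ACGT", 10))$withinMaxLen)
  expect_false(validateBlockingPrimer("ACGTNACGTN")$alphabetACGT)
})

test_that("versatile primer evaluation scores degenerate matches correctly", {
  lco <- primerDef("LCO1490", "GGTCAACAAATCATAAAGATATTGG", "forward")
  dglco <- primerDef("dgLCO1490", "GGTCAACAAATCATAAAGAYATYGG", "forward")
  # template differing from LCO at its two Y positions (C where LCO has T)
  tmpl <- paste0("AAAA", "GGTCAACAAATCATAAAGACATCGG", "CCCC")
  lib <- seqLibrary(c(t1 = tmpl))
  perfect <- seqLibrary(c(t2 = paste0("GG", "GGTCAACAAATCATAAAGATATTGG")))
  expect_equal(evaluateVersatilePrimer(lco, perfect)$totalMismatches, 0L)
  r_lco <- evaluateVersatilePrimer(lco, lib)
  r_dg <- evaluateVersatilePrimer(dglco, lib)
  expect_equal(r_lco$totalMismatches, 2L)     # T/C at both degenerate spots
  expect_equal(r_lco$threePrimeMismatches, 1L)  # the Y at position 23 is 3'-near
  expect_equal(r_dg$totalMismatches, 0L)      # Y covers C
  expect_error(evaluateVersatilePrimer(lco, seqLibrary(c(s = "ACGT"))),
               "longer than")
})

test_that("reverse primers are evaluated through their reverse complement", {
  hco <- primerDef("HCO2198", "TAAACTTCAGGGTGACCAAAAAATCA", "reverse")
  tmpl <- paste0("GGGG", revComp(hco@seq), "TTTT")
  r <- evaluateVersatilePrimer(hco, seqLibrary(c(t = tmpl)))
  expect_equal(r$totalMismatches, 0L)
  # a mismatch at the primer's 3' end sits at the *start* of the rc pattern
  tmpl2 <- tmpl
  substr(tmpl2, 5, 5) <- if (substr(tmpl2, 5, 5) == "A") "C" else "A"
  r2 <- evaluateVersatilePrimer(hco, seqLibrary(c(t = tmpl2)))
  expect_equal(r2$threePrimeMismatches, 1L)
})
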