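ecori <- restrictionEnzyme("EcoRI", "GAATTC")
gdii <- restrictionEnzyme("GdiII", "CGGCCR")
bspei <- restrictionEnzyme("BspEI", "TCCGGA")

test_that("scanSites finds degenerate sites at hand-checked positions", {
  hits <- scanSites("AAGAATTCAA", ecori)
  expect_equal(hits$start, 3L)
  expect_equal(hits$strand, "+")       # palindromic: reported once
  hits <- scanSites("ACGGCCGT", gdii, bothStrands = FALSE)
  expect_equal(hits$start, 2L)         # R matches G
  expect_equal(nrow(scanSites("ACGTACGT", bspei)), 0L)
})

test_that("reverse-strand sites are reported in forward coordinates", {
  # GGTCTC (BsaI) is non-palindromic, so the two strands differ
  bsai <- restrictionEnzyme("BsaI", "GGTCTC")
  s <- paste0("AAAA", revComp("GGTCTC"), "AAAA")   # only the reverse site
  expect_equal(nrow(scanSites(s, bsai, bothStrands = FALSE)), 0L)
  hits <- scanSites(s, bsai, bothStrands = TRUE)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 5L)
})

test_that("palindromic motifs give identical hits with or without both strands", {
  set.seed(101)
  for (enz in list(ecori, bspei, restrictionEnzyme("BstXI", "CCANNNNNNTGG"))) {
    for (i in 1:10) {
      s <- random_acgt(120)
      expect_identical(scanSites(s, enz, bothStrands = TRUE)$start,
                       scanSites(s, enz, bothStrands = FALSE)$start)
    }
  }
})

test_that("scanSites agrees with the expansion + substring-search oracle", {
  set.seed(77)
  for (i in 1:60) {
    s <- random_acgt(sample(40:150, 1L))
    m <- random_motif(sample(6:8, 1L))
    enz <- restrictionEnzyme("rnd", m)
    got <- scanSites(s, enz, bothStrands = TRUE)
    want <- oracle_scan(s, m, bothStrands = TRUE)
    expect_identical(got$start, want$start)
    expect_identical(got$strand, want$strand)
  }
})

test_that("gapped sequences are stripped, or rejected when stripping is off", {
  expect_equal(scanSites("AAG-AATTC-AA", ecori)$start, 3L)
  expect_error(scanSites("AAG-AATTC-AA", ecori, stripGaps = FALSE), "gap")
})

test_that("cuttingFrequency counts sequences with at least one site", {
  set.seed(214)
  lib <- seqLibrary(c(a = "AAGAATTCAA", b = random_acgt(10),
                      c = "ACGTACGTAC", d = "TTTTTTTTTT"),
                    groups = c("g1", "g1", "g2", "g2"))
  rep_ <- cuttingFrequency(lib, ecori)
  expect_equal(rep_@overallFrequency, 0.25)
  expect_equal(rep_@perGroup$frequency[rep_@perGroup$group == "g1"], 0.5)
  expect_equal(rep_@perGroup$frequency[rep_@perGroup$group == "g2"], 0)
  none <- cuttingFrequency(lib, restrictionEnzyme("NotI", "GCGGCCGC"))
  expect_true(all(none@perGroup$frequency == 0))
  expect_error(cuttingFrequency(seqLibrary(character()), ecori), "empty")
})

test_that("a sequence carrying only the reverse-complement site counts as cut", {
  bsai <- restrictionEnzyme("BsaI", "GGTCTC")
  lib <- seqLibrary(c(a = paste0("AT", revComp("GGTCTC"), "ATAT")),
                    groups = "g1")
  expect_equal(cuttingFrequency(lib, bsai)@overallFrequency, 1)
  expect_equal(cuttingFrequency(lib, bsai, bothStrands = FALSE)@overallFrequency, 0)
})

test_that("inserting a concrete site never decreases any cutting frequency", {
  set.seed(5)
  for (i in 1:5) {
    seqs <- vapply(1:6, function(j) random_acgt(80), character(1L))
    names(seqs) <- paste0("s", 1:6)
    lib <- seqLibrary(seqs, groups = rep(c("x", "y"), 3))
    before <- cuttingFrequency(lib, ecori)
    k <- sample(6, 1L)
    seqs[k] <- paste0(substr(seqs[k], 1, 40), "GAATTC", substr(seqs[k], 41, 80))
    after <- cuttingFrequency(seqLibrary(seqs, groups = rep(c("x", "y"), 3)),
                              ecori)
    expect_true(all(after@perGroup$frequency >= before@perGroup$frequency))
    expect_gte(after@overallFrequency, before@overallFrequency)
  }
})

test_that("rankEnzymes orders by ascending mean prey frequency, name on ties", {
  set.seed(211)
  # predator carries sites for A and B; prey: A cuts none, B cuts 2/3
  predator <- paste0(random_acgt(20), "GAATTC", "TCCGGA", random_acgt(20))
  prey <- seqLibrary(c(p1 = paste0("ATTCCGGAAT", random_acgt(30)),
                       p2 = paste0(random_acgt(30), "TCCGGA", "AAAA"),
                       p3 = random_acgt(40)),
                     groups = rep("prey", 3))
  rk <- rankEnzymes(list(bspei, ecori,
                         restrictionEnzyme("NotI", "GCGGCCGC")),
                    predator, prey)
  expect_identical(rk@table$enzyme, c("EcoRI", "BspEI"))
  expect_identical(rk@excluded, "NotI")
  expect_error(rankEnzymes(list(), predator, prey), "empty")
})

test_that("no eligible enzymes when none cuts the predator; ties break by name", {
  set.seed(212)
  predator <- strrep("AC", 30)
  prey <- seqLibrary(c(p1 = random_acgt(50)), groups = "prey")
  rk <- rankEnzymes(list(ecori, bspei), predator, prey)
  expect_equal(nrow(rk@table), 0L)
  expect_identical(rk@excluded, c("BspEI", "EcoRI"))
  # both cut predator, both cut no prey -> tie -> lexicographic by name
  predator2 <- paste0("GAATTC", strrep("A", 20), "TCCGGA")
  prey2 <- seqLibrary(c(p1 = strrep("AC", 30)), groups = "prey")
  rk2 <- rankEnzymes(list(bspei, ecori), predator2, prey2)
  expect_identical(rk2@table$enzyme, c("BspEI", "EcoRI"))
})

test_that("fragment lengths partition the sequence", {
  s1 <- paste0(strrep("A", 295), "GAATTC", strrep("T", 357))  # site at 296
  enz <- restrictionEnzyme("EcoRI", "GAATTC", cutOffset = 5L)  # cut after 300
  expect_equal(predictFragments(s1, enz), c(300L, 358L))
  expect_equal(predictFragments(strrep("AC", 50), ecori), 100L)
  # two cut points after bases 100 and 400 on a 658-bp sequence
  s2 <- paste0(strrep("AC", 50), "GAATTC", strrep("AC", 147), "GAATTC",
               strrep("AC", 126))
  enz0 <- restrictionEnzyme("EcoRI", "GAATTC", cutOffset = 0L)
  expect_equal(predictFragments(s2, enz0), c(100L, 300L, 258L))
  set.seed(13)
  for (i in 1:20) {
    s <- random_acgt(sample(50:400, 1L))
    enz <- restrictionEnzyme("rnd", random_motif(6), cutOffset = sample(0:6, 1L))
    fr <- predictFragments(s, enz)
    expect_equal(sum(fr), nchar(s))
    hits <- scanSites(s, enz)
    cuts <- unique(hits$start - 1L + enz@cutOffset)
    cuts <- cuts[cuts > 0 & cuts < nchar(s)]
    expect_equal(length(fr), length(cuts) + 1L)
  }
})
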