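test_that("p-distances use pairwise deletion and record compared lengths", {
  aln <- seqLibrary(c(a = "ACGT", b = "ACGA", c = "AC-T", d = "ACGT"),
                    aligned = TRUE)
  dm <- pDistance(aln)
  d <- pdist(dm)
  expect_equal(d["a", "b"], 0.25)          # 1 mismatch / 4
  expect_equal(d["a", "c"], 0)             # 3 compared columns, none differ
  expect_equal(comparedLength(dm)["a", "c"], 3L)
  expect_equal(d["a", "d"], 0)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("ambiguity codes drop out of the comparison like gaps", {
  aln <- seqLibrary(c(a = "ANGT", b = "ACGT"), aligned = TRUE)
  dm <- pDistance(aln)
  expect_equal(comparedLength(dm)["a", "b"], 3L)
  expect_equal(pdist(dm)["a", "b"], 0)
})

test_that("a pair with no comparable columns errors naming the pair", {
  aln <- seqLibrary(c(a = "AC--", b = "--GT"), aligned = TRUE)
  expect_error(pDistance(aln), "'a' and 'b'")
})

test_that("p-distance agrees with ape::dist.dna raw pairwise-deletion", {
  skip_if_not_installed("ape")
  set.seed(71)
  seqs <- vapply(1:8, function(i) random_acgt(120), character(1L))
  names(seqs) <- paste0("s", 1:8)
  dm <- pDistance(seqLibrary(seqs, aligned = TRUE))
  mat <- do.call(rbind, strsplit(tolower(seqs), ""))
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(mat), model = "raw",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(pdist(dm)), unname(ref[rownames(pdist(dm)),
                                             colnames(pdist(dm))]),
               tolerance = 1e-12)
})

toy_dmat <- function(dAB, dAC, dBC) {
  d <- matrix(c(0, dAB, dAC, dAB, 0, dBC, dAC, dBC, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  as_pdist(d)
}

test_that("furthest neighbor merges below threshold, complete-linkage above", {
  dm <- toy_dmat(0.02, 0.2, 0.2)
  cl <- furthestNeighbor(dm, 0.05)
  expect_equal(partition_of(cl), list(c("A", "B"), "C"))
  cl2 <- furthestNeighbor(dm, 0.25)
  expect_equal(partition_of(cl2), list(c("A", "B", "C")))
})

test_that("merge ties resolve to the lexicographically smallest pair", {
  dm <- toy_dmat(0.04, 0.12, 0.04)   # (A,B) and (B,C) tie at 0.04
  cl <- furthestNeighbor(dm, 0.05)
  # (A,B) merges first; {A,B} vs C has complete distance 0.12 > t
  expect_equal(partition_of(cl), list(c("A", "B"), "C"))
})

test_that("furthest neighbor matches the exhaustive oracle, ties included", {
  set.seed(72)
  for (i in 1:40) {
    n <- sample(4:8, 1L)
    d <- random_dmat(n, digits = 2)    # coarse rounding forces ties
    t_ <- sample(c(0.05, 0.1, 0.15, 0.2), 1L)
    got <- partition_of(furthestNeighbor(as_pdist(d), t_))
    want <- oracle_complete_linkage(d, t_)
    expect_equal(got, want)
  }
})

test_that("tie-free matrices reproduce hclust complete-linkage cuts", {
  set.seed(73)
  for (i in 1:10) {
    n <- 12L
    d <- random_dmat(n, digits = 6)    # ties essentially impossible
    t_ <- stats::runif(1, 0.05, 0.25)
    got <- otuLabels(furthestNeighbor(as_pdist(d), t_))
    ref <- stats::cutree(stats::hclust(stats::as.dist(d), method = "complete"),
                         h = t_)
    canon <- function(lab) {
      parts <- lapply(split(names(lab), lab), sort)
      unname(parts[order(vapply(parts, `[`, character(1L), 1L))])
    }
    expect_equal(canon(got), canon(ref))
  }
})

test_that("OTU counts are non-increasing and hit both extremes", {
  set.seed(74)
  for (i in 1:10) {
    d <- random_dmat(sample(5:12, 1L), digits = 3)
    ts <- thresholdScan(as_pdist(d))
    expect_true(all(diff(scanCounts(ts)) <= 0L))
    off <- pdist(as_pdist(d))[upper.tri(d)]
    expect_equal(length(unique(otuLabels(
      furthestNeighbor(as_pdist(d), max(off))))), 1L)
    below <- min(off[off > 0]) * 0.99
    expect_equal(length(unique(otuLabels(
      furthestNeighbor(as_pdist(d), below)))), nrow(d))
  }
})

test_that("plateau detection picks the longest, earliest constant run", {
  th <- seq(0.01, 0.07, by = 0.01)
  pl <- otuPlateau(th, c(5L, 4L, 3L, 3L, 3L, 3L, 2L))
  expect_equal(pl$start, 0.03)
  expect_equal(pl$end, 0.06)
  expect_equal(pl$count, 3L)
  allsame <- otuPlateau(th, rep(4L, 7))
  expect_equal(c(allsame$start, allsame$end), c(0.01, 0.07))
  strict <- otuPlateau(th, 7:1)
  expect_equal(strict$start, 0.01)      # earliest run on length ties
  expect_equal(strict$runLength, 1L)
})

test_that("representatives minimize the distance sum, ids break ties", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 0.02
  d["a", "c"] <- d["c", "a"] <- 0.03
  d["b", "c"] <- d["c", "b"] <- 0.05
  d["a", "d"] <- d["d", "a"] <- 0.5
  d["b", "d"] <- d["d", "b"] <- 0.5
  d["c", "d"] <- d["d", "c"] <- 0.5
  dm <- as_pdist(d)
  cl <- pickRepresentatives(furthestNeighbor(dm, 0.1), dm)
  reps <- otuRepresentatives(cl)
  expect_equal(sort(unname(reps)), c("a", "d"))   # a central; d singleton
  # exact tie between all members resolves to the smallest id
  d2 <- matrix(c(0, 0.04, 0.04, 0.04, 0, 0.04, 0.04, 0.04, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  dm2 <- as_pdist(d2)
  cl2 <- pickRepresentatives(furthestNeighbor(dm2, 0.05), dm2)
  expect_equal(unname(otuRepresentatives(cl2)), "x")
})
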