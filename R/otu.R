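## Uncorrected p-distances, furthest-neighbor (complete linkage) clustering,
## threshold scans with plateau detection, and representative selection.

#' Uncorrected pairwise p-distances
#'
#' For each pair of aligned sequences, columns where either member carries a
#' gap or an ambiguity code are excluded (pairwise deletion) and the distance
#' is the fraction of mismatches among the remaining compared columns. The
#' number of compared columns is recorded per pair; a pair with nothing to
#' compare is an error naming the pair.
#'
#' @param alignment An aligned [SeqLibrary-class] with >= 2 records.
#' @return A [PDistMatrix-class].
#' @examples
#' aln <- seqLibrary(c(a = "ACGT", b = "ACGA", c = "AC-T"), aligned = TRUE)
#' pdist(pDistance(aln))
#' @export
pDistance <- function(alignment) {
  stopifnot(methods::is(alignment, "SeqLibrary"))
  if (!isAligned(alignment)) stop("pDistance requires an aligned library")
  n <- length(alignment)
  if (n < 2L) stop("pDistance requires at least 2 sequences")
  ids <- seqIds(alignment)
  chars <- do.call(rbind, strsplit(as.character(alignment), "", fixed = TRUE))
  code <- matrix(match(chars, c("A", "C", "G", "T")), nrow = n)  # NA = gap/ambig
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  cl <- matrix(ncol(code), n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    xi <- code[i, ]
    for (j in seq.int(i + 1L, n)) {
      ok <- !is.na(xi) & !is.na(code[j, ])
      ncomp <- sum(ok)
      if (ncomp == 0L)
        stop("no comparable columns between '", ids[i], "' and '", ids[j], "'")
      dd <- sum(xi[ok] != code[j, ok]) / ncomp
      d[i, j] <- d[j, i] <- dd
      cl[i, j] <- cl[j, i] <- ncomp
    }
  }
  diag(cl) <- as.integer(rowSums(!is.na(code)))
  storage.mode(cl) <- "integer"
  methods::new("PDistMatrix", d = d, comparedLen = cl)
}

#' @describeIn pDistance The symmetric distance matrix.
#' @param x A `PDistMatrix`.
#' @export
pdist <- function(x) x@d

#' @describeIn pDistance Compared columns per pair.
#' @export
comparedLength <- function(x) x@comparedLen

## Deterministic complete-linkage agglomeration shared by furthestNeighbor
## and thresholdScan. Merges the pair of clusters with the smallest
## complete-linkage (maximum pairwise) distance, ties broken by the
## lexicographically smallest (min-member-id, min-member-id) pair. Complete
## linkage has no inversions, so merge heights are non-decreasing and a
## single full run serves every threshold.
.fn_agglomerate <- function(d) {
  ids <- rownames(d)
  n <- length(ids)
  members <- as.list(seq_len(n))
  minid <- ids
  cd <- d                       # complete-linkage distances between clusters
  diag(cd) <- Inf
  active <- rep(TRUE, n)
  heights <- numeric(0)
  merges <- list()
  step <- 0L
  while (sum(active) > 1L) {
    act <- which(active)
    sub <- cd[act, act, drop = FALSE]
    h <- min(sub)
    cand <- which(sub == h, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pairids <- cbind(minid[act[cand[, 1L]]], minid[act[cand[, 2L]]])
    key <- apply(pairids, 1L, function(p) paste(sort(p), collapse = "\r"))
    pick <- cand[order(key)[1L], ]
    i <- act[pick[1L]]; j <- act[pick[2L]]
    if (minid[j] < minid[i]) { tmp <- i; i <- j; j <- tmp }
    ## merge j into i
    members[[i]] <- c(members[[i]], members[[j]])
    minid[i] <- min(minid[i], minid[j])
    active[j] <- FALSE
    newd <- pmax(cd[i, ], cd[j, ])
    cd[i, ] <- newd; cd[, i] <- newd
    cd[i, i] <- Inf
    step <- step + 1L
    heights[step] <- h
    merges[[step]] <- c(i, j)
  }
  ## membership after 0..step merges, one row per state
  memb <- matrix(0L, nrow = step + 1L, ncol = n, dimnames = list(NULL, ids))
  memb[1L, ] <- seq_len(n)
  cur <- seq_len(n)
  for (s in seq_len(step)) {
    cur[cur == merges[[s]][2L]] <- merges[[s]][1L]
    memb[s + 1L, ] <- cur
  }
  list(heights = heights, membership = memb)
}

.relabel <- function(assign_raw) {
  ## canonical labels 1..k in order of first appearance
  f <- match(assign_raw, unique(assign_raw))
  stats::setNames(as.integer(f), names(assign_raw))
}

#' Furthest-neighbor (complete linkage) clustering at a threshold
#'
#' Agglomerative complete-linkage clustering: repeatedly merge the pair of
#' clusters with the smallest complete-linkage distance (the maximum pairwise
#' distance between members) while that distance is <= `threshold`. Merge
#' ties are broken by the lexicographically smallest pair of minimum member
#' ids, making the output deterministic.
#'
#' @param dmat A [PDistMatrix-class].
#' @param threshold Dissimilarity threshold in `[0, 1]`.
#' @return An [OTUClustering-class] (without representatives; see
#'   [pickRepresentatives()]).
#' @export
furthestNeighbor <- function(dmat, threshold) {
  stopifnot(methods::is(dmat, "PDistMatrix"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  agg <- .fn_agglomerate(pdist(dmat))
  k <- sum(agg$heights <= threshold)
  raw <- agg$membership[k + 1L, ]
  methods::new("OTUClustering", threshold = threshold,
               clusters = .relabel(raw),
               representatives = character())
}

#' Longest constant run of OTU counts
#'
#' Step-function analysis: the plateau is the longest maximal run of
#' consecutive thresholds with an equal OTU count (the earliest run on a
#' length tie); the stable threshold is its start. Exposed separately so the
#' scan output can be re-analysed with user judgment.
#'
#' @param thresholds Ascending numeric thresholds.
#' @param counts Integer OTU count per threshold.
#' @return A list with `start`, `end` (thresholds), `count` and `runLength`.
#' @examples
#' otuPlateau(seq(0.01, 0.07, 0.01), c(5, 4, 3, 3, 3, 3, 2))
#' @export
otuPlateau <- function(thresholds, counts) {
  if (length(thresholds) != length(counts) || !length(thresholds))
    stop("thresholds and counts must be non-empty and parallel")
  r <- rle(as.integer(counts))
  best <- which.max(r$lengths)         # earliest on ties
  endIdx <- cumsum(r$lengths)
  startIdx <- endIdx - r$lengths + 1L
  list(start = thresholds[startIdx[best]], end = thresholds[endIdx[best]],
       count = as.integer(r$values[best]), runLength = r$lengths[best])
}

#' OTU counts across a dissimilarity-threshold grid
#'
#' Clusters once (complete linkage has monotone merge heights) and reads the
#' OTU count at each threshold of the grid, then locates the plateau where
#' the count becomes stable — the range separating intra- from inter-specific
#' variation.
#'
#' @param dmat A [PDistMatrix-class].
#' @param thresholds Ascending fractions (default 1% to 15% in steps of 1%).
#' @return A [ThresholdScan-class].
#' @export
thresholdScan <- function(dmat, thresholds = seq(0.01, 0.15, by = 0.01)) {
  stopifnot(methods::is(dmat, "PDistMatrix"))
  if (!length(thresholds)) stop("empty threshold list")
  thresholds <- as.numeric(thresholds)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly ascending")
  agg <- .fn_agglomerate(pdist(dmat))
  n <- ncol(agg$membership)
  counts <- vapply(thresholds, function(t) n - sum(agg$heights <= t),
                   integer(1L))
  pl <- otuPlateau(thresholds, counts)
  methods::new("ThresholdScan", thresholds = thresholds, otuCounts = counts,
               plateauStart = pl$start, plateauEnd = pl$end,
               plateauCount = pl$count)
}

#' Choose one representative sequence per OTU
#'
#' The member minimizing the sum of distances to the other members of its
#' cluster (its most central sequence); singletons represent themselves;
#' exact ties resolve to the lexicographically smallest id.
#'
#' @param clustering An [OTUClustering-class].
#' @param dmat The [PDistMatrix-class] the clustering was built from.
#' @return The clustering with its `representatives` slot filled.
#' @export
pickRepresentatives <- function(clustering, dmat) {
  stopifnot(methods::is(clustering, "OTUClustering"),
            methods::is(dmat, "PDistMatrix"))
  d <- pdist(dmat)
  cl <- otuLabels(clustering)
  if (!all(names(cl) %in% rownames(d)))
    stop("clustering ids not all present in the distance matrix")
  reps <- vapply(sort(unique(cl)), function(lab) {
    ids <- sort(names(cl)[cl == lab])
    if (length(ids) == 1L) return(ids)
    sums <- rowSums(d[ids, ids, drop = FALSE])
    ids[which.min(sums)]                 # ties -> first of sorted ids
  }, character(1L))
  clustering@representatives <-
    stats::setNames(reps, as.character(sort(unique(cl))))
  methods::validObject(clustering)
  clustering
}
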