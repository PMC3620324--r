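# Independent oracles used to cross-check the package implementations.
# Deliberately self-contained: they carry their own IUPAC tables and use
# naive algorithms (full expansion + substring search; exhaustive
# agglomeration over explicit member sets).

.ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.ORACLE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                        S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                        D = "H", H = "D", N = "N")

oracle_revcomp <- function(x) {
  ch <- rev(strsplit(x, "", fixed = TRUE)[[1L]])
  paste(.ORACLE_COMPLEMENT[ch], collapse = "")
}

# all concrete ACGT strings a degenerate motif denotes
oracle_expand <- function(motif) {
  ch <- strsplit(motif, "", fixed = TRUE)[[1L]]
  out <- ""
  for (c_ in ch) out <- as.vector(outer(out, .ORACLE_IUPAC[[c_]], paste0))
  out
}

# forward-strand starts where any expansion of `motif` occurs in `seq`
# (seq assumed concrete ACGT)
oracle_starts <- function(seq, motif) {
  k <- nchar(motif)
  n <- nchar(seq)
  if (k > n) return(integer())
  wins <- vapply(seq_len(n - k + 1L), function(i) substr(seq, i, i + k - 1L),
                 character(1L))
  which(wins %in% oracle_expand(motif))
}

# hits on both strands in forward coordinates, palindromic motifs deduped
oracle_scan <- function(seq, motif, bothStrands = TRUE) {
  fwd <- oracle_starts(seq, motif)
  hits <- data.frame(strand = rep("+", length(fwd)), start = fwd,
                     stringsAsFactors = FALSE)
  rc <- oracle_revcomp(motif)
  if (bothStrands && !identical(rc, motif)) {
    rev <- oracle_starts(seq, rc)
    hits <- rbind(hits, data.frame(strand = rep("-", length(rev)),
                                   start = rev, stringsAsFactors = FALSE))
  }
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

# exhaustive complete-linkage agglomeration over explicit member sets,
# same tie rule: smallest complete-linkage distance first; ties to the
# lexicographically smallest (sorted) pair of minimum member ids
oracle_complete_linkage <- function(d, threshold) {
  ids <- rownames(d)
  clusters <- lapply(ids, identity)
  repeat {
    if (length(clusters) < 2L) break
    bestPair <- NULL
    bestD <- Inf
    bestKey <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq.int(i + 1L, length(clusters))) {
        cd <- max(d[clusters[[i]], clusters[[j]]])
        key <- paste(sort(c(min(clusters[[i]]), min(clusters[[j]]))),
                     collapse = "\r")
        if (cd < bestD - 1e-15 ||
            (abs(cd - bestD) <= 1e-15 && !is.null(bestKey) && key < bestKey)) {
          bestD <- cd
          bestPair <- c(i, j)
          bestKey <- key
        }
      }
    }
    if (bestD > threshold) break
    merged <- c(clusters[[bestPair[1L]]], clusters[[bestPair[2L]]])
    clusters <- clusters[-bestPair]
    clusters[[length(clusters) + 1L]] <- merged
  }
  # canonical partition: sorted members, clusters ordered by first member
  parts <- lapply(clusters, sort)
  parts[order(vapply(parts, `[`, character(1L), 1L))]
}

# canonical partition of an OTUClustering for comparison with the oracle
partition_of <- function(clustering) {
  cl <- otuLabels(clustering)
  parts <- lapply(split(names(cl), cl), sort)
  unname(parts[order(vapply(parts, `[`, character(1L), 1L))])
}

# random symmetric distance matrix with zero diagonal; values rounded to
# `digits` so exact ties occur
random_dmat <- function(n, digits = 2) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- round(stats::runif(n * (n - 1L) / 2L, 0, 0.3), digits)
  d <- d + t(d)
  ids <- sprintf("s%02d", seq_len(n))
  dimnames(d) <- list(ids, ids)
  d
}

# wrap a plain matrix as the package's distance object
as_pdist <- function(d) {
  methods::new("PDistMatrix", d = d,
               comparedLen = matrix(100L, nrow(d), ncol(d),
                                    dimnames = dimnames(d)))
}

random_iupac_string <- function(len, alphabet = names(.ORACLE_IUPAC)) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_acgt <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# random degenerate motif with expansion count bounded by maxExpansion
random_motif <- function(len, maxExpansion = 64L) {
  repeat {
    m <- paste(sample(names(.ORACLE_IUPAC), len, replace = TRUE,
                      prob = c(rep(10, 4), rep(1, 11))), collapse = "")
    sizes <- vapply(strsplit(m, "", fixed = TRUE)[[1L]],
                    function(ch) length(.ORACLE_IUPAC[[ch]]), integer(1L))
    if (prod(sizes) <= maxExpansion) return(m)
  }
}
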