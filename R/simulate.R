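## Seeded synthetic generators: every input class the design and QC tools
## consume can be produced in code, so nothing depends on external
## databases. Each generator runs on its own explicitly seeded random
## stream and restores the caller's RNG state on exit.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.rand_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                        replace = TRUE), collapse = "")

#' Simulate an alignment from a position frequency matrix
#'
#' Draws each row i.i.d. per column from the generating frequencies —
#' the null model under which empirical column frequencies converge to the
#' generator and the analytic anchor mismatch probability is recovered.
#' Undefined PFM columns are an error.
#'
#' @param pfm A [PositionFrequencyMatrix-class] of generating frequencies.
#' @param n Number of rows (sequences) to draw.
#' @param seed Integer seed; the generator is bit-reproducible under it.
#' @param idPrefix Prefix for record ids (default `"sim"`).
#' @param group Optional single group label applied to all rows.
#' @return An aligned [SeqLibrary-class] with one column per PFM position.
#' @export
genAlignmentFromPfm <- function(pfm, n, seed, idPrefix = "sim",
                                group = NA_character_) {
  stopifnot(methods::is(pfm, "PositionFrequencyMatrix"))
  f <- pfmFreqs(pfm)
  if (anyNA(f)) stop("generating PFM has undefined columns")
  n <- as.integer(n)
  .with_seed(seed, {
    cols <- lapply(seq_len(nrow(f)), function(i)
      sample(colnames(f), n, replace = TRUE, prob = f[i, ]))
    seqs <- do.call(paste0, cols)
    names(seqs) <- sprintf("%s%0*d", idPrefix, nchar(as.character(n)),
                           seq_len(n))
    seqLibrary(seqs, groups = rep(group, n), aligned = TRUE)
  })
}

## substitute exactly nmut positions (sampled without replacement) with a
## uniformly chosen different base
.mutate_seq <- function(chars, nmut) {
  if (nmut == 0L) return(chars)
  pos <- sample.int(length(chars), nmut)
  for (p in pos) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[p])
    chars[p] <- alt[sample.int(3L, 1L)]
  }
  chars
}

.p_dist_chars <- function(a, b) mean(a != b)

#' Simulate sequence clusters with known membership
#'
#' Generates `nClusters` ancestor sequences mutually at least `interDiv`
#' apart (each ancestor derived from a common base sequence at substitution
#' rate `interDiv`, rejection-checked against all previous ancestors, so
#' inter-cluster distances sit just above the floor and the threshold scan
#' decays realistically at high thresholds), then derives each member by
#' substituting `min(Binomial(len, intraDiv), floor(len * intraDiv))` sites —
#' concentrated near the intraspecific cap, so low thresholds oversplit
#' clusters while the maximum intra-cluster pairwise distance is provably
#' <= `2 * intraDiv`. Substitutions only (no indels): the expected p-distance
#' equals the substitution fraction, keeping recovery tests analytic.
#'
#' @param nClusters Number of clusters (true OTUs).
#' @param membersPerCluster Members per cluster (scalar or vector).
#' @param len Sequence length (default 658, the COI barcode fragment).
#' @param intraDiv Maximum member-to-ancestor divergence (default 0.02).
#' @param interDiv Minimum ancestor-to-ancestor divergence (default 0.12).
#' @param seed Integer seed.
#' @param maxTries Rejection-sampling bound per ancestor before erroring.
#' @return An aligned [SeqLibrary-class] whose `groups` carry the true
#'   cluster labels (`"otu1"`, `"otu2"`, ...).
#' @export
genClusteredSequences <- function(nClusters, membersPerCluster, len = 658L,
                                  intraDiv = 0.02, interDiv = 0.12, seed,
                                  maxTries = 200L) {
  stopifnot(intraDiv >= 0, interDiv > 0, intraDiv <= 1, interDiv <= 1)
  if (intraDiv >= interDiv) stop("need intraDiv < interDiv")
  nClusters <- as.integer(nClusters)
  m <- rep_len(as.integer(membersPerCluster), nClusters)
  len <- as.integer(len)
  .with_seed(seed, {
    base <- strsplit(.rand_seq(len), "", fixed = TRUE)[[1L]]
    ancestors <- list()
    for (c_ in seq_len(nClusters)) {
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        anc <- .mutate_seq(base, round(interDiv * len))
        if (all(vapply(ancestors, function(a)
              .p_dist_chars(a, anc) >= interDiv, logical(1L)))) {
          ancestors[[c_]] <- anc
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place ancestor ", c_, " at interDiv >= ", interDiv,
             " after ", maxTries, " tries")
    }
    cap <- floor(intraDiv * len)
    seqs <- character(0)
    groups <- character(0)
    for (c_ in seq_len(nClusters)) {
      for (k in seq_len(m[c_])) {
        nmut <- min(stats::rbinom(1L, len, intraDiv), cap)
        seqs <- c(seqs, paste(.mutate_seq(ancestors[[c_]], nmut),
                              collapse = ""))
        groups <- c(groups, paste0("otu", c_))
      }
    }
    names(seqs) <- sprintf("c%02d_m%02d",
                           rep(seq_len(nClusters), m),
                           unlist(lapply(m, seq_len)))
    seqLibrary(seqs, groups = groups, aligned = TRUE)
  })
}

## does motif (possibly degenerate) hit the sequence on either strand?
.motif_hits <- function(seq, motif) {
  subj <- Biostrings::DNAString(seq)
  h <- length(Biostrings::matchPattern(motif, subj, fixed = FALSE))
  rc <- revComp(motif)
  if (!identical(rc, motif))
    h <- h + length(Biostrings::matchPattern(rc, subj, fixed = FALSE))
  h
}

## one concrete instance of a degenerate motif
.instantiate_motif <- function(motif) {
  chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
  paste(vapply(chars, function(ch) {
    opts <- IUPAC_CODES[[ch]]
    opts[sample.int(length(opts), 1L)]
  }, character(1L)), collapse = "")
}

## a random sequence with exactly `want` (0 or 1) planted instances of the
## motif and no accidental hits elsewhere, on either strand
.seq_with_motif <- function(len, motif, want, maxTries = 200L) {
  k <- nchar(motif)
  for (try in seq_len(maxTries)) {
    s <- .rand_seq(len)
    if (want == 1L) {
      at <- sample.int(len - k + 1L, 1L)
      inst <- .instantiate_motif(motif)
      s <- paste0(substr(s, 1L, at - 1L), inst, substr(s, at + k, len))
      if (.motif_hits(s, motif) == 1L) return(s)
    } else {
      if (.motif_hits(s, motif) == 0L) return(s)
    }
  }
  stop("could not generate a sequence with ", want,
       " instance(s) of motif ", motif, " after ", maxTries, " tries")
}

#' Simulate a predator + grouped prey library with planted restriction sites
#'
#' The predator sequence carries each planted motif exactly once; each prey
#' sequence carries it with probability `rate` (exactly once when it does,
#' never accidentally otherwise — occurrences are rejection-checked on both
#' strands). Exercises the restriction screen end to end: at `rate = 0` the
#' enzyme cuts the predator and no prey.
#'
#' @param groups Named integer vector: prey group label -> number of
#'   sequences (e.g. `c(decapod = 30, fish = 20)`).
#' @param motif IUPAC recognition motif to plant (effective length <= `len`).
#' @param rate Per-prey probability of carrying the site (default 0).
#' @param len Sequence length (default 658).
#' @param seed Integer seed.
#' @param predatorId Id for the predator record (default `"predator"`).
#' @return A list with `library` (the prey [SeqLibrary-class], grouped),
#'   `predatorSeq` (character) and `predatorId`.
#' @export
genPredatorPreyLibrary <- function(groups, motif, rate = 0, len = 658L,
                                   seed, predatorId = "predator") {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named vector of counts")
  if (nchar(motif) > len) stop("motif longer than sequence length")
  stopifnot(rate >= 0, rate <= 1)
  len <- as.integer(len)
  .with_seed(seed, {
    predator <- .seq_with_motif(len, motif, 1L)
    seqs <- character(0)
    glab <- character(0)
    for (g in names(groups)) {
      for (k in seq_len(groups[[g]])) {
        want <- if (stats::runif(1L) < rate) 1L else 0L
        seqs <- c(seqs, .seq_with_motif(len, motif, want))
        glab <- c(glab, g)
      }
    }
    names(seqs) <- sprintf("%s%03d", glab, unlist(lapply(groups, seq_len)))
    list(library = seqLibrary(seqs, groups = glab, aligned = FALSE),
         predatorSeq = stats::setNames(predator, predatorId),
         predatorId = predatorId)
  })
}

.STOPS5 <- c("TAA", "TAG")   # stop codons of the invertebrate mito code

## random coding sequence with no internal stop in frame 1
.rand_coding <- function(ncodons, gc) {
  nonstop <- names(gc)[gc != "*"]
  paste(sample(nonstop, ncodons, replace = TRUE), collapse = "")
}

## substitute nmut sites without creating a frame-1 stop codon
.mutate_coding <- function(chars, nmut, gc) {
  pos <- sample.int(length(chars), nmut)
  for (p in pos) {
    cod <- (p - 1L) %/% 3L            # 0-based codon index
    idx <- (3L * cod + 1L):(3L * cod + 3L)
    for (alt in sample(setdiff(c("A", "C", "G", "T"), chars[p]))) {
      cand <- chars
      cand[p] <- alt
      if (gc[[paste(cand[idx], collapse = "")]] != "*") {
        chars <- cand
        break
      }
    }
  }
  chars
}

## plant a stop codon in every forward frame
.plant_stops <- function(chars, maxTries = 50L) {
  len <- length(chars)
  for (try in seq_len(maxTries)) {
    cand <- chars
    for (frame in 1:3) {
      ncod <- (len - frame + 1L) %/% 3L
      cod <- sample.int(ncod - 1L, 1L)           # internal: not the last codon
      at <- frame + 3L * (cod - 1L)
      stop_codon <- .STOPS5[sample.int(2L, 1L)]
      cand[at:(at + 2L)] <- strsplit(stop_codon, "", fixed = TRUE)[[1L]]
    }
    ok <- all(vapply(1:3, function(fr) {
      s <- cand[fr:len]
      nc <- length(s) %/% 3L
      any(vapply(seq_len(nc - 1L), function(k)
        paste(s[(3L * k - 2L):(3L * k)], collapse = "") %in% .STOPS5,
        logical(1L)))
    }, logical(1L)))
    if (ok) return(cand)
  }
  stop("could not plant stops in all frames")
}

#' Simulate a clone library with planted pseudogenes
#'
#' Draws `nSources` mutually distant source coding sequences (stop-free in
#' frame 1 under the invertebrate mitochondrial code), derives
#' `clonesPerSource` clones from each by substitution at rate `divergence`
#' (substitutions are re-drawn rather than allowed to create an in-frame
#' stop, so clean clones stay clean), then converts a chosen subset of clones
#' into pseudogene mimics by planting a stop codon in every forward frame.
#' The planted set is returned so filter recovery can be checked exactly.
#'
#' @param nSources Number of source species.
#' @param clonesPerSource Clones drawn per source.
#' @param nCodons Coding length in codons (default 220, ~660 nt).
#' @param divergence Per-site clone-to-source substitution rate (default
#'   0.01, within the species-level identity bound).
#' @param nPseudogenes Number of clones to convert (default 1 per 10 clones,
#'   at least 1).
#' @param seed Integer seed.
#' @return A list with `references` (sources as a [SeqLibrary-class]),
#'   `clones` (a [SeqLibrary-class] whose `groups` name the true source) and
#'   `pseudogeneIds` (character).
#' @export
genCloneLibrary <- function(nSources, clonesPerSource, nCodons = 220L,
                            divergence = 0.01, nPseudogenes = NULL, seed) {
  gc <- Biostrings::getGeneticCode("5")
  nSources <- as.integer(nSources)
  clonesPerSource <- as.integer(clonesPerSource)
  nclones <- nSources * clonesPerSource
  if (is.null(nPseudogenes)) nPseudogenes <- max(1L, nclones %/% 10L)
  .with_seed(seed, {
    refs <- stats::setNames(
      vapply(seq_len(nSources), function(i) .rand_coding(nCodons, gc),
             character(1L)),
      sprintf("source%02d", seq_len(nSources)))
    len <- 3L * nCodons
    cloneSeqs <- character(0)
    src <- character(0)
    for (i in seq_len(nSources)) {
      chars0 <- strsplit(refs[[i]], "", fixed = TRUE)[[1L]]
      for (k in seq_len(clonesPerSource)) {
        nmut <- stats::rbinom(1L, len, divergence)
        cloneSeqs <- c(cloneSeqs,
                       paste(.mutate_coding(chars0, nmut, gc), collapse = ""))
        src <- c(src, names(refs)[i])
      }
    }
    names(cloneSeqs) <- sprintf("clone%03d", seq_len(nclones))
    pseudo <- sort(sample(names(cloneSeqs), nPseudogenes))
    for (id in pseudo) {
      chars <- strsplit(cloneSeqs[[id]], "", fixed = TRUE)[[1L]]
      cloneSeqs[[id]] <- paste(.plant_stops(chars), collapse = "")
    }
    list(references = seqLibrary(refs, aligned = FALSE),
         clones = seqLibrary(cloneSeqs, groups = src, aligned = FALSE),
         pseudogeneIds = pseudo)
  })
}
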