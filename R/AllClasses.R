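## S4 class definitions and validity methods.

setOldClass("data.frame")

#' SeqLibrary: a grouped DNA sequence library
#'
#' Container for a collection of DNA sequences (optionally an alignment) with
#' an optional taxon-group label per record (e.g. `"decapod"`, `"fish"`,
#' `"gastropod"`). Sequences are held as a [Biostrings::DNAStringSet] over the
#' IUPAC alphabet plus the gap character `-`.
#'
#' @slot seqs A [Biostrings::DNAStringSet]; names are record ids, unique and
#'   non-empty.
#' @slot groups Character vector parallel to `seqs`; `NA` means ungrouped.
#' @slot aligned Logical flag; if `TRUE` all sequences must have equal length
#'   and positions are interpreted as 1-based alignment columns.
#' @seealso [seqLibrary()], [readFasta()]
#' @export
setClass("SeqLibrary",
  representation(seqs = "DNAStringSet", groups = "character",
                 aligned = "logical"))

setValidity("SeqLibrary", function(object) {
  ids <- names(object@seqs)
  msgs <- character()
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    msgs <- c(msgs, "all records must have non-empty ids")
  else if (anyDuplicated(ids))
    msgs <- c(msgs, paste("duplicated ids:",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object@groups) != length(object@seqs))
    msgs <- c(msgs, "groups must be parallel to seqs")
  if (length(object@aligned) != 1L || is.na(object@aligned))
    msgs <- c(msgs, "aligned must be TRUE or FALSE")
  w <- Biostrings::width(object@seqs)
  if (any(w == 0L))
    msgs <- c(msgs, "sequences must be non-empty")
  if (isTRUE(object@aligned) && length(w) > 0L && length(unique(w)) > 1L)
    msgs <- c(msgs, "aligned library has ragged sequence lengths")
  if (length(msgs)) msgs else TRUE
})

#' RestrictionEnzyme: a degenerate recognition motif
#'
#' A commercially available restriction enzyme described by its name, IUPAC
#' recognition sequence (effective length 6-15 bp, runs of N counting toward
#' the length, e.g. BstXI `CCANNNNNNTGG` has effective length 12), and an
#' optional cut offset within the site (0 = cut at the 5' boundary of the
#' matched site; enzyme catalogues rarely matter at single-base resolution
#' for screening, so fragment predictions are approximate).
#'
#' @slot name Enzyme name.
#' @slot site IUPAC recognition motif, uppercase.
#' @slot cutOffset Integer in `[0, nchar(site)]`.
#' @seealso [restrictionEnzyme()], [readEnzymeTable()], [scanSites()]
#' @export
setClass("RestrictionEnzyme",
  representation(name = "character", site = "character",
                 cutOffset = "integer"))

setValidity("RestrictionEnzyme", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msgs <- c(msgs, "name must be a non-empty string")
  site <- object@site
  if (length(site) != 1L || is.na(site) || !nzchar(site)) {
    msgs <- c(msgs, "site must be a non-empty string")
  } else {
    chars <- strsplit(site, "", fixed = TRUE)[[1L]]
    if (any(!.is_iupac(chars)))
      msgs <- c(msgs, paste0("site '", site, "' contains non-IUPAC characters"))
    if (nchar(site) < 6L || nchar(site) > 15L)
      msgs <- c(msgs, paste0("effective recognition length ", nchar(site),
                             " outside [6, 15]"))
  }
  off <- object@cutOffset
  if (length(off) != 1L || is.na(off) || off < 0L || off > nchar(site))
    msgs <- c(msgs, "cutOffset must lie in [0, nchar(site)]")
  if (length(msgs)) msgs else TRUE
})

#' PrimerDef: a (possibly degenerate) PCR primer
#'
#' @slot name Primer name (e.g. `"HCO2198"`).
#' @slot seq IUPAC DNA, written 5' to 3'.
#' @slot orientation `"forward"` or `"reverse"`.
#' @seealso [primerDef()], [evaluateVersatilePrimer()]
#' @export
setClass("PrimerDef",
  representation(name = "character", seq = "character",
                 orientation = "character"))

setValidity("PrimerDef", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "name must be a non-empty string")
  chars <- strsplit(object@seq, "", fixed = TRUE)[[1L]]
  if (!length(chars) || any(!.is_iupac(chars)))
    msgs <- c(msgs, "seq must be non-empty IUPAC DNA")
  if (!object@orientation %in% c("forward", "reverse"))
    msgs <- c(msgs, "orientation must be 'forward' or 'reverse'")
  if (length(msgs)) msgs else TRUE
})

#' PositionFrequencyMatrix: per-column base frequencies
#'
#' Fractions of unambiguous A/C/G/T per 1-based alignment column, the shape of
#' a published per-position frequency table. Gaps and ambiguity codes are
#' excluded from both numerator and denominator; a column with nothing to
#' count carries `NA` fractions (an undefined marker, not zeros).
#'
#' @slot positions Integer vector of 1-based alignment columns.
#' @slot freqs Numeric matrix, one row per position, columns `A`,`C`,`G`,`T`;
#'   each defined row sums to 1 within 1e-9.
#' @slot nCounted Integer vector of unambiguous bases counted per position
#'   (`NA` when unknown, e.g. a table read from a publication).
#' @seealso [positionFrequencyMatrix()], [columnFrequencies()],
#'   [readFrequencyTable()]
#' @export
setClass("PositionFrequencyMatrix",
  representation(positions = "integer", freqs = "matrix",
                 nCounted = "integer"))

setValidity("PositionFrequencyMatrix", function(object) {
  msgs <- character()
  np <- length(object@positions)
  f <- object@freqs
  if (!identical(colnames(f), c("A", "C", "G", "T")))
    msgs <- c(msgs, "freqs must have columns A, C, G, T")
  if (nrow(f) != np || length(object@nCounted) != np)
    msgs <- c(msgs, "positions, freqs rows and nCounted must be parallel")
  if (anyDuplicated(object@positions))
    msgs <- c(msgs, "positions must be unique")
  if (!length(msgs)) {
    defined <- !apply(is.na(f), 1L, all)
    if (any(is.na(f[defined, , drop = FALSE])))
      msgs <- c(msgs, "rows must be fully defined or fully NA")
    else {
      fd <- f[defined, , drop = FALSE]
      if (length(fd) && (any(fd < -1e-12) || any(fd > 1 + 1e-12)))
        msgs <- c(msgs, "frequencies must lie in [0, 1]")
      if (length(fd) && any(abs(rowSums(fd) - 1) > 1e-9))
        msgs <- c(msgs, "defined rows must sum to 1 within 1e-9")
      nc <- object@nCounted[defined]
      if (any(!is.na(nc) & nc == 0L))
        msgs <- c(msgs, "rows with nCounted = 0 must be NA")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' EntropyProfile: per-column Shannon entropy
#'
#' Shannon information content h(x) per alignment column, computed from a
#' [PositionFrequencyMatrix]. Zero at conserved columns; maximal (ln 4 nats,
#' or 2 bits) when all four bases are equifrequent.
#'
#' @slot positions Integer vector of 1-based columns.
#' @slot hx Numeric entropy per column (`NA` for undefined columns).
#' @slot base `"e"` (nats, the default) or `"2"` (bits).
#' @seealso [entropyProfile()]
#' @export
setClass("EntropyProfile",
  representation(positions = "integer", hx = "numeric", base = "character"))

setValidity("EntropyProfile", function(object) {
  msgs <- character()
  if (length(object@positions) != length(object@hx))
    msgs <- c(msgs, "positions and hx must be parallel")
  if (!object@base %in% c("e", "2"))
    msgs <- c(msgs, "base must be 'e' or '2'")
  hmax <- if (identical(object@base, "2")) 2 else log(4)
  h <- object@hx[!is.na(object@hx)]
  if (length(h) && (any(h < -1e-12) || any(h > hmax + 1e-9)))
    msgs <- c(msgs, sprintf("hx must lie in [0, %.6f]", hmax))
  if (length(msgs)) msgs else TRUE
})

#' CutReport: per-group cutting frequencies for one enzyme
#'
#' @slot enzyme Enzyme name.
#' @slot perGroup `data.frame` with columns `group`, `nCut`, `nTotal`,
#'   `frequency` (= nCut/nTotal exactly).
#' @slot overallFrequency Pooled cutting frequency over all records.
#' @slot nTotal Total number of records screened.
#' @seealso [cuttingFrequency()]
#' @export
setClass("CutReport",
  representation(enzyme = "character", perGroup = "data.frame",
                 overallFrequency = "numeric", nTotal = "integer"))

setValidity("CutReport", function(object) {
  pg <- object@perGroup
  msgs <- character()
  need <- c("group", "nCut", "nTotal", "frequency")
  if (!all(need %in% names(pg)))
    msgs <- c(msgs, "perGroup needs columns group, nCut, nTotal, frequency")
  else {
    if (any(pg$frequency != pg$nCut / pg$nTotal))
      msgs <- c(msgs, "frequency must equal nCut/nTotal exactly")
    if (sum(pg$nTotal) != object@nTotal)
      msgs <- c(msgs, "group totals must sum to nTotal")
  }
  if (length(msgs)) msgs else TRUE
})

#' EnzymeRanking: enzymes ranked for predator removal
#'
#' Enzymes that cut the predator sequence (`eligible`), ordered by ascending
#' unweighted mean of per-group prey cutting frequencies (ties broken by
#' enzyme name), against enzymes that do not (`excluded`).
#'
#' @slot table `data.frame` over the eligible enzymes, in rank order, with
#'   columns `enzyme`, `predatorHits`, `meanPreyFrequency` and one
#'   `freq.<group>` column per prey group.
#' @slot excluded Character vector of enzymes with no predator site.
#' @seealso [rankEnzymes()]
#' @export
setClass("EnzymeRanking",
  representation(table = "data.frame", excluded = "character"))

setValidity("EnzymeRanking", function(object) {
  msgs <- character()
  if (length(intersect(object@table$enzyme, object@excluded)))
    msgs <- c(msgs, "eligible and excluded enzymes must be disjoint")
  mp <- object@table$meanPreyFrequency
  if (length(mp) > 1L && is.unsorted(mp))
    msgs <- c(msgs, "eligible enzymes must be sorted by ascending mean prey frequency")
  if (length(msgs)) msgs else TRUE
})

#' AnchorWindow: the 3'-terminal binding window of a blocking primer
#'
#' A closed interval of alignment columns (length k, default 4) together with
#' the predator's unambiguous bases across it, e.g. the predator-specific
#' `TCTT` tetramer that discriminates a predator from its prey.
#'
#' @slot start,end 1-based alignment columns, closed interval.
#' @slot predatorBases Unambiguous ACGT string of length `end - start + 1`,
#'   read from the predator row of the alignment.
#' @seealso [anchorWindow()], [mismatchProbability()], [selectAnchor()]
#' @export
setClass("AnchorWindow",
  representation(start = "integer", end = "integer",
                 predatorBases = "character"))

setValidity("AnchorWindow", function(object) {
  msgs <- character()
  k <- object@end - object@start + 1L
  if (object@start < 1L || k < 1L)
    msgs <- c(msgs, "window must be a non-empty closed interval of columns >= 1")
  b <- strsplit(object@predatorBases, "", fixed = TRUE)[[1L]]
  if (length(b) != k)
    msgs <- c(msgs, "predatorBases length must equal window length")
  if (any(!b %in% c("A", "C", "G", "T")))
    msgs <- c(msgs, "predatorBases must be unambiguous ACGT")
  if (length(msgs)) msgs else TRUE
})

#' BlockingPrimerDesign: a predator-specific annealing blocking primer
#'
#' The primer sequence (5' to 3'), the alignment span it covers, its anchor
#' window, the number of bases shared with the versatile primer binding
#' region, the 3' elongation-blocking modification (an annotation, never a
#' base), and optionally per-prey-group mismatch probabilities.
#'
#' @slot primerSeq Primer 5'->3', ACGT.
#' @slot orientation `"reverse"` (competes with the reverse versatile primer;
#'   the usual case) or `"forward"`.
#' @slot spanStart,spanEnd Alignment columns covered (closed).
#' @slot templateSeq The predator row over the span, in forward-strand
#'   orientation (the primer's template-orientation sequence).
#' @slot anchor An [AnchorWindow-class].
#' @slot overlapLen Bases falling inside the versatile primer region.
#' @slot threePrimeMod Annotation for the 3' modification (default
#'   `"SpacerC3"`).
#' @slot perGroupMismatchProb Named numeric, possibly empty.
#' @seealso [buildBlockingPrimer()], [profileMismatches()]
#' @export
setClass("BlockingPrimerDesign",
  representation(primerSeq = "character", orientation = "character",
                 spanStart = "integer", spanEnd = "integer",
                 templateSeq = "character", anchor = "AnchorWindow",
                 overlapLen = "integer", threePrimeMod = "character",
                 perGroupMismatchProb = "numeric"))

setValidity("BlockingPrimerDesign", function(object) {
  msgs <- character()
  span <- object@spanEnd - object@spanStart + 1L
  if (nchar(object@templateSeq) != span)
    msgs <- c(msgs, "templateSeq must cover the span")
  if (nchar(object@primerSeq) != span)
    msgs <- c(msgs, "primerSeq must cover the span")
  if (!object@orientation %in% c("forward", "reverse"))
    msgs <- c(msgs, "orientation must be 'forward' or 'reverse'")
  a <- object@anchor
  if (a@start < object@spanStart || a@end > object@spanEnd)
    msgs <- c(msgs, "anchor must lie within the primer span")
  else {
    tmpl_anchor <- substr(object@templateSeq,
                          a@start - object@spanStart + 1L,
                          a@end - object@spanStart + 1L)
    if (!identical(tmpl_anchor, a@predatorBases))
      msgs <- c(msgs,
        "primer 3'-terminal bases must equal the anchor predator bases on the template orientation")
  }
  p <- object@perGroupMismatchProb
  if (length(p) && (any(p < 0) || any(p > 1)))
    msgs <- c(msgs, "mismatch probabilities must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' PDistMatrix: uncorrected pairwise distances
#'
#' Symmetric matrix of uncorrected p-distances under pairwise deletion (for
#' each pair, columns where either sequence carries a gap or ambiguity code
#' are excluded), with the number of columns actually compared per pair.
#'
#' @slot d Symmetric numeric matrix in `[0, 1]`, zero diagonal, dimnames =
#'   record ids.
#' @slot comparedLen Integer matrix of compared columns per pair.
#' @seealso [pDistance()]
#' @export
setClass("PDistMatrix",
  representation(d = "matrix", comparedLen = "matrix"))

setValidity("PDistMatrix", function(object) {
  d <- object@d
  msgs <- character()
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    msgs <- c(msgs, "d must have matching row/col ids")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    msgs <- c(msgs, "d must be symmetric")
  if (any(diag(d) != 0))
    msgs <- c(msgs, "diagonal must be zero")
  if (any(d < 0) || any(d > 1))
    msgs <- c(msgs, "distances must lie in [0, 1]")
  if (!identical(dim(object@comparedLen), dim(d)))
    msgs <- c(msgs, "comparedLen must be conformable with d")
  if (length(msgs)) msgs else TRUE
})

#' ThresholdScan: OTU counts across dissimilarity thresholds
#'
#' OTU counts from furthest-neighbor clustering at each threshold of an
#' ascending grid, with the longest constant run (the plateau) and the stable
#' threshold (the plateau start) from step-function analysis.
#'
#' @slot thresholds Ascending numeric fractions.
#' @slot otuCounts Integer OTU count per threshold (non-increasing).
#' @slot plateauStart,plateauEnd Thresholds bounding the longest constant run
#'   (earliest run on ties).
#' @slot plateauCount OTU count on the plateau.
#' @seealso [thresholdScan()], [otuPlateau()]
#' @export
setClass("ThresholdScan",
  representation(thresholds = "numeric", otuCounts = "integer",
                 plateauStart = "numeric", plateauEnd = "numeric",
                 plateauCount = "integer"))

setValidity("ThresholdScan", function(object) {
  msgs <- character()
  if (length(object@thresholds) != length(object@otuCounts))
    msgs <- c(msgs, "thresholds and otuCounts must be parallel")
  if (is.unsorted(object@thresholds, strictly = TRUE))
    msgs <- c(msgs, "thresholds must be strictly ascending")
  if (any(diff(object@otuCounts) > 0L))
    msgs <- c(msgs, "OTU counts must be non-increasing in threshold")
  if (length(msgs)) msgs else TRUE
})

#' OTUClustering: a furthest-neighbor partition at one threshold
#'
#' @slot threshold The dissimilarity threshold used.
#' @slot clusters Named integer vector: record id -> cluster label.
#' @slot representatives Named character vector: cluster label (as character)
#'   -> representative id (empty until [pickRepresentatives()] is applied).
#' @seealso [furthestNeighbor()], [pickRepresentatives()]
#' @export
setClass("OTUClustering",
  representation(threshold = "numeric", clusters = "integer",
                 representatives = "character"))

setValidity("OTUClustering", function(object) {
  msgs <- character()
  if (is.null(names(object@clusters)) || any(!nzchar(names(object@clusters))))
    msgs <- c(msgs, "every id must be labelled")
  reps <- object@representatives
  if (length(reps)) {
    lab <- object@clusters[reps]
    if (any(is.na(lab)) || any(as.character(lab) != names(reps)))
      msgs <- c(msgs, "each representative must be a member of its cluster")
  }
  if (length(msgs)) msgs else TRUE
})

#' AssignmentPolicy: identity threshold for species-level assignment
#'
#' @slot speciesMinIdentity Fraction in `(0, 1]`; default 0.98, the customary
#'   species-level barcode identity bound (inclusive).
#' @seealso [assignmentPolicy()], [assignIdentity()]
#' @export
setClass("AssignmentPolicy",
  representation(speciesMinIdentity = "numeric"))

setValidity("AssignmentPolicy", function(object) {
  p <- object@speciesMinIdentity
  if (length(p) != 1L || is.na(p) || p <= 0 || p > 1)
    "speciesMinIdentity must lie in (0, 1]" else TRUE
})
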