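## Constructors, accessors and show methods for the core containers.

#' Construct a SeqLibrary
#'
#' @param seqs A named character vector or [Biostrings::DNAStringSet]
#'   (uppercased on construction; `U` is rejected, DNA only).
#' @param groups Optional character vector of taxon-group labels, either
#'   parallel to `seqs` or named by record id; `NA` = ungrouped.
#' @param aligned Logical; assert that the sequences form an alignment
#'   (uniform length, `-` for gaps).
#' @return A [SeqLibrary-class] object.
#' @examples
#' lib <- seqLibrary(c(s1 = "ACGT", s2 = "ACGA"),
#'                   groups = c("decapod", "fish"), aligned = TRUE)
#' seqIds(lib)
#' @export
seqLibrary <- function(seqs, groups = NULL, aligned = FALSE) {
  if (!methods::is(seqs, "DNAStringSet")) {
    if (!is.character(seqs))
      stop("seqs must be a named character vector or DNAStringSet")
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  ids <- names(seqs)
  if (is.null(groups)) {
    groups <- rep(NA_character_, length(seqs))
  } else if (!is.null(names(groups))) {
    groups <- unname(groups[ids])
  } else {
    groups <- as.character(groups)
  }
  methods::new("SeqLibrary", seqs = seqs, groups = groups,
               aligned = isTRUE(aligned))
}

#' @describeIn seqLibrary Record ids, in order.
#' @param x A `SeqLibrary`.
#' @export
seqIds <- function(x) names(x@seqs)

#' @describeIn seqLibrary Group labels (`NA` where ungrouped).
#' @export
seqGroups <- function(x) x@groups

#' @describeIn seqLibrary Is the library flagged as an alignment?
#' @export
isAligned <- function(x) x@aligned

#' @describeIn seqLibrary The sequences as a [Biostrings::DNAStringSet].
#' @export
seqSet <- function(x) x@seqs

setMethod("length", "SeqLibrary", function(x) length(x@seqs))

setMethod("as.character", "SeqLibrary", function(x) {
  out <- as.character(x@seqs)
  names(out) <- names(x@seqs)
  out
})

setMethod("[", "SeqLibrary", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@seqs))
  methods::new("SeqLibrary", seqs = x@seqs[i], groups = x@groups[i],
               aligned = x@aligned)
})

setMethod("show", "SeqLibrary", function(object) {
  w <- Biostrings::width(object@seqs)
  cat(sprintf("SeqLibrary of %d sequence%s%s\n", length(object@seqs),
              if (length(object@seqs) == 1L) "" else "s",
              if (object@aligned)
                sprintf(", aligned (%d columns)", if (length(w)) w[1L] else 0L)
              else ""))
  tab <- table(ifelse(is.na(object@groups), "<ungrouped>", object@groups))
  cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
})

#' Construct a RestrictionEnzyme
#'
#' @param name Enzyme name.
#' @param site IUPAC recognition motif (effective length 6-15; N runs count).
#' @param cutOffset Cut position within the site, default 0 (5' boundary).
#' @return A [RestrictionEnzyme-class] object.
#' @examples
#' restrictionEnzyme("EcoRI", "GAATTC")
#' restrictionEnzyme("BstXI", "CCANNNNNNTGG")
#' @export
restrictionEnzyme <- function(name, site, cutOffset = 0L) {
  methods::new("RestrictionEnzyme", name = as.character(name),
               site = toupper(as.character(site)),
               cutOffset = as.integer(cutOffset))
}

setMethod("show", "RestrictionEnzyme", function(object) {
  cat(sprintf("RestrictionEnzyme %s: %s (%d bp, cut offset %d)\n",
              object@name, object@site, nchar(object@site), object@cutOffset))
})

#' Construct a PrimerDef
#'
#' @param name Primer name.
#' @param seq IUPAC DNA, 5' to 3'.
#' @param orientation `"forward"` or `"reverse"`.
#' @return A [PrimerDef-class] object.
#' @examples
#' primerDef("LCO1490", "GGTCAACAAATCATAAAGATATTGG", "forward")
#' @export
primerDef <- function(name, seq, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  methods::new("PrimerDef", name = as.character(name),
               seq = toupper(gsub("[[:space:]]", "", seq)),
               orientation = orientation)
}

setMethod("show", "PrimerDef", function(object) {
  cat(sprintf("PrimerDef %s (%s): 5'-%s-3' (%d nt)\n", object@name,
              object@orientation, object@seq, nchar(object@seq)))
})

#' Construct a PositionFrequencyMatrix
#'
#' @param positions Integer 1-based alignment columns.
#' @param freqs Numeric matrix (rows = positions) with columns `A`,`C`,`G`,`T`
#'   in any order; rows are renormalized to sum to 1 when they are within
#'   `renormTol` of 1 (printed tables round to one decimal), otherwise an
#'   error is raised. Fully-`NA` rows are kept as undefined markers.
#' @param nCounted Integer vector of counted bases per position; `NA` when
#'   unknown.
#' @param renormTol Maximum |row sum - 1| that is silently renormalized.
#' @return A [PositionFrequencyMatrix-class] object.
#' @export
positionFrequencyMatrix <- function(positions, freqs, nCounted = NA_integer_,
                                    renormTol = 0.05) {
  positions <- as.integer(positions)
  if (is.null(colnames(freqs)) || !all(c("A", "C", "G", "T") %in% colnames(freqs)))
    stop("freqs must have columns A, C, G, T")
  freqs <- as.matrix(freqs)[, c("A", "C", "G", "T"), drop = FALSE]
  storage.mode(freqs) <- "double"
  nCounted <- rep_len(as.integer(nCounted), length(positions))
  defined <- !apply(is.na(freqs), 1L, all)
  s <- rowSums(freqs[defined, , drop = FALSE])
  if (any(abs(s - 1) > renormTol))
    stop("frequency rows must sum to 1 (within ", renormTol, "); worst sum = ",
         format(s[which.max(abs(s - 1))]))
  freqs[defined, ] <- freqs[defined, , drop = FALSE] / s
  rownames(freqs) <- positions
  methods::new("PositionFrequencyMatrix", positions = positions,
               freqs = freqs, nCounted = nCounted)
}

#' @describeIn positionFrequencyMatrix Alignment columns covered.
#' @param x A `PositionFrequencyMatrix`.
#' @export
pfmPositions <- function(x) x@positions

#' @describeIn positionFrequencyMatrix The frequency matrix (rows named by
#'   position, columns `A`,`C`,`G`,`T`).
#' @export
pfmFreqs <- function(x) x@freqs

#' @describeIn positionFrequencyMatrix Unambiguous bases counted per position.
#' @export
pfmCounts <- function(x) x@nCounted

#' @describeIn positionFrequencyMatrix Frequency of `base` at alignment column
#'   `position` (errors if the column is absent; `NA` if undefined).
#' @param position 1-based alignment column.
#' @param base One of `"A"`,`"C"`,`"G"`,`"T"`.
#' @export
baseFreq <- function(x, position, base) {
  i <- match(as.integer(position), x@positions)
  if (any(is.na(i)))
    stop("position(s) ", paste(position[is.na(i)], collapse = ", "),
         " not covered by this frequency matrix")
  x@freqs[cbind(i, match(toupper(base), colnames(x@freqs)))]
}

setMethod("show", "PositionFrequencyMatrix", function(object) {
  cat(sprintf("PositionFrequencyMatrix over %d column%s (%d..%d)\n",
              length(object@positions),
              if (length(object@positions) == 1L) "" else "s",
              min(object@positions), max(object@positions)))
  print(utils::head(round(object@freqs, 4), 6L))
  if (length(object@positions) > 6L) cat("  ...\n")
})

setMethod("show", "EntropyProfile", function(object) {
  unit <- if (identical(object@base, "2")) "bits" else "nats"
  cat(sprintf("EntropyProfile over %d columns (%s); h(x) range [%.4f, %.4f]\n",
              length(object@positions), unit,
              min(object@hx, na.rm = TRUE), max(object@hx, na.rm = TRUE)))
})

setMethod("show", "CutReport", function(object) {
  cat(sprintf("CutReport for %s: overall %d/%d cut (%.1f%%)\n", object@enzyme,
              as.integer(round(object@overallFrequency * object@nTotal)),
              object@nTotal, 100 * object@overallFrequency))
  print(object@perGroup, row.names = FALSE)
})

setMethod("show", "EnzymeRanking", function(object) {
  cat(sprintf("EnzymeRanking: %d eligible (cut the predator), %d excluded\n",
              nrow(object@table), length(object@excluded)))
  if (nrow(object@table)) print(utils::head(object@table, 10L), row.names = FALSE)
})

#' Construct an AnchorWindow
#'
#' @param start,end Closed interval of 1-based alignment columns.
#' @param predatorBases Unambiguous ACGT bases of the predator across the
#'   window (length `end - start + 1`).
#' @return An [AnchorWindow-class] object.
#' @examples
#' anchorWindow(640, 643, "TCTT")
#' @export
anchorWindow <- function(start, end, predatorBases) {
  methods::new("AnchorWindow", start = as.integer(start), end = as.integer(end),
               predatorBases = toupper(as.character(predatorBases)))
}

setMethod("show", "AnchorWindow", function(object) {
  cat(sprintf("AnchorWindow %d..%d: predator bases %s\n", object@start,
              object@end, object@predatorBases))
})

setMethod("show", "BlockingPrimerDesign", function(object) {
  cat(sprintf("BlockingPrimerDesign (%s orientation, 3' %s)\n",
              object@orientation, object@threePrimeMod))
  cat(sprintf("  primer 5'-%s-3' (%d nt), columns %d..%d, overlap %d nt\n",
              object@primerSeq, nchar(object@primerSeq), object@spanStart,
              object@spanEnd, object@overlapLen))
  cat(sprintf("  anchor %d..%d (%s)\n", object@anchor@start, object@anchor@end,
              object@anchor@predatorBases))
  p <- object@perGroupMismatchProb
  if (length(p))
    cat("  mismatch prob:",
        paste(sprintf("%s %.3f", names(p), p), collapse = ", "), "\n")
})

setMethod("show", "PDistMatrix", function(object) {
  cat(sprintf("PDistMatrix over %d sequences; distances in [%.4f, %.4f]\n",
              nrow(object@d), min(object@d[upper.tri(object@d)]),
              max(object@d)))
})

setMethod("show", "ThresholdScan", function(object) {
  cat("ThresholdScan:\n")
  print(data.frame(threshold = object@thresholds, otus = object@otuCounts),
        row.names = FALSE)
  cat(sprintf("  plateau: %d OTUs from %.2f to %.2f (stable threshold %.2f)\n",
              object@plateauCount, object@plateauStart, object@plateauEnd,
              object@plateauStart))
})

setMethod("show", "OTUClustering", function(object) {
  cat(sprintf("OTUClustering at threshold %.3f: %d OTUs over %d sequences\n",
              object@threshold, length(unique(object@clusters)),
              length(object@clusters)))
})

#' Construct an AssignmentPolicy
#'
#' @param speciesMinIdentity Minimum identity fraction for species-level
#'   assignment (inclusive); default 0.98.
#' @return An [AssignmentPolicy-class] object.
#' @export
assignmentPolicy <- function(speciesMinIdentity = 0.98) {
  methods::new("AssignmentPolicy",
               speciesMinIdentity = as.numeric(speciesMinIdentity))
}

setMethod("show", "AssignmentPolicy", function(object) {
  cat(sprintf("AssignmentPolicy: assign to species at identity >= %.3f\n",
              object@speciesMinIdentity))
})

## -- accessors used across modules -------------------------------------------

#' Thresholds and OTU counts of a scan
#' @param x A [ThresholdScan-class].
#' @return `scanThresholds`/`scanCounts` return numeric/integer vectors;
#'   `stableThreshold` the plateau start.
#' @export
scanThresholds <- function(x) x@thresholds

#' @rdname scanThresholds
#' @export
scanCounts <- function(x) x@otuCounts

#' @rdname scanThresholds
#' @export
stableThreshold <- function(x) x@plateauStart

#' Cluster membership and representatives
#' @param x An [OTUClustering-class].
#' @return `otuLabels` returns the named id -> cluster vector;
#'   `otuRepresentatives` the cluster -> representative id vector.
#' @export
otuLabels <- function(x) x@clusters

#' @rdname otuLabels
#' @export
otuRepresentatives <- function(x) x@representatives
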