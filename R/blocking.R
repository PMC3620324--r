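## Blocking-primer design: anchor selection by mismatch probability,
## primer construction/validation, and per-prey mismatch profiling.

#' Probability of at least one mismatch at the anchor
#'
#' For a prey group with per-column base frequencies `pfm` and a predator
#' anchor (the 3'-terminal bases of the blocking primer), the probability
#' that a random prey template differs from the predator at one or more
#' anchor positions is `1 - prod(P(predator base at position))`, columns
#' treated as independent. High values mean the primer is unlikely to block
#' prey amplification.
#'
#' @param pfm A [PositionFrequencyMatrix-class] covering the anchor columns
#'   for one prey group.
#' @param anchor An [AnchorWindow-class].
#' @return Probability in `[0, 1]`.
#' @examples
#' pfms <- anchorSiteFrequencies()
#' mismatchProbability(pfms$decapod, anchorWindow(640, 643, "TCTT"))
#' @export
mismatchProbability <- function(pfm, anchor) {
  stopifnot(methods::is(pfm, "PositionFrequencyMatrix"),
            methods::is(anchor, "AnchorWindow"))
  cols <- seq.int(anchor@start, anchor@end)
  bases <- strsplit(anchor@predatorBases, "", fixed = TRUE)[[1L]]
  f <- baseFreq(pfm, cols, bases)
  if (anyNA(f))
    stop("anchor column(s) ", paste(cols[is.na(f)], collapse = ", "),
         " are undefined in the frequency matrix")
  1 - prod(f)
}

#' @describeIn mismatchProbability Apply over a named list of per-group
#'   frequency matrices; returns a named probability vector.
#' @param pfmByGroup Named list of [PositionFrequencyMatrix-class] objects.
#' @export
groupMismatchProbabilities <- function(pfmByGroup, anchor) {
  vapply(pfmByGroup, mismatchProbability, numeric(1L), anchor = anchor)
}

#' Rank candidate anchor windows
#'
#' Slides a window of `k` columns across `searchRange` on the predator row
#' and ranks admissible windows by descending minimum-over-groups mismatch
#' probability (the worst-case prey group decides). Windows whose probability
#' falls below `minProb` for any group are dropped. Ties are broken by higher
#' mean entropy over the window, then by smaller start column.
#'
#' @param entropy An [EntropyProfile-class] covering the search range (used
#'   only for tie-breaking).
#' @param pfmByGroup Named list of per-group
#'   [PositionFrequencyMatrix-class] objects covering the search range.
#' @param predatorRow The predator's aligned sequence (full row, or any
#'   string indexable by alignment column); must be unambiguous ACGT over the
#'   search range.
#' @param k Anchor length in columns (default 4).
#' @param searchRange Length-2 integer vector `c(from, to)` of alignment
#'   columns to search (closed).
#' @param minProb Per-group floor on the mismatch probability: a single
#'   number, or a named vector by group (default 0 = no floor).
#' @return A `data.frame`, one row per admissible window in rank order, with
#'   columns `start`, `end`, `predatorBases`, `minProb`, `meanEntropy` and
#'   one `prob.<group>` column per group. Zero rows when every window fails
#'   the floor.
#' @export
selectAnchor <- function(entropy, pfmByGroup, predatorRow, k = 4L,
                         searchRange, minProb = 0) {
  stopifnot(methods::is(entropy, "EntropyProfile"))
  searchRange <- as.integer(searchRange)
  if (length(searchRange) != 2L || searchRange[2L] < searchRange[1L] ||
      searchRange[2L] - searchRange[1L] + 1L < k)
    stop("empty or too-short search range")
  row <- toupper(as.character(predatorRow)[1L])
  cols <- seq.int(searchRange[1L], searchRange[2L])
  rowChars <- strsplit(row, "", fixed = TRUE)[[1L]]
  if (length(rowChars) < searchRange[2L])
    stop("predator row does not cover the search range")
  if (any(!rowChars[cols] %in% c("A", "C", "G", "T")))
    stop("predator row must be unambiguous ACGT over the search range")
  floors <- if (is.null(names(minProb)))
    stats::setNames(rep_len(minProb, length(pfmByGroup)), names(pfmByGroup))
  else minProb
  hx <- entropyValues(entropy)
  starts <- seq.int(searchRange[1L], searchRange[2L] - k + 1L)
  rows <- lapply(starts, function(s) {
    a <- anchorWindow(s, s + k - 1L,
                      paste(rowChars[s:(s + k - 1L)], collapse = ""))
    p <- groupMismatchProbabilities(pfmByGroup, a)
    if (any(p < floors[names(p)])) return(NULL)
    he <- hx[as.character(s:(s + k - 1L))]
    c(list(start = s, end = s + k - 1L, predatorBases = a@predatorBases,
           minProb = min(p), meanEntropy = mean(he)),
      as.list(stats::setNames(p, paste0("prob.", names(p)))))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    out <- data.frame(start = integer(), end = integer(),
                      predatorBases = character(), minProb = numeric(),
                      meanEntropy = numeric())
    return(out)
  }
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  tab <- tab[order(-tab$minProb, -tab$meanEntropy, tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Construct a predator-specific annealing blocking primer
#'
#' The primer spans contiguously from the versatile-primer overlap into the
#' predator-specific sequence, with its 3' end at the anchor window and
#' exactly `overlap` bases inside the versatile primer binding region. The
#' orientation is chosen from the geometry: when the versatile region lies on
#' the 3' side of the anchor (higher columns, the usual case of competing
#' with the reverse versatile primer), the primer is emitted 5'->3' on the
#' reverse strand; the mirrored layout yields a forward-orientation primer.
#' The elongation-blocking 3' modification (default Spacer C3) is recorded as
#' an annotation, never as a base.
#'
#' @param predatorRow The predator's aligned row (gap-free over the spanned
#'   interval).
#' @param versatileRegion Length-2 vector of alignment columns (closed) where
#'   the versatile primer binds.
#' @param anchor An [AnchorWindow-class] on the predator row.
#' @param overlap Bases shared with the versatile primer region (default 10).
#' @param maxLen Maximum primer length (default 30; designs aim for < 30 bp
#'   to keep melting temperature low).
#' @param threePrimeMod Annotation string (default `"SpacerC3"`).
#' @return A [BlockingPrimerDesign-class].
#' @examples
#' row <- paste(rep("ACGT", 10), collapse = "")  # 40-column toy row
#' buildBlockingPrimer(row, c(31, 40), anchorWindow(25, 28, "ACGT"))
#' @export
buildBlockingPrimer <- function(predatorRow, versatileRegion, anchor,
                                overlap = 10L, maxLen = 30L,
                                threePrimeMod = "SpacerC3") {
  stopifnot(methods::is(anchor, "AnchorWindow"))
  row <- toupper(as.character(predatorRow)[1L])
  vr <- as.integer(versatileRegion)
  overlap <- as.integer(overlap)
  if (length(vr) != 2L || vr[2L] < vr[1L])
    stop("versatileRegion must be a closed column interval c(start, end)")
  if (overlap < 1L || overlap > vr[2L] - vr[1L] + 1L)
    stop("overlap must lie in [1, length of the versatile region]")
  if (vr[1L] > anchor@end) {
    orientation <- "reverse"
    spanStart <- anchor@start
    spanEnd <- vr[1L] + overlap - 1L
  } else if (vr[2L] < anchor@start) {
    orientation <- "forward"
    spanStart <- vr[2L] - overlap + 1L
    spanEnd <- anchor@end
  } else {
    stop("versatile region must not overlap the anchor window")
  }
  if (spanEnd > nchar(row) || spanStart < 1L)
    stop("primer span ", spanStart, "..", spanEnd,
         " falls outside the predator row")
  len <- spanEnd - spanStart + 1L
  if (len > maxLen)
    stop("required span (", len, " nt) exceeds maxLen (", maxLen, ")")
  template <- substr(row, spanStart, spanEnd)
  if (grepl("-", template, fixed = TRUE))
    stop("gap in predator row within the primer span ",
         spanStart, "..", spanEnd)
  template <- .check_iupac_string(template, "predator row span")
  primer <- if (identical(orientation, "reverse")) revComp(template)
            else template
  methods::new("BlockingPrimerDesign", primerSeq = primer,
               orientation = orientation, spanStart = spanStart,
               spanEnd = spanEnd, templateSeq = template, anchor = anchor,
               overlapLen = overlap, threePrimeMod = threePrimeMod,
               perGroupMismatchProb = numeric())
}

#' @describeIn buildBlockingPrimer Attach per-group anchor mismatch
#'   probabilities to a design.
#' @param design A [BlockingPrimerDesign-class].
#' @param pfmByGroup Named list of per-group frequency matrices.
#' @export
addMismatchProbabilities <- function(design, pfmByGroup) {
  design@perGroupMismatchProb <-
    groupMismatchProbabilities(pfmByGroup, design@anchor)
  methods::validObject(design)
  design
}

#' Validate a blocking primer sequence
#'
#' Checks an ordered (or published) blocking primer against the design
#' constraints: length within `maxLen` and a pure-ACGT alphabet. The 3'
#' elongation-blocking modification is carried as an annotation in the
#' output, as in design objects.
#'
#' @param primerSeq Primer 5'->3'.
#' @param maxLen Length bound (default 30).
#' @param threePrimeMod Annotation (default `"SpacerC3"`).
#' @return A list with elements `primerSeq`, `length`, `withinMaxLen`,
#'   `alphabetACGT`, `ok` and `threePrimeMod`.
#' @export
validateBlockingPrimer <- function(primerSeq, maxLen = 30L,
                                   threePrimeMod = "SpacerC3") {
  s <- toupper(gsub("[[:space:]]", "", as.character(primerSeq)[1L]))
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  acgt <- length(chars) > 0L && all(chars %in% c("A", "C", "G", "T"))
  within <- nchar(s) <= maxLen
  list(primerSeq = s, length = nchar(s), withinMaxLen = within,
       alphabetACGT = acgt, ok = within && acgt,
       threePrimeMod = threePrimeMod)
}

#' Profile prey mismatches against a blocking primer
#'
#' For each prey sequence of an alignment sharing the design's coordinate
#' system, reports the alignment columns within `window` where the prey base
#' is incompatible with the primer's template-orientation base
#' (IUPAC-aware: a mismatch iff the expansion sets do not intersect, so an N
#' never counts as a mismatch — conservative toward flagging the risk of
#' blocking prey; a gap always counts), plus the mismatch count within the
#' anchor columns (the first k bases of the primer's 3' end).
#'
#' @param design A [BlockingPrimerDesign-class].
#' @param preyAlignment An aligned [SeqLibrary-class] in the same coordinate
#'   system.
#' @param window Length-2 vector of alignment columns to profile (closed);
#'   default: the full primer span.
#' @return A `data.frame` with columns `seqId`, `mismatchesFirstK`,
#'   `nMismatches` and `mismatchPositions` (comma-separated columns).
#' @export
profileMismatches <- function(design, preyAlignment, window = NULL) {
  stopifnot(methods::is(design, "BlockingPrimerDesign"),
            methods::is(preyAlignment, "SeqLibrary"))
  if (!isAligned(preyAlignment))
    stop("profileMismatches requires an aligned prey library")
  width <- Biostrings::width(seqSet(preyAlignment))[1L]
  if (is.null(window)) window <- c(design@spanStart, design@spanEnd)
  window <- as.integer(window)
  if (window[1L] < 1L || window[2L] > width || window[2L] < window[1L])
    stop("window ", window[1L], "..", window[2L],
         " outside alignment columns 1..", width)
  cols <- seq.int(window[1L], window[2L])
  incover <- cols >= design@spanStart & cols <= design@spanEnd
  if (!all(incover))
    stop("window extends beyond the primer span ",
         design@spanStart, "..", design@spanEnd)
  tmpl <- strsplit(design@templateSeq, "", fixed = TRUE)[[1L]]
  tmplWin <- tmpl[cols - design@spanStart + 1L]
  anchorCols <- seq.int(design@anchor@start, design@anchor@end)
  seqs <- as.character(preyAlignment)
  rows <- lapply(seqIds(preyAlignment), function(id) {
    prey <- strsplit(seqs[[id]], "", fixed = TRUE)[[1L]][cols]
    mm <- !iupacCompatible(tmplWin, prey)
    mmCols <- cols[mm]
    data.frame(seqId = id,
               mismatchesFirstK = sum(mmCols %in% anchorCols),
               nMismatches = sum(mm),
               mismatchPositions = paste(mmCols, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate a versatile primer against a library
#'
#' Finds the best ungapped sliding-window placement of the primer on each
#' sequence (IUPAC-aware: a position matches iff the expansion sets
#' intersect, so a degenerate primer base such as Y matches either C or T)
#' and reports the total mismatch count and the count within the 3'-terminal
#' 5 bases of the primer — the positions that matter most for extension.
#' Reverse-orientation primers are aligned as their reverse complement on the
#' forward strand.
#'
#' @param primer A [PrimerDef-class].
#' @param library A [SeqLibrary-class] (gaps stripped per sequence).
#' @param threePrimeBases Size of the 3'-terminal window (default 5).
#' @return A `data.frame` with columns `seqId`, `start` (forward-strand
#'   offset of the best placement), `totalMismatches`,
#'   `threePrimeMismatches`.
#' @export
evaluateVersatilePrimer <- function(primer, library, threePrimeBases = 5L) {
  stopifnot(methods::is(primer, "PrimerDef"),
            methods::is(library, "SeqLibrary"))
  pat <- if (identical(primer@orientation, "reverse")) revComp(primer@seq)
         else primer@seq
  patChars <- strsplit(pat, "", fixed = TRUE)[[1L]]
  m <- length(patChars)
  ## indices (within the pattern) of the primer's 3'-terminal bases
  tp <- if (identical(primer@orientation, "reverse"))
    seq_len(min(threePrimeBases, m))
  else seq.int(m - min(threePrimeBases, m) + 1L, m)
  rows <- lapply(seqIds(library), function(id) {
    s <- .strip_gaps(as.character(library)[[id]])
    sChars <- strsplit(s, "", fixed = TRUE)[[1L]]
    n <- length(sChars)
    if (m > n) stop("primer ", primer@name, " longer than sequence ", id)
    best <- NULL
    for (off in 0:(n - m)) {
      mm <- !iupacCompatible(patChars, sChars[off + seq_len(m)])
      if (is.null(best) || sum(mm) < best$total) {
        best <- list(start = off + 1L, total = sum(mm), tp = sum(mm[tp]))
        if (best$total == 0L) break
      }
    }
    data.frame(seqId = id, start = best$start, totalMismatches = best$total,
               threePrimeMismatches = best$tp, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
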