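## Per-column nucleotide frequencies and Shannon entropy over an alignment.

#' Per-column base frequencies of an alignment
#'
#' Counts of unambiguous A/C/G/T per alignment column, normalized to
#' fractions. Gaps and ambiguity codes are excluded from both numerator and
#' denominator (published per-position tables sum to 100% over A/C/T/G only);
#' a column with nothing to count is reported as undefined (`NA`), not as
#' zeros.
#'
#' @param alignment An aligned [SeqLibrary-class].
#' @param positions Optional integer vector of 1-based columns to restrict to
#'   (default: all columns).
#' @return A [PositionFrequencyMatrix-class].
#' @examples
#' aln <- seqLibrary(c(a = "TTGA", b = "TTGA", c = "CNGA", d = "C-GA"),
#'                   aligned = TRUE)
#' pfmFreqs(columnFrequencies(aln))
#' @export
columnFrequencies <- function(alignment, positions = NULL) {
  stopifnot(methods::is(alignment, "SeqLibrary"))
  if (!isAligned(alignment))
    stop("columnFrequencies requires an aligned library")
  cm <- Biostrings::consensusMatrix(seqSet(alignment))
  width <- ncol(cm)
  if (is.null(positions)) positions <- seq_len(width)
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > width))
    stop("positions outside alignment columns 1..", width)
  counts <- t(cm[c("A", "C", "G", "T"), positions, drop = FALSE])
  n <- as.integer(rowSums(counts))
  freqs <- counts / n            # NaN where n == 0
  freqs[n == 0L, ] <- NA_real_
  positionFrequencyMatrix(positions, freqs, nCounted = n, renormTol = 1e-9)
}

#' Shannon entropy profile of a frequency matrix
#'
#' Information content per column, `h(x) = -sum(p * log(p))` over the bases
#' with non-zero frequency (0 log 0 := 0). Zero at conserved columns; maximal
#' — ln 4 nats or 2 bits — when all four bases occur at frequency 0.25.
#' Undefined columns propagate as `NA`. The default base is e; only the
#' ordering of columns matters for anchor selection, which is base-agnostic.
#'
#' @param pfm A [PositionFrequencyMatrix-class].
#' @param base `"e"` (nats, default) or `"2"` (bits).
#' @return An [EntropyProfile-class].
#' @examples
#' aln <- seqLibrary(c(a = "AAC", b = "ACG", c = "AGT", d = "ATA"),
#'                   aligned = TRUE)
#' entropyValues(entropyProfile(columnFrequencies(aln)))
#' @export
entropyProfile <- function(pfm, base = c("e", "2")) {
  stopifnot(methods::is(pfm, "PositionFrequencyMatrix"))
  base <- match.arg(base)
  logb <- if (identical(base, "2")) function(x) log2(x) else log
  f <- pfmFreqs(pfm)
  hx <- apply(f, 1L, function(p) {
    if (anyNA(p)) return(NA_real_)
    p <- p[p > 0]
    -sum(p * logb(p))
  })
  methods::new("EntropyProfile", positions = pfmPositions(pfm),
               hx = unname(hx), base = base)
}

#' @describeIn entropyProfile Entropy values named by alignment column.
#' @param x An `EntropyProfile`.
#' @export
entropyValues <- function(x) stats::setNames(x@hx, x@positions)

#' @describeIn entropyProfile Columns covered by the profile.
#' @export
entropyPositions <- function(x) x@positions
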