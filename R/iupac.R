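## IUPAC nucleotide machinery shared by the scanning, primer and QC code.

#' IUPAC degenerate nucleotide codes
#'
#' Named list mapping each of the 15 IUPAC DNA letters to the set of
#' unambiguous bases it denotes. The gap character `-` is deliberately not a
#' member: it never matches anything.
#'
#' @format A named list of character vectors.
#' @export
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

## 15 x 15 logical matrix: do the expansion sets of two codes intersect?
.iupac_compat <- local({
  letters15 <- names(IUPAC_CODES)
  m <- matrix(FALSE, 15L, 15L, dimnames = list(letters15, letters15))
  for (a in letters15) for (b in letters15)
    m[a, b] <- length(intersect(IUPAC_CODES[[a]], IUPAC_CODES[[b]])) > 0L
  m
})

.is_iupac <- function(chars, allow_gap = FALSE) {
  ok <- chars %in% names(IUPAC_CODES)
  if (allow_gap) ok <- ok | chars == "-"
  ok
}

.check_iupac_string <- function(x, what = "sequence", allow_gap = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a non-empty character string", call. = FALSE)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  bad <- !.is_iupac(chars, allow_gap = allow_gap)
  if (any(bad))
    stop(what, " contains non-IUPAC character(s): ",
         paste(unique(chars[bad]), collapse = ", "), call. = FALSE)
  paste(chars, collapse = "")
}

#' Are two IUPAC bases compatible?
#'
#' Two IUPAC codes are compatible when their expansion sets intersect, i.e.
#' there exists at least one unambiguous base both could be. This is the
#' matching rule used throughout: a degenerate motif letter matches a target
#' letter iff they are compatible, and a primer-template pair counts as a
#' mismatch iff they are not. A gap is compatible with nothing.
#'
#' @param a,b Character vectors of single IUPAC letters (recycled).
#' @return Logical vector.
#' @examples
#' iupacCompatible("R", "G")  # TRUE: {A,G} and {G} intersect
#' iupacCompatible("Y", "G")  # FALSE: {C,T} and {G} are disjoint
#' @export
iupacCompatible <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- logical(n)
  ok <- .is_iupac(a) & .is_iupac(b)
  out[ok] <- .iupac_compat[cbind(a[ok], b[ok])]
  out
}

#' Reverse complement of an IUPAC DNA string
#'
#' Standard IUPAC complementation (R<->Y, K<->M, S<->S, W<->W, B<->V, D<->H,
#' N<->N) followed by reversal; gaps are preserved in place. An involution:
#' `revComp(revComp(x)) == x`.
#'
#' @param x A single DNA string over the IUPAC alphabet (gap allowed).
#' @return The reverse-complemented string, uppercase.
#' @examples
#' revComp("GAATTC")  # palindromic EcoRI site
#' revComp("CGGCCR")  # "YGGCCG"
#' @export
revComp <- function(x) {
  x <- .check_iupac_string(x, "sequence", allow_gap = TRUE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
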