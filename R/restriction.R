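## Degenerate restriction-site mapping, per-group cutting frequencies,
## enzyme ranking for predator removal, and digestion fragment prediction.

.strip_gaps <- function(seq) gsub("-", "", seq, fixed = TRUE)

#' Scan a sequence for restriction sites
#'
#' Maps every window where the enzyme's degenerate recognition motif matches
#' under IUPAC set-intersection semantics: a motif letter matches a target
#' letter iff their expansion sets intersect. This is optimistic cut
#' detection — an ambiguous target base that *could* be cut counts as a hit,
#' the conservative direction when the goal is to avoid losing prey
#' templates. Restriction enzymes act on duplex DNA, so both strands are
#' scanned by default: the reverse-complement motif is searched on the
#' forward strand and hits are reported in forward-strand coordinates.
#' Palindromic motifs report each site once (strand `+`).
#'
#' @param seq A DNA string (IUPAC); gaps are stripped before scanning unless
#'   `stripGaps = FALSE`, in which case gapped input is an error.
#' @param enzyme A [RestrictionEnzyme-class].
#' @param bothStrands Scan the reverse strand too (default `TRUE`).
#' @param stripGaps Remove `-` before scanning (default `TRUE`).
#' @return A `data.frame` with columns `seqId` (`NA` for a bare string),
#'   `strand` (`+`/`-`), `start` (1-based leftmost base of the site on the
#'   forward strand) and `siteLen`, ordered by `start`.
#' @examples
#' ecori <- restrictionEnzyme("EcoRI", "GAATTC")
#' scanSites("AAGAATTCAA", ecori)
#' @export
scanSites <- function(seq, enzyme, bothStrands = TRUE, stripGaps = TRUE) {
  stopifnot(methods::is(enzyme, "RestrictionEnzyme"))
  id <- if (!is.null(names(seq))) names(seq)[1L] else NA_character_
  seq <- toupper(as.character(seq)[1L])
  if (stripGaps) seq <- .strip_gaps(seq)
  else if (grepl("-", seq, fixed = TRUE))
    stop("sequence contains gap characters; strip gaps before scanning")
  seq <- .check_iupac_string(seq, "sequence")
  site <- enzyme@site
  subject <- Biostrings::DNAString(seq)
  hit_starts <- function(motif) {
    if (nchar(motif) > nchar(seq)) return(integer())
    Biostrings::start(Biostrings::matchPattern(motif, subject, fixed = FALSE))
  }
  fwd <- hit_starts(site)
  hits <- data.frame(seqId = rep(id, length(fwd)),
                     strand = rep("+", length(fwd)),
                     start = fwd, siteLen = rep(nchar(site), length(fwd)),
                     stringsAsFactors = FALSE)
  rcsite <- revComp(site)
  if (bothStrands && !identical(rcsite, site)) {
    rev <- hit_starts(rcsite)
    hits <- rbind(hits,
                  data.frame(seqId = rep(id, length(rev)),
                             strand = rep("-", length(rev)),
                             start = rev,
                             siteLen = rep(nchar(site), length(rev)),
                             stringsAsFactors = FALSE))
  }
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

#' Per-group cutting frequency of an enzyme over a library
#'
#' A sequence counts as cut iff it carries at least one recognition site
#' ([scanSites()] returns a hit). Frequencies are reported per taxon group
#' (ungrouped records are pooled as `"ungrouped"`) and overall.
#'
#' @param library A non-empty [SeqLibrary-class] (gaps are stripped per
#'   sequence before scanning).
#' @param enzyme A [RestrictionEnzyme-class].
#' @param bothStrands Passed to [scanSites()].
#' @return A [CutReport-class].
#' @export
cuttingFrequency <- function(library, enzyme, bothStrands = TRUE) {
  stopifnot(methods::is(library, "SeqLibrary"))
  if (length(library) == 0L) stop("library is empty")
  seqs <- as.character(library)
  cut <- vapply(seqs, function(s)
    nrow(scanSites(s, enzyme, bothStrands = bothStrands)) > 0L, logical(1L))
  grp <- ifelse(is.na(seqGroups(library)), "ungrouped", seqGroups(library))
  per <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    sel <- grp == g
    data.frame(group = g, nCut = sum(cut[sel]), nTotal = sum(sel),
               frequency = sum(cut[sel]) / sum(sel),
               stringsAsFactors = FALSE)
  }))
  methods::new("CutReport", enzyme = enzyme@name, perGroup = per,
               overallFrequency = sum(cut) / length(cut),
               nTotal = length(cut))
}

#' Rank enzymes for predator DNA removal
#'
#' An enzyme is eligible iff it cuts the predator sequence at least once.
#' Eligible enzymes are ordered by ascending unweighted mean of per-group
#' prey cutting frequencies — the unweighted mean keeps small prey groups
#' from being swamped by large ones — with ties broken lexicographically by
#' enzyme name. The best candidates remove the predator while digesting the
#' fewest prey.
#'
#' @param enzymes Non-empty list of [RestrictionEnzyme-class] objects.
#' @param predatorSeq Ungapped predator DNA string.
#' @param preyLibrary A grouped [SeqLibrary-class] of potential prey.
#' @param bothStrands Passed to [scanSites()].
#' @return An [EnzymeRanking-class].
#' @export
rankEnzymes <- function(enzymes, predatorSeq, preyLibrary, bothStrands = TRUE) {
  if (methods::is(enzymes, "RestrictionEnzyme")) enzymes <- list(enzymes)
  if (!length(enzymes)) stop("empty enzyme list")
  rows <- lapply(enzymes, function(enz) {
    nhit <- nrow(scanSites(predatorSeq, enz, bothStrands = bothStrands))
    rep_ <- cuttingFrequency(preyLibrary, enz, bothStrands = bothStrands)
    freqs <- stats::setNames(rep_@perGroup$frequency,
                             paste0("freq.", rep_@perGroup$group))
    c(list(enzyme = enz@name, predatorHits = nhit,
           meanPreyFrequency = mean(rep_@perGroup$frequency)),
      as.list(freqs))
  })
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  eligible <- tab[tab$predatorHits > 0L, , drop = FALSE]
  eligible <- eligible[order(eligible$meanPreyFrequency, eligible$enzyme), ,
                       drop = FALSE]
  rownames(eligible) <- NULL
  methods::new("EnzymeRanking", table = eligible,
               excluded = sort(tab$enzyme[tab$predatorHits == 0L]))
}

#' Predict digestion fragment lengths
#'
#' Cut points fall at `start - 1 + cutOffset` on the forward strand for every
#' site hit (either strand), deduplicated and sorted; cut points at the very
#' ends that would produce empty fragments are dropped. Fragment lengths
#' always sum to the sequence length; with no site the single full-length
#' fragment is returned. Enzyme catalogues place the cut at single-base
#' resolution, but for gel-band interpretation predictions are approximate.
#'
#' @param seq Ungapped DNA string.
#' @param enzyme A [RestrictionEnzyme-class].
#' @param bothStrands Passed to [scanSites()].
#' @return Integer vector of fragment lengths, 5' to 3'.
#' @examples
#' bsp <- restrictionEnzyme("BspEI", "TCCGGA")
#' predictFragments(paste0(strrep("A", 300), "TCCGGA", strrep("A", 352)), bsp)
#' @export
predictFragments <- function(seq, enzyme, bothStrands = TRUE) {
  seq <- .strip_gaps(toupper(as.character(seq)[1L]))
  hits <- scanSites(seq, enzyme, bothStrands = bothStrands)
  len <- nchar(seq)
  cuts <- sort(unique(hits$start - 1L + enzyme@cutOffset))
  cuts <- cuts[cuts > 0L & cuts < len]
  diff(c(0L, cuts, len))
}
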