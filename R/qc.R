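## Clone-library QC: pseudogene filtering by translation, and
## identity-threshold taxonomic assignment.

.GENETIC_CODE_IDS <- c("invert-mito" = "5", "vert-mito" = "2", standard = "1")

.internal_stops <- function(seqChars, frame, code) {
  s <- seqChars[frame:length(seqChars)]
  ncod <- length(s) %/% 3L                 # terminal partial codon ignored
  if (ncod < 2L) return(0L)
  codons <- vapply(seq_len(ncod), function(k)
    paste(s[(3L * k - 2L):(3L * k)], collapse = ""), character(1L))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"                     # ambiguous codon: not a stop call
  sum(aa[-ncod] == "*")                    # stops before the final codon
}

#' Filter pseudogene-like sequences by translation
#'
#' Translates each sequence in its three forward frames under the chosen
#' genetic code (default: invertebrate mitochondrial, the appropriate code
#' for COI of decapod/gastropod prey, under which AGA/AGG encode serine
#' rather than stop). The best frame is the one with the fewest internal stop
#' codons (terminal partial codons ignored; a stop in the final complete
#' codon is not internal); a sequence passes iff its best frame is stop-free,
#' otherwise it is flagged as a putative pseudogene. Sequences shorter than
#' 60 nt are reported as `too_short`. Frame-shift calling against a curated
#' reference is out of scope: a frame-shifted copy generally presents stops
#' in every forward frame and is caught by the same rule.
#'
#' @param seqs A [SeqLibrary-class] of ungapped sequences (gaps stripped).
#' @param code `"invert-mito"` (default), `"vert-mito"` or `"standard"`.
#' @param minLen Minimum length (default 60 nt).
#' @return A `data.frame` with columns `seqId`, `status`
#'   (`pass`/`pseudogene`/`too_short`), `bestFrame` (1/2/3, `NA` when too
#'   short) and `nInternalStops` (in the best frame).
#' @export
pseudogeneFilter <- function(seqs, code = c("invert-mito", "vert-mito",
                                            "standard"), minLen = 60L) {
  stopifnot(methods::is(seqs, "SeqLibrary"))
  code <- match.arg(code)
  gc <- Biostrings::getGeneticCode(.GENETIC_CODE_IDS[[code]])
  rows <- lapply(seqIds(seqs), function(id) {
    s <- .strip_gaps(as.character(seqs)[[id]])
    if (nchar(s) < minLen)
      return(data.frame(seqId = id, status = "too_short",
                        bestFrame = NA_integer_,
                        nInternalStops = NA_integer_,
                        stringsAsFactors = FALSE))
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    stops <- vapply(1:3, .internal_stops, integer(1L),
                    seqChars = chars, code = gc)
    best <- which.min(stops)               # smallest frame on ties
    data.frame(seqId = id,
               status = if (stops[best] == 0L) "pass" else "pseudogene",
               bestFrame = as.integer(best),
               nInternalStops = stops[best], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign a query to its closest reference by identity
#'
#' Computes, for each reference, the best semi-global pairwise alignment
#' (ends-free overlap alignment; fixed scores: match +1, mismatch -1, gap
#' -2) and the identity = matches / aligned columns. The best reference is
#' the one with the highest-scoring alignment (ends-free alignments to
#' unrelated references can form short perfect overlaps, so raw identity
#' cannot rank references); ties resolve by identity, then to the
#' lexicographically smallest reference id. The query is assigned to species
#' iff the best identity meets the policy threshold (inclusive at the bound,
#' e.g. exactly 98%). This is a deterministic local
#' stand-in for a similarity search against an external reference database;
#' the identity definition is documented here rather than inherited from any
#' search tool.
#'
#' @param query A DNA string (or named length-1 character).
#' @param referenceLibrary A non-empty [SeqLibrary-class] of ungapped
#'   references.
#' @param policy An [AssignmentPolicy-class] (default: 0.98 species bound).
#' @return A list with `bestRefId`, `identity` and `assigned`.
#' @export
assignIdentity <- function(query, referenceLibrary,
                           policy = assignmentPolicy()) {
  stopifnot(methods::is(referenceLibrary, "SeqLibrary"),
            methods::is(policy, "AssignmentPolicy"))
  if (length(referenceLibrary) == 0L) stop("empty reference set")
  q <- Biostrings::DNAString(.strip_gaps(toupper(as.character(query)[1L])))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  ids <- sort(seqIds(referenceLibrary))
  best <- list(id = NA_character_, identity = -Inf, score = -Inf)
  for (id in ids) {
    ref <- Biostrings::DNAString(
      .strip_gaps(as.character(referenceLibrary)[[id]]))
    aln <- Biostrings::pairwiseAlignment(q, ref, type = "overlap",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2)
    ncols <- nchar(as.character(Biostrings::alignedPattern(aln)))
    ident <- Biostrings::nmatch(aln) / ncols        # matches / aligned columns
    sc <- Biostrings::score(aln)
    ## best reference = highest-scoring alignment (an ends-free alignment to
    ## an unrelated reference can be a tiny perfect overlap, so identity
    ## alone cannot rank references); score ties resolve by identity, then
    ## by the lexicographically smaller id
    if (sc > best$score + 1e-9 ||
        (abs(sc - best$score) <= 1e-9 && ident > best$identity + 1e-12))
      best <- list(id = id, identity = ident, score = sc)
  }
  list(bestRefId = best$id, identity = best$identity,
       assigned = best$identity >= policy@speciesMinIdentity - 1e-9)
}
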