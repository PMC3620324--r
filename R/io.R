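## Readers and writers for the external plain-text interfaces: FASTA
## libraries, enzyme tables, group maps and per-position frequency tables.

#' Read a FASTA file into a SeqLibrary
#'
#' Sequences are uppercased; the record id is the first whitespace-delimited
#' token of the header. `U` (RNA) and any character outside the IUPAC DNA
#' alphabet plus `-` are rejected.
#'
#' @param path Path to a FASTA file.
#' @param aligned Logical; validate that all sequences have equal length and
#'   flag the library as an alignment.
#' @param groups Optional id -> group map: a named character vector, or a path
#'   to a two-column TSV as read by [readGroupMap()].
#' @return A [SeqLibrary-class].
#' @export
readFasta <- function(path, aligned = FALSE, groups = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1L]
  if (is.na(first) || !startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA (", path, "): line ",
         if (is.na(first)) 1L else first, " does not start a '>' record")
  ## DNA only: reject U and anything outside the IUPAC alphabet plus gap
  ## before Biostrings silently normalizes it
  seqline <- !startsWith(trimws(lines), ">")
  bad <- seqline & grepl("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn \t-]",
                         trimws(lines))
  if (any(bad))
    stop("malformed FASTA (", path, "): line ", which(bad)[1L],
         " contains non-IUPAC DNA character(s)")
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e)
      stop("malformed FASTA (", path, "): ", conditionMessage(e),
           call. = FALSE))
  names(seqs) <- sub("[[:space:]].*$", "", names(seqs))
  if (is.character(groups) && length(groups) == 1L && is.null(names(groups)) &&
      file.exists(groups))
    groups <- readGroupMap(groups)
  lib <- seqLibrary(seqs, groups = groups, aligned = FALSE)
  if (aligned) {
    w <- Biostrings::width(seqs)
    if (length(unique(w)) > 1L)
      stop("alignment error (", path, "): ragged sequence lengths ",
           paste(sort(unique(w)), collapse = ", "))
    lib@aligned <- TRUE
    methods::validObject(lib)
  }
  lib
}

#' Write a SeqLibrary to FASTA
#'
#' @param x A [SeqLibrary-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  Biostrings::writeXStringSet(seqSet(x), path, format = "fasta")
  invisible(path)
}

#' Read an id -> group map
#'
#' Two-column TSV (`id`, `group`), with or without a header line. Group maps
#' are supplied separately from the FASTA so header dialects stay out of the
#' sequence reader.
#'
#' @param path Path to the TSV.
#' @return Named character vector: id -> group.
#' @export
readGroupMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(tab) < 2L) stop("group map must have two columns: id, group")
  if (identical(tolower(tab[1L, 1L]), "id")) tab <- tab[-1L, , drop = FALSE]
  if (anyDuplicated(tab[[1L]]))
    stop("duplicated ids in group map: ",
         paste(unique(tab[[1L]][duplicated(tab[[1L]])]), collapse = ", "))
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Read a restriction enzyme table
#'
#' TSV with columns `name`, `site` and optional `cut_offset`. Rows whose site
#' contains a non-IUPAC character, whose effective recognition length falls
#' outside 6-15 bp, or whose cut offset is out of range are rejected
#' individually with a warning naming the row; the remaining rows are kept
#' (an all-bad table is an error).
#'
#' @param path Path to the TSV.
#' @return A list of [RestrictionEnzyme-class] objects.
#' @export
readEnzymeTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (!all(c("name", "site") %in% names(tab))) {
    ## headerless two/three-column form
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             comment.char = "#")
    names(tab) <- c("name", "site", "cut_offset")[seq_len(ncol(tab))]
  }
  if (!"cut_offset" %in% names(tab)) tab$cut_offset <- 0L
  tab$cut_offset[is.na(tab$cut_offset)] <- 0L
  out <- vector("list", nrow(tab))
  bad <- character()
  for (i in seq_len(nrow(tab))) {
    enz <- tryCatch(
      restrictionEnzyme(tab$name[i], tab$site[i], tab$cut_offset[i]),
      error = function(e) {
        bad <<- c(bad, sprintf("row %d (%s): %s", i, tab$name[i],
                               conditionMessage(e)))
        NULL
      })
    out[[i]] <- enz
  }
  if (length(bad))
    warning("rejected ", length(bad), " enzyme row(s):\n  ",
            paste(bad, collapse = "\n  "), call. = FALSE)
  out <- Filter(Negate(is.null), out)
  if (!length(out)) stop("no valid enzyme rows in ", path)
  out
}

#' Read a per-position nucleotide frequency table
#'
#' TSV in the layout of a published frequency table: a `position` column plus
#' `A`, `C`, `T`, `G` columns (a leading `%` in the column names is accepted),
#' and optionally a `group` column (one sub-table per taxon group) and an
#' `n_counted` column. Values larger than 1.5 are interpreted as percentages
#' and divided by 100. Rows are renormalized to sum to exactly 1 (published
#' tables round to one decimal).
#'
#' @param path Path to the TSV.
#' @return A [PositionFrequencyMatrix-class], or a named list of them when a
#'   `group` column is present.
#' @seealso [writeFrequencyTable()], [anchorSiteFrequencies()]
#' @export
readFrequencyTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#", check.names = FALSE)
  names(tab) <- sub("^%", "", names(tab))
  names(tab)[names(tab) %in% c("a", "c", "g", "t")] <-
    toupper(names(tab)[names(tab) %in% c("a", "c", "g", "t")])
  need <- c("position", "A", "C", "T", "G")
  if (!all(need %in% names(tab)))
    stop("frequency table needs columns position, A, C, T, G (got: ",
         paste(names(tab), collapse = ", "), ")")
  build <- function(sub) {
    f <- as.matrix(sub[, c("A", "C", "G", "T")])
    if (any(f > 1.5, na.rm = TRUE)) f <- f / 100
    nc <- if ("n_counted" %in% names(sub)) sub$n_counted else NA_integer_
    positionFrequencyMatrix(sub$position, f, nCounted = nc)
  }
  if ("group" %in% names(tab)) {
    sp <- split(tab, tab$group)
    lapply(sp, build)
  } else {
    build(tab)
  }
}

#' Write a PositionFrequencyMatrix as TSV
#'
#' Columns `position`, `%A`, `%C`, `%T`, `%G` (percent, the layout of
#' published tables) plus `n_counted` when known.
#'
#' @param pfm A [PositionFrequencyMatrix-class].
#' @param path Output path.
#' @param digits Rounding for the percentages.
#' @return `path`, invisibly.
#' @export
writeFrequencyTable <- function(pfm, path, digits = 1) {
  f <- pfmFreqs(pfm)
  out <- data.frame(position = pfmPositions(pfm),
                    `%A` = round(100 * f[, "A"], digits),
                    `%C` = round(100 * f[, "C"], digits),
                    `%T` = round(100 * f[, "T"], digits),
                    `%G` = round(100 * f[, "G"], digits),
                    check.names = FALSE)
  if (!all(is.na(pfmCounts(pfm)))) out$n_counted <- pfmCounts(pfm)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Published anchor-site base frequencies
#'
#' Loads the per-group nucleotide frequencies at alignment columns 640-643 of
#' the 658-bp COI barcode fragment — the binding site of the 3' end of the
#' predator-specific blocking primers — tabulated from alignments of 947
#' decapod, 758 ray-finned fish and 271 gastropod reference sequences. These
#' are the frequencies that enter the anchor mismatch-probability
#' calculation. (The gastropod %G entry at column 641 is corrected from an
#' evident typographical duplication so the row sums to 100%.)
#'
#' @return Named list of [PositionFrequencyMatrix-class] objects
#'   (`decapod`, `fish`, `gastropod`).
#' @examples
#' pfms <- anchorSiteFrequencies()
#' baseFreq(pfms$decapod, 640, "T")
#' @export
anchorSiteFrequencies <- function() {
  path <- system.file("extdata", "anchor_site_freqs.tsv", package = "preyblock",
                      mustWork = TRUE)
  pfms <- readFrequencyTable(path)
  n <- c(decapod = 947L, fish = 758L, gastropod = 271L)
  for (g in names(pfms)) pfms[[g]]@nCounted[] <- n[[g]]
  pfms[c("decapod", "fish", "gastropod")]
}
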