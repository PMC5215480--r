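#' @import methods
NULL

## Legal residue sets. Determinate states are the unambiguous residues used
## for distance computation and SNP calling; ambiguity codes and '?' count as
## missing there but are legal storage characters.
.NT_DETERMINATE <- c("A", "C", "G", "T")
.NT_AMBIGUOUS <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "?")
.AA_DETERMINATE <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                     "K", "M", "F", "P", "S", "T", "W", "Y", "V")
.AA_AMBIGUOUS <- c("X", "B", "Z", "J", "U", "O", "*", "?")
.GAP <- "-"

.legalResidues <- function(alphabet) {
  if (alphabet == "nucleotide") c(.NT_DETERMINATE, .NT_AMBIGUOUS, .GAP)
  else c(.AA_DETERMINATE, .AA_AMBIGUOUS, .GAP)
}

#' LocusAlignment: one gene's aligned sequences
#'
#' Stores the aligned sequences of a single locus as named residue strings of
#' equal length. Residues are kept uppercase; legal characters are the
#' declared alphabet plus the gap \code{'-'} and the missing symbols
#' (\code{N}/IUPAC ambiguity/\code{?} for nucleotide, \code{X}/\code{?} for
#' amino acid). A concatenated alignment additionally carries a partition
#' table locating each source locus (1-based closed column intervals).
#'
#' @slot name single locus identifier.
#' @slot sequences named character vector, one residue string per individual.
#' @slot nCols number of alignment columns.
#' @slot alphabet \code{"nucleotide"} or \code{"amino-acid"}.
#' @slot partitions data.frame with columns \code{locus}, \code{start},
#'   \code{end}; zero rows except for concatenated alignments.
#'
#' @export
setClass("LocusAlignment",
  representation(name = "character",
                 sequences = "character",
                 nCols = "integer",
                 alphabet = "character",
                 partitions = "data.frame"),
  prototype(name = NA_character_, sequences = character(0), nCols = 0L,
            alphabet = "nucleotide",
            partitions = data.frame(locus = character(0),
                                    start = integer(0), end = integer(0))))

setValidity("LocusAlignment", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L)
    msg <- c(msg, "'name' must be a single string")
  if (!object@alphabet %in% c("nucleotide", "amino-acid"))
    msg <- c(msg, "'alphabet' must be 'nucleotide' or 'amino-acid'")
  labs <- names(object@sequences)
  if (length(object@sequences) > 0L) {
    if (is.null(labs) || anyNA(labs) || any(labs == ""))
      msg <- c(msg, "all sequences must be labelled")
    else if (anyDuplicated(labs))
      msg <- c(msg, sprintf("duplicate sequence labels: %s",
                            paste(unique(labs[duplicated(labs)]), collapse = ", ")))
    if (any(nchar(object@sequences) != object@nCols))
      msg <- c(msg, sprintf("all sequences must have %d columns", object@nCols))
    chars <- unique(unlist(strsplit(object@sequences, "", fixed = TRUE)))
    bad <- setdiff(chars, .legalResidues(object@alphabet))
    if (length(bad) > 0L)
      msg <- c(msg, sprintf("illegal %s residues: %s", object@alphabet,
                            paste(bad, collapse = " ")))
  }
  if (!all(c("locus", "start", "end") %in% names(object@partitions)))
    msg <- c(msg, "'partitions' needs columns locus, start, end")
  if (length(msg) > 0L) msg else TRUE
})

#' MultiLocusAlignment: harmonized multi-gene alignment container
#'
#' An ordered list of \linkS4class{LocusAlignment} objects sharing one
#' canonical, alphanumerically sorted individual list. On construction every
#' individual absent from a locus receives a gap-only row, so all loci hold
#' the same taxa in the same order and per-locus analyses are directly
#' comparable.
#'
#' @slot loci named list of \linkS4class{LocusAlignment}.
#' @slot labels canonical sorted individual labels.
#' @slot nInd number of individuals.
#' @slot nSeq total number of sequences over all loci, including gap-only
#'   padding rows.
#' @slot nSeqMiss number of gap-only (missing) sequences.
#' @slot type alphabet tag shared by all loci.
#' @slot indInfo optional data.frame of per-individual metadata (may cover a
#'   subset of individuals); zero rows when absent.
#' @slot geneInfo optional data.frame of per-locus metadata; zero rows when
#'   absent.
#'
#' @export
setClass("MultiLocusAlignment",
  representation(loci = "list",
                 labels = "character",
                 nInd = "integer",
                 nSeq = "integer",
                 nSeqMiss = "integer",
                 type = "character",
                 indInfo = "data.frame",
                 geneInfo = "data.frame"))

setValidity("MultiLocusAlignment", function(object) {
  msg <- character(0)
  if (length(object@loci) == 0L)
    return("container must hold at least one locus")
  if (!all(vapply(object@loci, is, logical(1), "LocusAlignment")))
    return("'loci' must be a list of LocusAlignment objects")
  lnames <- names(object@loci)
  if (is.null(lnames) || anyDuplicated(lnames))
    msg <- c(msg, "loci must have unique names")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "individual labels must be unique")
  if (!identical(object@labels, .sortLabels(object@labels)))
    msg <- c(msg, "labels must be in canonical sorted order")
  for (a in object@loci) {
    if (!identical(names(a@sequences), object@labels))
      msg <- c(msg, sprintf("locus '%s' does not hold the canonical labels", a@name))
    if (a@alphabet != object@type)
      msg <- c(msg, sprintf("locus '%s' alphabet differs from container type", a@name))
  }
  if (object@nInd != length(object@labels))
    msg <- c(msg, "nInd must equal the number of labels")
  if (object@nSeq != object@nInd * length(object@loci))
    msg <- c(msg, "nSeq must equal nInd * number of loci")
  miss <- sum(vapply(object@loci, function(a) sum(.isGapOnly(a@sequences)), integer(1)))
  if (object@nSeqMiss != miss)
    msg <- c(msg, "nSeqMiss does not match the gap-only row count")
  if (length(msg) > 0L) msg else TRUE
})

#' SitePatternTable: compressed site-pattern representation
#'
#' Unique alignment columns (site patterns over the individuals, in canonical
#' order) with positive integer weights. Weights sum to the source locus
#' column count; expanding the patterns by their weights reproduces an
#' alignment column-equivalent to the source.
#'
#' @slot patterns character matrix, one row per unique pattern, one column
#'   per individual.
#' @slot weights integer multiplicities, parallel to pattern rows.
#' @slot labels individual labels (pattern column names).
#' @slot locusName source locus.
#'
#' @export
setClass("SitePatternTable",
  representation(patterns = "matrix",
                 weights = "integer",
                 labels = "character",
                 locusName = "character"))

setValidity("SitePatternTable", function(object) {
  msg <- character(0)
  if (nrow(object@patterns) != length(object@weights))
    msg <- c(msg, "one weight per pattern required")
  if (ncol(object@patterns) != length(object@labels))
    msg <- c(msg, "one pattern column per individual required")
  if (any(object@weights <= 0L))
    msg <- c(msg, "weights must be positive")
  key <- apply(object@patterns, 1L, paste, collapse = "")
  if (anyDuplicated(key))
    msg <- c(msg, "patterns must be pairwise distinct")
  if (length(msg) > 0L) msg else TRUE
})

#' GenotypeTable: individuals x markers integer allele codes
#'
#' Haploid genotype table produced by SNP extraction or haplotype (MLST-style)
#' coding. Codes per marker are consecutive integers starting at 1 in order
#' of first appearance over individuals in canonical order; missing data is
#' \code{NA}. The legend maps each code back to its allele string (a single
#' base for SNP markers, a full sequence for haplotype markers).
#'
#' @slot individuals ordered individual labels (row names of \code{codes}).
#' @slot markers data.frame describing markers: columns \code{locus},
#'   \code{site} (\code{NA} for haplotype markers), \code{type}
#'   (\code{"snp"} or \code{"haplotype"}).
#' @slot codes integer matrix individuals x markers; \code{NA} = missing.
#' @slot alleleLegend list (one element per marker) of character vectors
#'   mapping code index to allele string.
#'
#' @export
setClass("GenotypeTable",
  representation(individuals = "character",
                 markers = "data.frame",
                 codes = "matrix",
                 alleleLegend = "list"))

setValidity("GenotypeTable", function(object) {
  msg <- character(0)
  if (nrow(object@codes) != length(object@individuals))
    msg <- c(msg, "one code row per individual required")
  if (ncol(object@codes) != nrow(object@markers))
    msg <- c(msg, "one code column per marker required")
  if (length(object@alleleLegend) != nrow(object@markers))
    msg <- c(msg, "one legend entry per marker required")
  if (!all(c("locus", "site", "type") %in% names(object@markers)))
    msg <- c(msg, "'markers' needs columns locus, site, type")
  for (k in seq_along(object@alleleLegend)) {
    cod <- object@codes[, k]
    cod <- cod[!is.na(cod)]
    leg <- object@alleleLegend[[k]]
    if (length(cod) > 0L && (any(cod < 1L) || any(cod > length(leg))))
      msg <- c(msg, sprintf("marker %d holds codes outside its legend", k))
  }
  if (length(msg) > 0L) msg else TRUE
})
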