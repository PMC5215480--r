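#' Create a single-locus alignment
#'
#' Builds a \linkS4class{LocusAlignment} from named residue strings (or a
#' character matrix with one row per individual). Input is uppercased; for
#' nucleotide data \code{U} is normalized to \code{T}, so RNA input is
#' tolerated. All sequences must have equal length and unique labels.
#'
#' @param sequences named character vector of aligned residue strings, or a
#'   character matrix (rows = individuals, columns = sites) with rownames.
#' @param name locus identifier.
#' @param alphabet \code{"nucleotide"}, \code{"amino-acid"}, or \code{"auto"}
#'   (infer: nucleotide iff at least 90\% of non-gap, non-'?' residues are
#'   nucleotide symbols).
#'
#' @return A \linkS4class{LocusAlignment}.
#' @examples
#' locusAlignment(c(a = "ACGT", b = "AC-T"), name = "loc1")
#' @export
locusAlignment <- function(sequences, name = "locus",
                           alphabet = c("auto", "nucleotide", "amino-acid")) {
  alphabet <- match.arg(alphabet)
  if (is.matrix(sequences))
    sequences <- stats::setNames(apply(sequences, 1L, paste, collapse = ""),
                                 rownames(sequences))
  if (!is.character(sequences) || length(sequences) == 0L)
    stop("'sequences' must be a non-empty named character vector or matrix")
  sequences <- toupper(sequences)
  if (alphabet == "auto") alphabet <- .inferAlphabet(sequences)
  if (alphabet == "nucleotide")
    sequences <- gsub("U", "T", sequences, fixed = TRUE)
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1L)
    stop(sprintf("ragged alignment in locus '%s': sequence lengths %s",
                 name, paste(unique(lens), collapse = ", ")))
  new("LocusAlignment", name = name, sequences = sequences,
      nCols = as.integer(lens[1]), alphabet = alphabet)
}

#' Number of alignment columns
#' @param x a \linkS4class{LocusAlignment}.
#' @return integer site count.
#' @export
nCols <- function(x) {
  stopifnot(is(x, "LocusAlignment"))
  x@nCols
}

#' Partition table of a concatenated alignment
#'
#' @param x a \linkS4class{LocusAlignment}, typically the result of
#'   \code{\link{concatenateLoci}}.
#' @return data.frame with columns \code{locus}, \code{start}, \code{end}
#'   (1-based, closed intervals); zero rows for a plain single locus.
#' @export
getPartitions <- function(x) {
  stopifnot(is(x, "LocusAlignment"))
  x@partitions
}

#' RAxML-style partition block for a concatenated alignment
#'
#' @param x a concatenated \linkS4class{LocusAlignment} carrying partitions.
#' @return character vector, one \code{DNA, locus = start-end} line per locus.
#' @export
partitionText <- function(x) {
  p <- getPartitions(x)
  if (nrow(p) == 0L) stop("alignment carries no partition table")
  tag <- if (x@alphabet == "nucleotide") "DNA" else "PROT"
  sprintf("%s, %s = %d-%d", tag, p$locus, p$start, p$end)
}

#' @describeIn locusAlignment coerce to a character matrix (one row per
#'   individual, one column per site).
#' @param x a \linkS4class{LocusAlignment}.
#' @param ... unused.
#' @export
as.matrix.LocusAlignment <- function(x, ...) {
  if (length(x@sequences) == 0L)
    return(matrix(character(0), 0L, x@nCols))
  m <- do.call(rbind, strsplit(x@sequences, "", fixed = TRUE))
  rownames(m) <- names(x@sequences)
  m
}

setMethod("getLabels", "LocusAlignment", function(x) names(x@sequences))

setMethod("show", "LocusAlignment", function(object) {
  cat(sprintf("=== LocusAlignment '%s' ===\n", object@name))
  cat(sprintf("[%d %s sequences, %d columns]\n", length(object@sequences),
              if (object@alphabet == "nucleotide") "DNA" else "amino-acid",
              object@nCols))
  if (nrow(object@partitions) > 0L)
    cat(sprintf("@partitions: %d loci (%s)\n", nrow(object@partitions),
                paste(object@partitions$locus, collapse = ", ")))
  labs <- names(object@sequences)
  if (length(labs) > 6L) labs <- c(labs[1:6], "...")
  cat("@labels:", paste(labs, collapse = " "), "\n")
})
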