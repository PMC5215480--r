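#' Build a harmonized multi-locus container
#'
#' Enumerates all individuals with at least one sequence across the supplied
#' loci, sorts the labels alphanumerically (plain code-point order,
#' locale-independent), and, when \code{add.gaps} is \code{TRUE}, pads every
#' locus with gap-only rows (\code{'-'} repeated over the locus width) for
#' each missing individual so that all loci hold the same taxa in the same
#' order. Gap-only rows already present in the input also count as missing
#' sequences.
#'
#' @param loci a list of \linkS4class{LocusAlignment} objects, or of named
#'   character vectors / matrices coercible via \code{\link{locusAlignment}}.
#' @param add.gaps pad missing individuals with gap-only sequences (default).
#'   With \code{add.gaps = FALSE} every locus must already contain the same
#'   label set; otherwise construction fails.
#' @param ind.info optional data.frame of per-individual metadata, with row
#'   names matching (a subset of) the individual labels.
#' @param gene.info optional data.frame of per-locus metadata, with row names
#'   matching the locus names.
#'
#' @return A \linkS4class{MultiLocusAlignment}.
#' @examples
#' a <- locusAlignment(c(s1 = "ACGT", s2 = "ACCT"), name = "g1")
#' b <- locusAlignment(c(s2 = "GG", s3 = "GT"), name = "g2")
#' x <- multiLocusAlignment(list(a, b))
#' x  # 3 individuals, 6 sequences, 2 gap-only
#' @export
multiLocusAlignment <- function(loci, add.gaps = TRUE,
                                ind.info = NULL, gene.info = NULL) {
  if (!is.list(loci) || length(loci) == 0L)
    stop("'loci' must be a non-empty list")
  given <- names(loci)
  loci <- lapply(seq_along(loci), function(i) {
    a <- loci[[i]]
    if (!is(a, "LocusAlignment"))
      a <- locusAlignment(a, name = if (!is.null(given) && nzchar(given[i]))
                                      given[i] else sprintf("locus%d", i))
    validObject(a)
    a
  })
  lnames <- vapply(loci, function(a) a@name, character(1))
  if (!is.null(given) && any(nzchar(given)))
    lnames[nzchar(given)] <- given[nzchar(given)]
  if (anyDuplicated(lnames))
    stop(sprintf("duplicate locus names: %s",
                 paste(unique(lnames[duplicated(lnames)]), collapse = ", ")))
  alph <- unique(vapply(loci, function(a) a@alphabet, character(1)))
  if (length(alph) > 1L)
    stop(sprintf("mixed alphabets across loci: %s", paste(alph, collapse = " vs ")))

  labels <- .sortLabels(unique(unlist(lapply(loci, function(a) names(a@sequences)))))
  if (!add.gaps) {
    for (a in loci)
      if (!setequal(names(a@sequences), labels))
        stop(sprintf(paste0("incomplete data: locus '%s' lacks %s ",
                            "(use add.gaps = TRUE to pad with gap-only rows)"),
                     a@name,
                     paste(setdiff(labels, names(a@sequences)), collapse = ", ")))
  }
  loci <- lapply(loci, function(a) {
    seqs <- a@sequences
    missing <- setdiff(labels, names(seqs))
    if (length(missing) > 0L)
      seqs <- c(seqs, stats::setNames(rep(.gapRow(a@nCols), length(missing)),
                                      missing))
    a@sequences <- seqs[labels]
    a
  })
  names(loci) <- lnames

  ind.info <- if (is.null(ind.info))
    data.frame(row.names = character(0)) else as.data.frame(ind.info)
  gene.info <- if (is.null(gene.info))
    data.frame(row.names = character(0)) else as.data.frame(gene.info)

  nInd <- length(labels)
  nSeqMiss <- sum(vapply(loci, function(a) sum(.isGapOnly(a@sequences)),
                         integer(1)))
  new("MultiLocusAlignment", loci = loci, labels = labels,
      nInd = nInd, nSeq = nInd * length(loci), nSeqMiss = as.integer(nSeqMiss),
      type = alph, indInfo = ind.info, geneInfo = gene.info)
}

setMethod("show", "MultiLocusAlignment", function(object) {
  cat("=== MultiLocusAlignment ===\n")
  cat(sprintf("[%d %s sequences in %d genes]\n", object@nSeq,
              if (object@type == "nucleotide") "DNA" else "amino-acid",
              length(object@loci)))
  cat(sprintf("@n.ind: %d individuals\n", object@nInd))
  cat(sprintf("@n.seq: %d sequences in total\n", object@nSeq))
  cat(sprintf("@n.seq.miss: %d gap-only (missing) sequences\n", object@nSeqMiss))
  labs <- object@labels
  if (length(labs) > 6L) labs <- c(labs[1:6], "...")
  cat("@labels:", paste(labs, collapse = " "), "\n")
  cat(sprintf("@loci: %s\n", paste(names(object@loci), collapse = " ")))
  if (nrow(object@indInfo) > 0L)
    cat(sprintf("@ind.info: %d x %d data.frame\n",
                nrow(object@indInfo), ncol(object@indInfo)))
  if (nrow(object@geneInfo) > 0L)
    cat(sprintf("@gene.info: %d x %d data.frame\n",
                nrow(object@geneInfo), ncol(object@geneInfo)))
})

#' Subset a multi-locus container
#'
#' \code{x[i, j]} keeps the individuals selected by \code{i} and the loci
#' selected by \code{j}; each selector may be an integer index vector, a
#' label vector, or a logical mask. Counts and metadata tables are
#' recomputed/sliced. Individuals always remain in canonical sorted order
#' (an out-of-order individual selector is normalized); loci keep selector
#' order, so \code{j} can reorder genes. Subsetting never re-harmonizes:
#' loci that become entirely gap-only are retained.
#'
#' @param x a \linkS4class{MultiLocusAlignment}.
#' @param i individual selector.
#' @param j locus selector.
#' @param ... unused.
#' @param drop unused (always \code{FALSE} semantics).
#' @export
setMethod("[", signature(x = "MultiLocusAlignment"),
  function(x, i, j, ..., drop = FALSE) {
    ii <- if (missing(i)) seq_len(x@nInd)
          else .resolveSelector(i, x@labels, "individual selection")
    jj <- if (missing(j)) seq_along(x@loci)
          else .resolveSelector(j, names(x@loci), "locus selection")
    ii <- sort(unique(ii))  # canonical order is preserved, never re-sorted beyond it
    labels <- x@labels[ii]
    loci <- lapply(x@loci[jj], function(a) {
      a@sequences <- a@sequences[labels]
      a
    })
    indInfo <- x@indInfo[rownames(x@indInfo) %in% labels, , drop = FALSE]
    geneInfo <- x@geneInfo[rownames(x@geneInfo) %in% names(loci), , drop = FALSE]
    nSeqMiss <- sum(vapply(loci, function(a) sum(.isGapOnly(a@sequences)),
                           integer(1)))
    new("MultiLocusAlignment", loci = loci, labels = labels,
        nInd = length(labels), nSeq = length(labels) * length(loci),
        nSeqMiss = as.integer(nSeqMiss), type = x@type,
        indInfo = indInfo, geneInfo = geneInfo)
  })

#' Concatenate loci into a supermatrix alignment
#'
#' Juxtaposes each individual's rows across the selected loci (all by
#' default, in container order; an explicit selector is honoured in selector
#' order). Gap-padded rows are concatenated as-is. The result records the
#' partition boundaries of every source locus as 1-based closed column
#' intervals, retrievable with \code{\link{getPartitions}}.
#'
#' @param x a \linkS4class{MultiLocusAlignment}.
#' @param loci locus selector (indices, names, or logical mask); \code{NULL}
#'   selects all loci.
#' @return A \linkS4class{LocusAlignment} named \code{"concatenated"} with
#'   \code{nCols} equal to the summed locus widths.
#' @export
setMethod("concatenateLoci", "MultiLocusAlignment", function(x, loci = NULL) {
  jj <- .resolveSelector(loci, names(x@loci), "locus selection")
  sel <- x@loci[jj]
  widths <- vapply(sel, function(a) a@nCols, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  rows <- do.call(paste0, lapply(sel, function(a) a@sequences[x@labels]))
  out <- new("LocusAlignment", name = "concatenated",
             sequences = stats::setNames(rows, x@labels),
             nCols = as.integer(sum(widths)), alphabet = x@type,
             partitions = data.frame(locus = names(sel), start = starts,
                                     end = ends, row.names = NULL))
  validObject(out)
  out
})
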