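#' Number of loci in a container
#' @param x a \linkS4class{MultiLocusAlignment}.
#' @return integer count.
#' @rdname getNumLoci
#' @export
setMethod("getNumLoci", "MultiLocusAlignment", function(x) length(x@loci))

#' Get or set locus names
#'
#' \code{setLocusNames} returns an updated container; locus names in the
#' per-locus metadata table are renamed consistently. Sequence content is
#' untouched.
#'
#' @param x a \linkS4class{MultiLocusAlignment}.
#' @param value replacement names (unique, one per locus).
#' @return \code{getLocusNames}: character vector; \code{setLocusNames}: the
#'   renamed container.
#' @rdname getLocusNames
#' @export
setMethod("getLocusNames", "MultiLocusAlignment", function(x) names(x@loci))

#' @rdname getLocusNames
#' @export
setMethod("setLocusNames", "MultiLocusAlignment", function(x, value) {
  value <- as.character(value)
  if (length(value) != length(x@loci))
    stop(sprintf("expected %d locus names, got %d",
                 length(x@loci), length(value)))
  if (anyDuplicated(value) || anyNA(value) || any(value == ""))
    stop("locus names must be unique and non-empty")
  old <- names(x@loci)
  names(x@loci) <- value
  x@loci <- lapply(stats::setNames(seq_along(x@loci), value), function(k) {
    a <- x@loci[[k]]
    a@name <- value[k]
    a
  })
  if (nrow(x@geneInfo) > 0L) {
    hit <- match(rownames(x@geneInfo), old)
    rownames(x@geneInfo)[!is.na(hit)] <- value[hit[!is.na(hit)]]
  }
  validObject(x)
  x
})

#' Canonical individual labels
#' @param x a \linkS4class{MultiLocusAlignment} or \linkS4class{LocusAlignment}.
#' @return character vector of labels.
#' @rdname getLabels
#' @export
setMethod("getLabels", "MultiLocusAlignment", function(x) x@labels)

#' Per-locus sequence counts
#'
#' By default only sequences that are not composed entirely of gaps are
#' counted (the padding rows inserted during harmonization are excluded);
#' with \code{exclude.gap.only = FALSE} every locus reports all
#' \code{n.ind} rows.
#'
#' @param x a \linkS4class{MultiLocusAlignment}.
#' @param loci locus selector; \code{NULL} selects all loci.
#' @param exclude.gap.only drop gap-only rows from the counts (default).
#' @return named integer vector, one count per selected locus.
#' @rdname getNumSequences
#' @export
setMethod("getNumSequences", "MultiLocusAlignment",
  function(x, loci = NULL, exclude.gap.only = TRUE) {
    jj <- .resolveSelector(loci, names(x@loci), "locus selection")
    vapply(x@loci[jj], function(a) {
      if (exclude.gap.only) sum(!.isGapOnly(a@sequences))
      else length(a@sequences)
    }, integer(1))
  })

#' Per-locus sequence names
#'
#' @param x a \linkS4class{MultiLocusAlignment}.
#' @param loci locus selector; \code{NULL} selects all loci.
#' @param exclude.gap.only omit names of gap-only rows (default), mirroring
#'   \code{\link{getNumSequences}}.
#' @return named list of character vectors, one per selected locus.
#' @rdname getSequenceNames
#' @export
setMethod("getSequenceNames", "MultiLocusAlignment",
  function(x, loci = NULL, exclude.gap.only = TRUE) {
    jj <- .resolveSelector(loci, names(x@loci), "locus selection")
    lapply(x@loci[jj], function(a) {
      labs <- names(a@sequences)
      if (exclude.gap.only) labs[!.isGapOnly(a@sequences)] else labs
    })
  })

#' Extract (filtered) alignments from a container
#'
#' Returns the per-locus alignments restricted to the selected individuals
#' and loci. When exactly one locus is selected and \code{simplify} is
#' \code{TRUE} (the default) the bare \linkS4class{LocusAlignment} is
#' returned; otherwise a named list.
#'
#' @param x a \linkS4class{MultiLocusAlignment}.
#' @param ids individual selector; \code{NULL} selects all individuals.
#' @param loci locus selector; \code{NULL} selects all loci.
#' @param simplify unwrap a single-locus result (default \code{TRUE}).
#' @return A \linkS4class{LocusAlignment} or a named list of them.
#' @rdname getSequences
#' @export
setMethod("getSequences", "MultiLocusAlignment",
  function(x, ids = NULL, loci = NULL, simplify = TRUE) {
    sub <- x[if (is.null(ids)) seq_len(x@nInd) else ids,
             if (is.null(loci)) seq_along(x@loci) else loci]
    out <- sub@loci
    if (simplify && length(out) == 1L) out[[1]] else out
  })
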