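#' Compress an alignment into unique site patterns
#'
#' A site pattern is the column of residues over all individuals at one
#' alignment position. Compression stores each distinct pattern once with an
#' integer weight equal to the number of columns showing it, in order of
#' first appearance; weights sum to the alignment width. This is the compact
#' storage used by likelihood/parsimony machinery, where per-site work only
#' depends on the distinct patterns.
#'
#' @param x a \linkS4class{LocusAlignment}.
#' @return A \linkS4class{SitePatternTable}.
#' @seealso \code{\link{expandSitePatterns}} for the inverse operation.
#' @export
setMethod("compressSitePatterns", "LocusAlignment", function(x) {
  if (length(x@sequences) == 0L || x@nCols == 0L)
    stop("cannot compress an empty alignment")
  m <- as.matrix(x)                       # individuals x sites
  key <- apply(m, 2L, paste, collapse = "")
  first <- !duplicated(key)
  w <- as.integer(table(factor(key, levels = key[first])))
  new("SitePatternTable",
      patterns = t(m[, first, drop = FALSE]),
      weights = w, labels = rownames(m), locusName = x@name)
})

#' Expand a site-pattern table back into an alignment
#'
#' Repeats each pattern by its weight, producing an alignment whose column
#' multiset equals the source's (column order follows pattern order, which is
#' first-appearance order of the source columns).
#'
#' @param x a \linkS4class{SitePatternTable}.
#' @param alphabet alphabet tag for the rebuilt alignment.
#' @return A \linkS4class{LocusAlignment}.
#' @export
expandSitePatterns <- function(x, alphabet = c("nucleotide", "amino-acid")) {
  stopifnot(is(x, "SitePatternTable"))
  alphabet <- match.arg(alphabet)
  cols <- t(x@patterns)[, rep(seq_along(x@weights), times = x@weights),
                        drop = FALSE]
  rownames(cols) <- x@labels
  locusAlignment(cols, name = x@locusName, alphabet = alphabet)
}

setMethod("show", "SitePatternTable", function(object) {
  cat(sprintf("=== SitePatternTable '%s' ===\n", object@locusName))
  cat(sprintf("[%d unique patterns over %d individuals, %d sites]\n",
              nrow(object@patterns), length(object@labels),
              sum(object@weights)))
})
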