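## Residue -> display class for text mode: determinate bases and the gap keep
## their symbol, 'N' stays 'N', any other ambiguity collapses to '.'.
.textClass <- function(ch, alphabet) {
  if (alphabet == "nucleotide") {
    ifelse(ch %in% c(.NT_DETERMINATE, "-", "N"), ch, ".")
  } else {
    ifelse(ch %in% c(.AA_DETERMINATE, "-"), ch, ".")
  }
}

#' Multi-panel alignment overview
#'
#' Draws one panel per locus (rows = canonical individuals, columns =
#' sites), colouring each determinate residue with its own class and giving
#' gaps and ambiguous/missing residues distinct classes — the quickest way
#' to eyeball alignment quality and missing-data structure across loci.
#' Optionally adds a final panel showing the concatenated supermatrix.
#' Gap-padded individuals appear as full-width gap bands.
#'
#' @param x a \linkS4class{MultiLocusAlignment}.
#' @param include.concatenated add a panel with
#'   \code{\link{concatenateLoci}} over all loci.
#' @param file optional output path; \code{.png} or \code{.svg} selects the
#'   device, otherwise the current device is used.
#' @param ... passed to \code{\link[ape]{image.DNAbin}} /
#'   \code{image.AAbin}.
#' @return Invisibly, the panel count.
#' @export
plotOverview <- function(x, include.concatenated = FALSE, file = NULL, ...) {
  stopifnot(is(x, "MultiLocusAlignment"))
  panels <- unname(x@loci)
  if (include.concatenated) panels <- c(panels, concatenateLoci(x))
  np <- length(panels)
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           png = grDevices::png(file, width = 900, height = 260 * np),
           svg = grDevices::svg(file, width = 9, height = 2.6 * np),
           stop(sprintf("unsupported image extension '.%s' for %s", ext, file)))
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(np, 1L), mar = c(2.5, 6, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (a in panels) {
    m <- as.matrix(a)
    if (a@alphabet == "nucleotide") {
      bin <- ape::as.DNAbin(m)
    } else {
      m[m == "?"] <- "X"
      bin <- ape::as.AAbin(m)
    }
    graphics::image(bin, main = a@name, ...)
  }
  invisible(np)
}

#' Text-mode alignment overview
#'
#' Emits one character grid per locus: a header line naming the locus, then
#' one row per canonical individual with the residues rendered through the
#' display classes \code{A,C,G,T,-,N} and \code{'.'} for other ambiguity
#' codes (amino-acid data keeps residue letters, with \code{'.'} for
#' ambiguity). Purely read-only.
#'
#' @param x a \linkS4class{MultiLocusAlignment}.
#' @param loci locus selector; \code{NULL} selects all.
#' @return character vector of lines, invisibly when printed.
#' @export
textOverview <- function(x, loci = NULL) {
  stopifnot(is(x, "MultiLocusAlignment"))
  jj <- .resolveSelector(loci, names(x@loci), "locus selection")
  out <- character(0)
  wid <- max(nchar(x@labels))
  for (a in x@loci[jj]) {
    out <- c(out, sprintf("== %s (%d x %d) ==", a@name, length(a@sequences),
                          a@nCols))
    m <- as.matrix(a)
    cls <- matrix(.textClass(m, a@alphabet), nrow = nrow(m))
    out <- c(out, sprintf("%-*s %s", wid, rownames(m),
                          apply(cls, 1L, paste, collapse = "")))
  }
  out
}
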