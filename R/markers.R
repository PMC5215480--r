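## First-appearance integer coding: alleles numbered 1, 2, ... in the order
## they are first seen scanning individuals in canonical order; NA = missing.
.codeFirstAppearance <- function(alleles) {
  seen <- unname(unique(alleles[!is.na(alleles)]))
  list(codes = match(alleles, seen), legend = seen)
}

#' Extract SNP markers into a genotype table
#'
#' Scans every column of every locus. A site's determinate states are
#' \code{A/C/G/T}; gaps, \code{N}, \code{?} and IUPAC ambiguity codes count
#' as missing at that site. A column is a SNP iff at least two distinct
#' determinate states occur, and each SNP becomes one marker (descriptor:
#' locus name + 1-based column). Nucleotide containers only.
#'
#' @param x a \linkS4class{MultiLocusAlignment}.
#' @return A \linkS4class{GenotypeTable} with one column per SNP; individuals
#'   missing (or ambiguous) at a site carry \code{NA} there.
#' @export
extractSNPs <- function(x) {
  stopifnot(is(x, "MultiLocusAlignment"))
  ensureNucleotide(x)
  codes <- list(); legend <- list()
  locus <- character(0); site <- integer(0)
  for (a in x@loci) {
    m <- as.matrix(a)
    m[!m %in% .NT_DETERMINATE] <- NA
    for (j in seq_len(ncol(m))) {
      states <- unique(m[!is.na(m[, j]), j])
      if (length(states) >= 2L) {
        cc <- .codeFirstAppearance(m[, j])
        codes[[length(codes) + 1L]] <- cc$codes
        legend[[length(legend) + 1L]] <- cc$legend
        locus <- c(locus, a@name)
        site <- c(site, j)
      }
    }
  }
  cm <- if (length(codes) > 0L) do.call(cbind, codes)
        else matrix(integer(0), nrow = x@nInd, ncol = 0L)
  rownames(cm) <- x@labels
  colnames(cm) <- if (length(locus) > 0L) sprintf("%s:%d", locus, site)
                  else character(0)
  new("GenotypeTable", individuals = x@labels,
      markers = data.frame(locus = locus, site = site,
                           type = rep("snp", length(locus)),
                           row.names = NULL),
      codes = cm, alleleLegend = legend)
}

#' Code unique sequences per locus as haplotype alleles
#'
#' Generalizes multilocus sequence typing (MLST): within each locus, exact
#' full-length string equality partitions the rows into alleles, numbered by
#' first appearance over individuals in canonical order. Equality is exact —
#' sequences differing only by an \code{N} or an internal gap are distinct
#' alleles. With \code{skip.gap.only} (default) the gap-only padding rows are
#' coded as missing rather than forming a shared "absent" allele.
#'
#' @param x a \linkS4class{MultiLocusAlignment}.
#' @param skip.gap.only code gap-only rows as \code{NA} (default).
#' @return A \linkS4class{GenotypeTable} with one marker per locus; the
#'   legend maps each allele code to its full sequence string.
#' @export
codeHaplotypes <- function(x, skip.gap.only = TRUE) {
  stopifnot(is(x, "MultiLocusAlignment"))
  codes <- list(); legend <- list()
  for (a in x@loci) {
    seqs <- a@sequences
    if (skip.gap.only) seqs[.isGapOnly(seqs)] <- NA
    cc <- .codeFirstAppearance(unname(seqs))
    codes[[length(codes) + 1L]] <- cc$codes
    legend[[length(legend) + 1L]] <- cc$legend
  }
  cm <- do.call(cbind, codes)
  rownames(cm) <- x@labels
  colnames(cm) <- names(x@loci)
  new("GenotypeTable", individuals = x@labels,
      markers = data.frame(locus = names(x@loci), site = NA_integer_,
                           type = rep("haplotype", length(x@loci)),
                           row.names = NULL),
      codes = cm, alleleLegend = legend)
}

#' Number of alleles per marker
#' @param g a \linkS4class{GenotypeTable}.
#' @return named integer vector.
#' @export
numAlleles <- function(g) {
  stopifnot(is(g, "GenotypeTable"))
  stats::setNames(vapply(g@alleleLegend, length, integer(1)),
                  colnames(g@codes))
}

#' Access the code matrix of a genotype table
#' @param g a \linkS4class{GenotypeTable}.
#' @return integer matrix individuals x markers, \code{NA} = missing.
#' @export
genotypeCodes <- function(g) {
  stopifnot(is(g, "GenotypeTable"))
  g@codes
}

setMethod("show", "GenotypeTable", function(object) {
  cat("=== GenotypeTable ===\n")
  cat(sprintf("[%d individuals x %d markers (%s)]\n",
              length(object@individuals), nrow(object@markers),
              paste(unique(object@markers$type), collapse = "+")))
  cat(sprintf("missing calls: %d\n", sum(is.na(object@codes))))
})

#' Export a genotype table as tab-separated text
#'
#' Writes the code matrix as TSV (header row of marker descriptors —
#' \code{locus:column} for SNPs, \code{locus} for haplotype markers — one row
#' per individual, missing rendered as \code{NA}) plus a legend sidecar
#' \code{<path>.legend.tsv} mapping marker/code/allele.
#'
#' @param g a \linkS4class{GenotypeTable}.
#' @param path output path for the genotype TSV.
#' @return Invisibly, the genotype file path.
#' @seealso \code{\link{readGenotypes}} for the inverse.
#' @export
exportGenotypes <- function(g, path) {
  stopifnot(is(g, "GenotypeTable"))
  if (nrow(g@markers) == 0L || length(g@individuals) == 0L)
    stop("refusing to export an empty genotype table")
  utils::write.table(g@codes, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = TRUE, col.names = NA)
  leg <- data.frame(
    marker = rep(colnames(g@codes), vapply(g@alleleLegend, length, integer(1))),
    type = rep(g@markers$type, vapply(g@alleleLegend, length, integer(1))),
    code = unlist(lapply(g@alleleLegend, seq_along)),
    allele = unlist(g@alleleLegend), row.names = NULL)
  utils::write.table(leg, paste0(path, ".legend.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an exported genotype table
#'
#' @param path a genotype TSV written by \code{\link{exportGenotypes}}; its
#'   \code{<path>.legend.tsv} sidecar must sit alongside.
#' @return A \linkS4class{GenotypeTable}.
#' @export
readGenotypes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE, colClasses = "character")
  cm <- as.matrix(df)
  storage.mode(cm) <- "integer"
  leg <- utils::read.table(paste0(path, ".legend.tsv"), sep = "\t",
                           header = TRUE, colClasses = "character",
                           check.names = FALSE)
  markers <- colnames(cm)
  legend <- lapply(markers, function(mk) leg$allele[leg$marker == mk])
  type <- vapply(markers, function(mk) leg$type[leg$marker == mk][1],
                 character(1), USE.NAMES = FALSE)
  locus <- ifelse(type == "snp", sub(":[0-9]+$", "", markers), markers)
  site <- ifelse(type == "snp",
                 suppressWarnings(as.integer(sub("^.*:", "", markers))),
                 NA_integer_)
  new("GenotypeTable", individuals = rownames(cm),
      markers = data.frame(locus = locus, site = site, type = type,
                           row.names = NULL),
      codes = cm, alleleLegend = legend)
}
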