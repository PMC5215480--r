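## Canonical collation: plain code-point (C-locale) ordering, case-sensitive.
## Deliberately locale-independent so harmonization is reproducible across
## machines; note "sample10" sorts before "sample2" under this rule.
.sortLabels <- function(x) sort(x, method = "radix")

## A row is gap-only iff every character is '-'. All-'N'/'?' rows are data
## (ambiguous), not padding.
.isGapOnly <- function(seqs) {
  if (length(seqs) == 0L) return(logical(0))
  vapply(seqs, function(s) {
    n <- nchar(s)
    n > 0L && s == strrep("-", n)
  }, logical(1), USE.NAMES = FALSE)
}

.gapRow <- function(n) strrep("-", n)

## Resolve an individual/locus selector (integer indices, labels, or logical
## mask) against a universe of names, with strict error reporting.
.resolveSelector <- function(sel, universe, what = "selection") {
  n <- length(universe)
  if (is.null(sel)) return(seq_len(n))
  if (is.logical(sel)) {
    if (length(sel) != n)
      stop(sprintf("logical %s mask has length %d, expected %d",
                   what, length(sel), n), call. = FALSE)
    idx <- which(sel)
  } else if (is.numeric(sel)) {
    idx <- as.integer(sel)
    if (anyNA(idx) || any(idx < 1L) || any(idx > n))
      stop(sprintf("%s index out of range 1..%d", what, n), call. = FALSE)
  } else if (is.character(sel)) {
    idx <- match(sel, universe)
    if (anyNA(idx))
      stop(sprintf("unknown %s label(s): %s", what,
                   paste(sel[is.na(idx)], collapse = ", ")), call. = FALSE)
  } else {
    stop(sprintf("unsupported %s selector of class '%s'", what, class(sel)[1]),
         call. = FALSE)
  }
  if (length(idx) == 0L)
    stop(sprintf("empty %s", what), call. = FALSE)
  idx
}

## Alphabet inference: nucleotide iff >= 90% of non-gap, non-'?' residues are
## in {A,C,G,T,U,N} + IUPAC nucleotide ambiguity codes; ties and short-falls
## resolve to amino-acid (the superset alphabet).
.inferAlphabet <- function(seqs) {
  chars <- unlist(strsplit(toupper(seqs), "", fixed = TRUE))
  chars <- chars[!chars %in% c("-", "?")]
  if (length(chars) == 0L) return("nucleotide")
  ntset <- c("A", "C", "G", "T", "U", "N", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V")
  frac <- mean(chars %in% ntset)
  if (frac >= 0.9) "nucleotide" else "amino-acid"
}
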