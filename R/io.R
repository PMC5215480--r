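#' Read a single per-locus alignment file
#'
#' Supported formats: multi-record FASTA, and relaxed Phylip (sequential or
#' interleaved; names are whitespace-delimited rather than fixed 10-column).
#' \code{format = "auto"} detects FASTA by a leading \code{'>'} and otherwise
#' tries sequential then interleaved Phylip. The locus name defaults to the
#' file's base name without extension. Residues are validated against the
#' alphabet; \code{alphabet = "auto"} infers nucleotide iff at least 90\% of
#' non-gap, non-'?' residues are nucleotide symbols (ties and shortfalls fall
#' back to the amino-acid superset alphabet).
#'
#' @param path path to an alignment file.
#' @param format \code{"auto"}, \code{"fasta"}, \code{"phylip-sequential"} or
#'   \code{"phylip-interleaved"}.
#' @param alphabet \code{"auto"}, \code{"nucleotide"} or \code{"amino-acid"}.
#' @param name locus name override.
#' @return A \linkS4class{LocusAlignment}.
#' @export
readLocusFile <- function(path,
                          format = c("auto", "fasta", "phylip-sequential",
                                     "phylip-interleaved"),
                          alphabet = c("auto", "nucleotide", "amino-acid"),
                          name = NULL) {
  format <- match.arg(format)
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(name))
    name <- tools::file_path_sans_ext(basename(path))
  if (format == "auto") {
    lines <- readLines(path, n = 50L, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    format <- if (length(lines) > 0L && startsWith(trimws(lines[1]), ">"))
      "fasta" else "phylip-auto"
  }
  seqs <- switch(format,
    "fasta" = .readFasta(path),
    "phylip-sequential" = .readPhylip(path, interleaved = FALSE),
    "phylip-interleaved" = .readPhylip(path, interleaved = TRUE),
    "phylip-auto" = tryCatch(.readPhylip(path, interleaved = FALSE),
                             error = function(e) .readPhylip(path, TRUE)))
  tryCatch(locusAlignment(seqs, name = name, alphabet = alphabet),
           error = function(e)
             stop(sprintf("%s: %s", path, conditionMessage(e)), call. = FALSE))
}

.readFasta <- function(path) {
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e)
                  stop(sprintf("%s: FASTA parse error: %s", path,
                               conditionMessage(e)), call. = FALSE))
  if (length(x) == 0L)
    stop(sprintf("%s: no FASTA records", path), call. = FALSE)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

## Relaxed Phylip: "<n> <n_cols>" header, whitespace-delimited names.
## Sequential records may wrap over lines; interleaved blocks carry names in
## the first block only.
.readPhylip <- function(path, interleaved) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- trimws(lines[nzchar(trimws(lines))])
  if (length(nonblank) < 2L)
    stop(sprintf("%s: truncated Phylip file", path), call. = FALSE)
  hdr <- strsplit(nonblank[1], "\\s+")[[1]]
  n <- suppressWarnings(as.integer(hdr[1]))
  m <- suppressWarnings(as.integer(hdr[2]))
  if (length(hdr) != 2L || anyNA(c(n, m)) || n < 1L || m < 1L)
    stop(sprintf("%s: malformed Phylip counts line '%s'", path, nonblank[1]),
         call. = FALSE)
  body <- nonblank[-1]
  if (!interleaved) {
    toks <- unlist(strsplit(body, "\\s+"))
    seqs <- character(0)
    i <- 1L
    for (k in seq_len(n)) {
      if (i > length(toks))
        stop(sprintf("%s: expected %d records, found %d", path, n, k - 1L),
             call. = FALSE)
      nm <- toks[i]; i <- i + 1L
      acc <- ""
      while (nchar(acc) < m) {
        if (i > length(toks))
          stop(sprintf("%s: sequence '%s' shorter than %d", path, nm, m),
               call. = FALSE)
        acc <- paste0(acc, toks[i]); i <- i + 1L
      }
      if (nchar(acc) != m)
        stop(sprintf("%s: sequence '%s' is %d columns, expected %d",
                     path, nm, nchar(acc), m), call. = FALSE)
      seqs[nm] <- acc
    }
    if (i <= length(toks))
      stop(sprintf("%s: trailing content after %d records", path, n),
           call. = FALSE)
  } else {
    if (length(body) %% n != 0L)
      stop(sprintf("%s: interleaved body (%d lines) is not a multiple of %d",
                   path, length(body), n), call. = FALSE)
    first <- body[seq_len(n)]
    toks <- strsplit(first, "\\s+")
    nms <- vapply(toks, `[`, character(1), 1L)
    seqs <- stats::setNames(
      vapply(toks, function(t) paste(t[-1], collapse = ""), character(1)), nms)
    rest <- body[-seq_len(n)]
    for (r in seq_along(rest)) {
      k <- ((r - 1L) %% n) + 1L
      seqs[k] <- paste0(seqs[k], gsub("\\s+", "", rest[r]))
    }
    if (any(nchar(seqs) != m))
      stop(sprintf("%s: sequence lengths %s do not match header %d", path,
                   paste(unique(nchar(seqs)), collapse = ","), m),
           call. = FALSE)
  }
  seqs
}

#' Read one file per locus into a harmonized container
#'
#' Reads every path with \code{\link{readLocusFile}} (locus names taken from
#' the file base names, kept in the given order) and harmonizes the loci with
#' \code{\link{multiLocusAlignment}}. With \code{add.gaps = FALSE} no
#' gap-only padding is added and files must share an identical label set.
#'
#' @inheritParams readLocusFile
#' @param paths character vector of alignment file paths, one per locus.
#' @param add.gaps pad missing individuals with gap-only rows (default).
#' @return A \linkS4class{MultiLocusAlignment}.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' writeLines(c(">a", "ACGT", ">b", "ACCT"), file.path(dir, "g1.fasta"))
#' writeLines(c(">b", "GGTT", ">c", "GGTA"), file.path(dir, "g2.fasta"))
#' x <- readMulti(list.files(dir, full.names = TRUE))
#' getNumSequences(x)
#' @export
readMulti <- function(paths,
                      format = c("auto", "fasta", "phylip-sequential",
                                 "phylip-interleaved"),
                      alphabet = c("auto", "nucleotide", "amino-acid"),
                      add.gaps = TRUE) {
  if (length(paths) == 0L) stop("no input files given")
  loci <- lapply(paths, readLocusFile, format = format, alphabet = alphabet)
  nms <- vapply(loci, function(a) a@name, character(1))
  if (anyDuplicated(nms))
    stop(sprintf("duplicate locus names across files: %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  ## auto-inference can disagree across short loci; unify to the container-level
  ## consensus before harmonization when the user asked for auto
  alphabet <- match.arg(alphabet)
  if (alphabet == "auto") {
    tags <- vapply(loci, function(a) a@alphabet, character(1))
    if (length(unique(tags)) > 1L)
      stop(sprintf("inferred alphabets disagree across files (%s); pass an explicit alphabet",
                   paste(sprintf("%s: %s", nms, tags), collapse = ", ")))
  }
  multiLocusAlignment(loci, add.gaps = add.gaps)
}

#' Write a container as one alignment file per locus
#'
#' Writes \code{<locus>.fasta} (80-column wrapped) or \code{<locus>.phy}
#' (relaxed sequential Phylip) files into \code{dir}. With
#' \code{include.gap.only = FALSE} the gap-only padding rows are omitted,
#' inverting harmonization; a locus left without any sequence aborts the
#' export before any file is written.
#'
#' @param x a \linkS4class{MultiLocusAlignment}.
#' @param dir output directory (created if needed).
#' @param format \code{"fasta"} or \code{"phylip-sequential"}.
#' @param include.gap.only keep the gap-only padding rows (default).
#' @return Invisibly, the written file paths.
#' @export
writeMulti <- function(x, dir, format = c("fasta", "phylip-sequential"),
                       include.gap.only = TRUE) {
  stopifnot(is(x, "MultiLocusAlignment"))
  format <- match.arg(format)
  keep <- lapply(x@loci, function(a) {
    seqs <- a@sequences
    if (!include.gap.only) seqs <- seqs[!.isGapOnly(seqs)]
    if (length(seqs) == 0L)
      stop(sprintf("locus '%s' has no sequences to write (all gap-only)",
                   a@name))
    seqs
  })
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "fasta") "fasta" else "phy"
  paths <- file.path(dir, sprintf("%s.%s", names(x@loci), ext))
  for (k in seq_along(keep)) {
    seqs <- keep[[k]]
    if (format == "fasta") {
      Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), paths[k],
                                  width = 80L)
    } else {
      writeLines(c(sprintf("%d %d", length(seqs), nchar(seqs[1])),
                   sprintf("%s  %s", names(seqs), seqs)), paths[k])
    }
  }
  invisible(paths)
}

#' Gate a container to nucleotide data
#'
#' Conversions and analyses restricted to DNA (SNP extraction, JC69/K80
#' distances) pass through this gate: the container is returned unchanged iff
#' its alphabet tag is nucleotide, otherwise an error names the first
#' offending locus.
#'
#' @param x a \linkS4class{MultiLocusAlignment}.
#' @return \code{x}, unchanged.
#' @export
ensureNucleotide <- function(x) {
  stopifnot(is(x, "MultiLocusAlignment"))
  if (x@type != "nucleotide")
    stop(sprintf("nucleotide data required, but locus '%s' is %s",
                 names(x@loci)[1], x@type))
  x
}
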