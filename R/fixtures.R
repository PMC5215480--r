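#' Specification for a synthetic multi-locus data set
#'
#' Captures everything needed to simulate a reproducible multi-locus data
#' set: the individual labels, per-locus alignment lengths, which
#' individuals are present at each locus, an optional generating tree, and a
#' divergence level.
#'
#' @param n.ind number of individuals (labelled \code{ind_01}, ... unless
#'   \code{labels} is given).
#' @param locus.lengths integer vector of per-locus column counts.
#' @param presence list (one element per locus) of labels present at that
#'   locus; \code{NULL} means everyone present everywhere.
#' @param tree optional generating \code{phylo} tree whose tips are the
#'   individuals; when \code{NULL} sequences are i.i.d. uniform over
#'   \code{A/C/G/T}.
#' @param rate expected substitutions per site from root to tip along the
#'   generating tree (branch lengths are rescaled so the mean root-to-tip
#'   path equals \code{rate}); \code{0} yields identical sequences.
#' @param labels optional explicit individual labels.
#' @param locus.names optional locus names (default \code{locus1}, ...).
#' @return A list with class \code{"fixtureSpec"}.
#' @export
fixtureSpec <- function(n.ind, locus.lengths, presence = NULL, tree = NULL,
                        rate = 0.05, labels = NULL, locus.names = NULL) {
  if (is.null(labels))
    labels <- sprintf("ind_%02d", seq_len(n.ind))
  stopifnot(length(labels) == n.ind, all(locus.lengths > 0L), rate >= 0)
  nloc <- length(locus.lengths)
  if (is.null(locus.names)) locus.names <- sprintf("locus%d", seq_len(nloc))
  if (is.null(presence)) presence <- rep(list(labels), nloc)
  stopifnot(length(presence) == nloc)
  for (p in presence)
    if (!all(p %in% labels))
      stop("presence subsets must be drawn from the label set")
  if (all(lengths(presence) == 0L))
    stop("contradictory spec: every locus has an empty presence set")
  if (!is.null(tree) && !setequal(tree$tip.label, labels))
    stop("generating tree tips must match the labels")
  structure(list(n.ind = n.ind, labels = labels,
                 locus.lengths = as.integer(locus.lengths),
                 locus.names = locus.names, presence = presence,
                 tree = tree, rate = rate),
            class = "fixtureSpec")
}

## Evolve one locus: equal-rate (Jukes-Cantor) substitution along the tree via
## phangorn::simSeq, or i.i.d. uniform sites when no tree is given.
.simulateLocus <- function(spec, len) {
  if (is.null(spec$tree)) {
    m <- matrix(sample(c("A", "C", "G", "T"), spec$n.ind * len, replace = TRUE),
                nrow = spec$n.ind, dimnames = list(spec$labels, NULL))
    return(m)
  }
  tr <- spec$tree
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  mean.depth <- mean(depths)
  tr$edge.length <- if (mean.depth > 0) tr$edge.length * spec$rate / mean.depth
                    else tr$edge.length * 0
  s <- phangorn::simSeq(tr, l = len, type = "DNA")
  m <- as.character(s)
  m[] <- toupper(m)
  m[spec$labels, , drop = FALSE]
}

#' Simulate a multi-locus container (and its FASTA files)
#'
#' Generates sequences for every locus described by \code{spec} — evolved down the
#' generating tree under equal-rate substitution over \code{A/C/G/T}, or
#' i.i.d. uniform when no tree is given — writes one FASTA file per locus
#' (individuals absent from a locus's presence set are omitted from its
#' file), and reads the files back through \code{\link{readMulti}} with
#' gap-padding. Fully reproducible from \code{seed}.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param dir directory for the FASTA files (default: a fresh tempdir).
#' @param seed integer seed driving all randomness.
#' @return A \linkS4class{MultiLocusAlignment}; the file directory is
#'   attached as attribute \code{"dir"}.
#' @export
simulateContainer <- function(spec, dir = tempfile("mlfix"), seed = 1L) {
  stopifnot(inherits(spec, "fixtureSpec"))
  set.seed(seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (k in seq_along(spec$locus.lengths)) {
    m <- .simulateLocus(spec, spec$locus.lengths[k])
    keep <- spec$presence[[k]]
    if (length(keep) == 0L) next
    seqs <- apply(m[keep, , drop = FALSE], 1L, paste, collapse = "")
    p <- file.path(dir, sprintf("%s.fasta", spec$locus.names[k]))
    writeLines(paste0(">", names(seqs), "\n", seqs), p)
    paths <- c(paths, p)
  }
  x <- readMulti(paths, format = "fasta", alphabet = "nucleotide",
                 add.gaps = TRUE)
  attr(x, "dir") <- dir
  x
}

#' The worked-example fixture: 8 individuals, 4 loci, counts 5/6/8/5
#'
#' A synthetic data set emulating the structure of a classic multi-locus
#' study: 8 individuals typed at 4 nuclear loci (named
#' \code{patr_poat43/47/48/49}), where only 5, 6, 8 and 5 individuals are
#' present at the four loci respectively (the third locus covers everyone).
#' After gap-padding harmonization the container holds 32 sequences of which
#' 8 are gap-only. Sequences are simulated along a random 8-taxon tree;
#' which individuals are missing at the incomplete loci is drawn from the
#' seed.
#'
#' @param seed integer seed.
#' @return A \linkS4class{MultiLocusAlignment} with \code{n.ind = 8},
#'   \code{n.seq = 32}, \code{n.seq.miss = 8}.
#' @examples
#' x <- workedExampleFixture(1)
#' getNumSequences(x)  # 5 6 8 5
#' @export
workedExampleFixture <- function(seed = 1L) {
  set.seed(seed)
  labels <- sprintf("tax_%02d.ab1", 1:8)
  tree <- ape::rtree(8, tip.label = labels)
  counts <- c(5L, 6L, 8L, 5L)
  presence <- lapply(counts, function(k) sort(sample(labels, k)))
  spec <- fixtureSpec(n.ind = 8, locus.lengths = c(632L, 540L, 702L, 584L),
                      presence = presence, tree = tree, rate = 0.05,
                      labels = labels,
                      locus.names = paste0("patr_poat", c(43, 47, 48, 49)))
  simulateContainer(spec, seed = seed + 1L)
}
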