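#' Neighbour-joining tree from a distance matrix
#'
#' Classical neighbour-joining (Saitou-Nei agglomeration with the
#' Studier-Keppler criterion, as implemented in \code{\link[ape]{nj}});
#' consistent on additive distances. The output is unrooted (trifurcating at
#' the root node) and branch lengths are returned as computed — they may be
#' negative; see \code{\link{buildTrees}} for clamping. Distances with
#' undefined or saturated pairs are refused rather than imputed. Two labels
#' yield the degenerate single-edge tree.
#'
#' @param d a \code{\link[stats]{dist}}, e.g. from
#'   \code{\link{pairwiseDistance}}.
#' @return An \code{\link[ape]{ape}} \code{phylo} tree.
#' @export
njTree <- function(d) {
  dm <- as.matrix(d)
  if (anyNA(dm)) {
    bad <- flaggedPairs(d)
    lab <- if (nrow(bad) > 0L)
      sprintf(" (%s)", paste(sprintf("%s-%s", bad$a, bad$b), collapse = ", "))
    else ""
    stop(sprintf("incomplete distances: %d undefined/saturated pair(s)%s",
                 sum(is.na(dm[upper.tri(dm)])), lab))
  }
  n <- nrow(dm)
  if (n < 2L) stop("at least two labels are required")
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2L, 2L),
               edge.length = rep(dm[1, 2] / 2, 2L),
               tip.label = rownames(dm), Nnode = 1L)
    class(tr) <- "phylo"
    attr(tr, "order") <- "cladewise"
    return(tr)
  }
  ape::nj(stats::as.dist(dm))
}

#' Neighbour-joining trees per locus or on the supermatrix
#'
#' Reproduces the default per-locus tree workflow: for each locus, gap-only
#' (padding) rows are dropped — they carry no data and would poison the
#' distances — then pairwise-deletion distances are computed (Hamming
#' p-distance by default), a neighbour-joining tree is built, negative
#' branch lengths are clamped to zero, and the tree is ladderized. With
#' \code{pool = TRUE} a single tree is built from the concatenation of all
#' loci over all individuals (padded rows included, since each individual
#' has data at some locus).
#'
#' A locus with fewer than 3 non-gap-only individuals cannot be resolved and
#' is skipped with a warning; skipped loci are listed in the result's
#' \code{"skipped"} attribute.
#'
#' @inheritParams pairwiseDistance
#' @param x a \linkS4class{MultiLocusAlignment}.
#' @param pool build one tree from the concatenated alignment.
#' @param clamp force negative branch lengths to zero (default \code{TRUE}).
#' @param ladderize ladderize for reproducible display (default \code{TRUE}).
#' @return A named list of \code{phylo} trees (possibly with a
#'   \code{"skipped"} attribute), or a single \code{phylo} when
#'   \code{pool = TRUE}.
#' @export
buildTrees <- function(x, pool = FALSE, model = c("p", "raw", "jc69", "k80"),
                       clamp = TRUE, ladderize = TRUE) {
  stopifnot(is(x, "MultiLocusAlignment"))
  model <- match.arg(model)
  finish <- function(tr) {
    if (clamp) tr$edge.length[tr$edge.length < 0] <- 0
    if (ladderize) tr <- ape::ladderize(tr)
    tr
  }
  if (pool) {
    d <- pairwiseDistance(concatenateLoci(x), model = model)
    return(finish(njTree(d)))
  }
  trees <- list(); skipped <- character(0)
  for (nm in names(x@loci)) {
    a <- x@loci[[nm]]
    keep <- !.isGapOnly(a@sequences)
    if (sum(keep) < 3L) {
      warning(sprintf("locus '%s' skipped: only %d non-gap-only sequence(s)",
                      nm, sum(keep)))
      skipped <- c(skipped, nm)
      next
    }
    sub <- a
    sub@sequences <- a@sequences[keep]
    trees[[nm]] <- finish(njTree(pairwiseDistance(sub, model = model)))
  }
  if (length(skipped) > 0L) attr(trees, "skipped") <- skipped
  trees
}

#' Robinson-Foulds incongruence between two trees
#'
#' Symmetric difference of the non-trivial bipartitions of the two
#' topologies, computed on the induced subtrees over the leaves the trees
#' share (so per-locus trees with different taxon sets remain comparable).
#' At least 4 shared leaves are required for any non-trivial split to exist.
#'
#' @param t1,t2 \code{phylo} trees.
#' @return Integer RF distance.
#' @export
rfDistance <- function(t1, t2) {
  common <- intersect(t1$tip.label, t2$tip.label)
  if (length(common) < 4L)
    stop(sprintf("trees share only %d leaves; at least 4 are required",
                 length(common)))
  s1 <- ape::unroot(ape::keep.tip(t1, common))
  s2 <- ape::unroot(ape::keep.tip(t2, common))
  as.integer(phangorn::RF.dist(s1, s2, check.labels = TRUE))
}

#' Pairwise Robinson-Foulds table over a set of trees
#' @param trees named list of \code{phylo} trees.
#' @return symmetric integer matrix with zero diagonal; \code{NA} where two
#'   trees share fewer than 4 leaves.
#' @export
rfTable <- function(trees) {
  n <- length(trees)
  nms <- names(trees)
  out <- matrix(0L, n, n, dimnames = list(nms, nms))
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    out[i, j] <- out[j, i] <- tryCatch(rfDistance(trees[[i]], trees[[j]]),
                                       error = function(e) NA_integer_)
  out
}

## Newick quoting shim around ape: ape's writer replaces special characters,
## and its reader keeps quotes inside the label; labels with whitespace or
## Newick metacharacters are therefore protected by placeholder substitution
## on both paths.
.NEEDS_QUOTE <- "[][\\s(),:;']"

#' Read and write Newick trees
#'
#' \code{writeNewick} serializes with 6 significant digits on branch lengths
#' and a trailing \code{';'}; labels containing whitespace or Newick
#' metacharacters are single-quoted. \code{readNewick} parses labels,
#' branch lengths and multifurcations, and strips such quoting.
#'
#' @param t a \code{phylo} tree.
#' @param path optional file path; when \code{NULL} the Newick string is
#'   returned (write) or \code{text} is parsed (read).
#' @param text a Newick string (read).
#' @return \code{writeNewick}: the Newick string (invisibly when written to
#'   a file); \code{readNewick}: a \code{phylo} tree.
#' @export
writeNewick <- function(t, path = NULL) {
  labs <- t$tip.label
  need <- grepl(.NEEDS_QUOTE, labs, perl = TRUE)
  ph <- sprintf("QLBL%dQ", seq_along(labs))
  t$tip.label <- ifelse(need, ph, labs)
  s <- ape::write.tree(t, digits = 6)
  for (k in which(need))
    s <- sub(ph[k], paste0("'", labs[k], "'"), s, fixed = TRUE)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' @rdname writeNewick
#' @export
readNewick <- function(text = NULL, path = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("give either 'text' or 'path'")
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  ## extract quoted labels before handing the string to ape
  quoted <- regmatches(text, gregexpr("'[^']*'", text))[[1]]
  ph <- sprintf("QLBL%dQ", seq_along(quoted))
  for (k in seq_along(quoted))
    text <- sub(quoted[k], ph[k], text, fixed = TRUE)
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                 error = function(e) NULL)
  if (is.null(tr))
    stop(sprintf("malformed Newick near: %s",
                 substr(text, 1, min(60L, nchar(text)))))
  restore <- function(v) {
    hit <- match(v, ph)
    ifelse(is.na(hit), v, substr(quoted[hit], 2L, nchar(quoted[hit]) - 1L))
  }
  tr$tip.label <- restore(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- restore(tr$node.label)
  tr
}
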