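## Transition pairs under Kimura's two-parameter model: purine<->purine
## (A-G) and pyrimidine<->pyrimidine (C-T); everything else determinate is a
## transversion.
.isTransition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
  (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Pairwise genetic distances with pairwise deletion
#'
#' For each pair of sequences, comparison is restricted to the columns where
#' both rows carry a determinate residue (\code{A/C/G/T} for nucleotide
#' data; the 20 standard residues for amino acids) — gaps, \code{N},
#' \code{?} and ambiguity codes are deleted pairwise. Models:
#' \describe{
#'   \item{\code{raw}}{number of mismatching compared sites (Hamming count).}
#'   \item{\code{p}}{mismatch proportion \eqn{p} = mismatches / compared
#'     sites (Hamming/p-distance).}
#'   \item{\code{jc69}}{Jukes-Cantor correction
#'     \eqn{d = -\frac{3}{4}\ln(1 - \frac{4p}{3})}.}
#'   \item{\code{k80}}{Kimura two-parameter
#'     \eqn{d = -\frac{1}{2}\ln(1 - 2P - Q) - \frac{1}{4}\ln(1 - 2Q)}, with
#'     \eqn{P} and \eqn{Q} the transition and transversion proportions over
#'     compared sites.}
#' }
#' A pair with zero compared sites is undefined (\code{NA}, status
#' \code{"undefined"}); a pair whose model log argument is non-positive is
#' saturated (\code{NA}, status \code{"saturated"}). Undefined pairs are
#' never silently imputed — downstream tree building refuses them.
#'
#' @param a a \linkS4class{LocusAlignment} with at least 2 sequences.
#' @param model \code{"p"} (default), \code{"raw"}, \code{"jc69"} or
#'   \code{"k80"}; the corrections require nucleotide data.
#' @return A \code{\link[stats]{dist}} object with attributes \code{model}
#'   and \code{status} (a labelled character matrix: \code{"ok"},
#'   \code{"undefined"} or \code{"saturated"}).
#' @examples
#' a <- locusAlignment(c(x = "ACGT-A", y = "ACCTNA"))
#' pairwiseDistance(a, "p")  # 5 compared sites, 1 mismatch -> 0.2
#' @export
pairwiseDistance <- function(a, model = c("p", "raw", "jc69", "k80")) {
  stopifnot(is(a, "LocusAlignment"))
  model <- match.arg(model)
  if (length(a@sequences) < 2L)
    stop("at least two sequences are required for distances")
  if (model %in% c("jc69", "k80") && a@alphabet != "nucleotide")
    stop(sprintf("model '%s' requires nucleotide data", model))
  m <- as.matrix(a)
  det <- if (a@alphabet == "nucleotide") .NT_DETERMINATE else .AA_DETERMINATE
  ok <- matrix(m %in% det, nrow = nrow(m))
  n <- nrow(m)
  labs <- rownames(m)
  vals <- matrix(0, n, n, dimnames = list(labs, labs))
  status <- matrix("ok", n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- ok[i, ] & ok[j, ]
    nc <- sum(shared)
    if (nc == 0L) {
      d <- NA_real_; st <- "undefined"
    } else {
      xi <- m[i, shared]; xj <- m[j, shared]
      mism <- sum(xi != xj)
      st <- "ok"
      d <- switch(model,
        raw = mism,
        p = mism / nc,
        jc69 = {
          arg <- 1 - 4 * (mism / nc) / 3
          if (arg <= 0) { st <- "saturated"; NA_real_ }
          else -0.75 * log(arg)
        },
        k80 = {
          ts <- .isTransition(xi, xj)
          P <- sum(ts) / nc
          Q <- sum(xi != xj & !ts) / nc
          a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
          if (a1 <= 0 || a2 <= 0) { st <- "saturated"; NA_real_ }
          else -0.5 * log(a1) - 0.25 * log(a2)
        })
    }
    vals[i, j] <- vals[j, i] <- d
    status[i, j] <- status[j, i] <- st
  }
  out <- stats::as.dist(vals)
  attr(out, "model") <- model
  attr(out, "status") <- status
  out
}

#' Which pairs of a distance matrix are undefined or saturated?
#' @param d a distance from \code{\link{pairwiseDistance}}.
#' @return data.frame with columns \code{a}, \code{b}, \code{status}; zero
#'   rows when every pair is defined.
#' @export
flaggedPairs <- function(d) {
  st <- attr(d, "status")
  if (is.null(st)) st <- matrix("ok", 0, 0)
  bad <- which(upper.tri(st) & st != "ok", arr.ind = TRUE)
  data.frame(a = rownames(st)[bad[, 1]], b = colnames(st)[bad[, 2]],
             status = st[bad], row.names = NULL)
}

#' Distances per locus or on the concatenated supermatrix
#'
#' With \code{pool = FALSE} (default) one distance matrix per locus is
#' returned, each over the full canonical label set (gap-only padded rows
#' included, hence typically undefined against everything at that locus).
#' With \code{pool = TRUE} a single matrix is computed on
#' \code{\link{concatenateLoci}} over all loci.
#'
#' @inheritParams pairwiseDistance
#' @param x a \linkS4class{MultiLocusAlignment}.
#' @param pool concatenate all loci before computing (default \code{FALSE}).
#' @return A named list of \code{dist} objects, or a single \code{dist} when
#'   \code{pool = TRUE}.
#' @export
distMultiLocus <- function(x, pool = FALSE, model = c("p", "raw", "jc69", "k80")) {
  stopifnot(is(x, "MultiLocusAlignment"))
  model <- match.arg(model)
  if (pool) pairwiseDistance(concatenateLoci(x), model = model)
  else lapply(x@loci, pairwiseDistance, model = model)
}

#' Write a distance matrix as square tab-separated text
#' @param d a \code{dist} object.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeDistances <- function(d, path) {
  utils::write.table(as.matrix(d), path, sep = "\t", quote = FALSE,
                     na = "NA", col.names = NA)
  invisible(path)
}
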