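# Independent brute-force oracles and small random-fixture generators.
# Everything here is deliberately naive (per-column scans, explicit
# enumeration) so tests check the implementation against a second route.

NT <- c("A", "C", "G", "T")

# random character alignment matrix with injected gaps/Ns
randAlnMatrix <- function(n, m, gap.prob = 0.1, amb.prob = 0.05,
                          labels = sprintf("t%02d", seq_len(n))) {
  chars <- sample(NT, n * m, replace = TRUE)
  r <- runif(n * m)
  chars[r < gap.prob] <- "-"
  chars[r >= gap.prob & r < gap.prob + amb.prob] <- "N"
  matrix(chars, n, m, dimnames = list(labels, NULL))
}

randLocus <- function(n, m, name = "loc", ...) {
  locusAlignment(randAlnMatrix(n, m, ...), name = name,
                 alphabet = "nucleotide")
}

# random presence mask -> list of LocusAlignment with per-locus label subsets
randPresenceLoci <- function(n.ind, n.loc, m = 12L) {
  labels <- sprintf("t%02d", seq_len(n.ind))
  present <- lapply(seq_len(n.loc), function(k) {
    keep <- labels[runif(n.ind) < 0.7]
    if (length(keep) == 0L) keep <- sample(labels, 1L)
    keep
  })
  loci <- lapply(seq_len(n.loc), function(k) {
    mm <- randAlnMatrix(length(present[[k]]), m, gap.prob = 0.05,
                        labels = present[[k]])
    locusAlignment(mm, name = sprintf("loc%d", k), alphabet = "nucleotide")
  })
  list(loci = loci, labels = labels, present = present)
}

# brute-force pairwise-deletion comparison of two character rows
bfPairCounts <- function(a, b) {
  shared <- a %in% NT & b %in% NT
  list(compared = sum(shared),
       mismatches = sum(a[shared] != b[shared]),
       transitions = sum((a[shared] == "A" & b[shared] == "G") |
                         (a[shared] == "G" & b[shared] == "A") |
                         (a[shared] == "C" & b[shared] == "T") |
                         (a[shared] == "T" & b[shared] == "C")))
}

# brute-force SNP columns: >= 2 distinct determinate states
bfSnpColumns <- function(m) {
  which(vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    length(unique(v[v %in% NT])) >= 2L
  }, logical(1)))
}

# non-trivial bipartitions of an unrooted phylo, as canonical strings
bfSplits <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  n <- length(tips)
  desc <- function(node) {
    if (node <= n) return(tips[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  internal <- tree$edge[, 2][tree$edge[, 2] > n]
  keys <- vapply(internal, function(v) {
    side <- sort(desc(v))
    other <- sort(setdiff(tips, side))
    if (length(side) < 2L || length(other) < 2L) return(NA_character_)
    # canonical: the side containing the alphabetically first tip
    if (min(tips) %in% side) paste(side, collapse = "|")
    else paste(other, collapse = "|")
  }, character(1))
  unique(keys[!is.na(keys)])
}

bfRF <- function(t1, t2) {
  s1 <- bfSplits(t1); s2 <- bfSplits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# exhaustive least-squares quartet fit: returns the winning split key "ab|cd"
bfQuartetLS <- function(d) {
  labs <- attr(d, "Labels")
  stopifnot(length(labs) == 4L)
  dm <- as.matrix(d)
  tops <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  rss <- vapply(tops, function(tp) {
    # edges: e1..e4 pendant (in label order 1..4), e5 internal separating
    # {tp[1],tp[2]} from {tp[3],tp[4]}
    pairs <- t(combn(4, 2))
    X <- matrix(0, nrow(pairs), 5)
    y <- numeric(nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      X[r, i] <- 1; X[r, j] <- 1
      same <- (i %in% tp[1:2]) == (j %in% tp[1:2])
      if (!same) X[r, 5] <- 1
      y[r] <- dm[i, j]
    }
    fit <- lm.fit(X, y)
    sum(fit$residuals^2)
  }, numeric(1))
  tp <- tops[[which.min(rss)]]
  g1 <- sort(labs[tp[1:2]]); g2 <- sort(labs[tp[3:4]])
  if (min(labs) %in% g1) paste(g1, collapse = "|") else paste(g2, collapse = "|")
}

# split key of the cherry-side of an unrooted quartet tree
quartetKey <- function(tree) {
  s <- bfSplits(tree)
  stopifnot(length(s) == 1L)
  s
}

# additive distances implied by a tree (path lengths)
treeDistances <- function(tree) {
  stats::as.dist(ape::cophenetic.phylo(tree))
}

expect_valid_container <- function(x) {
  expect_s4_class(x, "MultiLocusAlignment")
  expect_true(validObject(x))
}
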