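test_that("harmonization pads missing individuals and keeps the books", {
  a <- locusAlignment(c(s1 = "ACGT", s2 = "ACCT"), name = "g1")
  b <- locusAlignment(c(s2 = "GG", s3 = "GT"), name = "g2")
  x <- multiLocusAlignment(list(a, b))
  expect_valid_container(x)
  expect_identical(getLabels(x), c("s1", "s2", "s3"))
  expect_identical(x@nSeq, 6L)
  expect_identical(x@nSeqMiss, 2L)
  expect_identical(x@loci$g2@sequences[["s1"]], "--")

  # single locus, all present: no padding, rows re-ordered to canonical order
  c1 <- locusAlignment(c(z = "AA", a = "AC", m = "GG"), name = "solo")
  y <- multiLocusAlignment(list(c1))
  expect_identical(y@nSeqMiss, 0L)
  expect_identical(names(y@loci$solo@sequences), c("a", "m", "z"))
  expect_identical(y@loci$solo@sequences[["z"]], "AA")
})

test_that("pre-existing gap-only rows count as missing; all-N rows do not", {
  a <- locusAlignment(c(s1 = "ACGT", s2 = "----", s3 = "NNNN"), name = "g1")
  x <- multiLocusAlignment(list(a))
  expect_identical(x@nSeqMiss, 1L)
  expect_identical(unname(getNumSequences(x)), 2L)
})

test_that("construction errors: mixed alphabets, duplicates, incomplete data", {
  nt <- locusAlignment(c(s1 = "ACGT"), name = "g1", alphabet = "nucleotide")
  aa <- locusAlignment(c(s1 = "MKLF"), name = "g2", alphabet = "amino-acid")
  expect_error(multiLocusAlignment(list(nt, aa)), "mixed alphabets")
  expect_error(locusAlignment(c(s1 = "ACGT", s1 = "ACCT")), "duplicate")
  expect_error(locusAlignment(c(s1 = "ACGT", s2 = "ACC")), "ragged")
  b <- locusAlignment(c(s2 = "GG", s3 = "GT"), name = "g2")
  expect_error(multiLocusAlignment(list(nt, b), add.gaps = FALSE),
               "incomplete data")
})

test_that("harmonization invariants hold on random presence masks and rebuilding is idempotent", {
  set.seed(101)
  for (rep in 1:25) {
    f <- randPresenceLoci(n.ind = 10L, n.loc = 3L)
    x <- multiLocusAlignment(f$loci)
    expect_identical(x@nSeq, x@nInd * length(x@loci))
    # brute-force count of absent (individual, locus) pairs; the universe is
    # the union of individuals with at least one sequence
    union.labs <- unique(unlist(f$present))
    expect_identical(x@nInd, length(union.labs))
    expected.miss <- sum(vapply(f$present, function(p)
      length(setdiff(union.labs, p)), integer(1)))
    # injected gap rows can never arise here (gap.prob per char, all-gap row
    # astronomically unlikely at 12 cols), so padding is the only source
    expect_identical(x@nSeqMiss, as.integer(expected.miss))
    # idempotence: re-building from harmonized loci changes nothing
    x2 <- multiLocusAlignment(x@loci)
    expect_equal(x2, x)
  }
})

test_that("subsetting follows selector semantics and recomputes counts", {
  set.seed(7)
  f <- randPresenceLoci(n.ind = 8L, n.loc = 4L)
  x <- multiLocusAlignment(f$loci)

  # identity selection
  expect_equal(x[seq_len(x@nInd), seq_along(x@loci)], x)

  # label selection = equivalent logical mask
  ids <- getLabels(x)[c(2, 4, 6, 8)]
  mask <- getLabels(x) %in% ids
  expect_equal(x[ids, ], x[mask, ])

  # counts recomputed on a slice
  s <- x[ids, c(1, 3)]
  expect_identical(s@nInd, 4L)
  expect_identical(s@nSeq, 8L)
  recount <- sum(vapply(s@loci, function(a)
    sum(vapply(a@sequences, function(z) z == strrep("-", nchar(z)), logical(1))),
    integer(1)))
  expect_identical(s@nSeqMiss, as.integer(recount))

  # composition law: subset of subset = single subset with intersected selectors
  i1 <- getLabels(x)[1:6]; i2 <- getLabels(x)[4:8]
  expect_equal(x[i1, c("loc1", "loc2")][intersect(i1, i2), "loc2"],
               x[intersect(i1, i2), "loc2"])

  # errors
  expect_error(x["nope", ], "unknown individual")
  expect_error(x[, 99], "out of range")
  expect_error(x[character(0), ], "empty")
})

test_that("loci that become entirely gap-only are retained by subsetting", {
  a <- locusAlignment(c(s1 = "ACGT"), name = "g1")
  b <- locusAlignment(c(s2 = "GGTT"), name = "g2")
  x <- multiLocusAlignment(list(a, b))
  s <- x["s1", ]
  expect_identical(getNumLoci(s), 2L)
  expect_identical(unname(getNumSequences(s)), c(1L, 0L))
})

test_that("concatenation juxtaposes rows and records 1-based closed partitions", {
  set.seed(11)
  f <- randPresenceLoci(n.ind = 6L, n.loc = 3L, m = 10L)
  x <- multiLocusAlignment(f$loci)
  y <- concatenateLoci(x)
  expect_identical(nCols(y), sum(vapply(x@loci, nCols, integer(1))))
  p <- getPartitions(y)
  expect_identical(p$start[1], 1L)
  expect_identical(p$end[nrow(p)], nCols(y))
  # character-wise juxtaposition per individual
  for (lab in getLabels(x))
    expect_identical(y@sequences[[lab]],
                     paste0(x@loci[[1]]@sequences[[lab]],
                            x@loci[[2]]@sequences[[lab]],
                            x@loci[[3]]@sequences[[lab]]))
  # slicing a locus's column range reproduces that locus exactly
  for (k in seq_len(nrow(p))) {
    sl <- substr(y@sequences, p$start[k], p$end[k])
    expect_identical(unname(sl), unname(x@loci[[k]]@sequences))
  }
  # single-locus selection is the locus itself (modulo name/partitions)
  one <- concatenateLoci(x, "loc2")
  expect_identical(one@sequences, x@loci$loc2@sequences)
  expect_identical(nCols(one), nCols(x@loci$loc2))
  expect_error(concatenateLoci(x, integer(0)), "empty")
})

test_that("explicit locus lengths give the forced partition boundaries", {
  a <- locusAlignment(setNames(strrep("A", 100), "s1"), name = "g1")
  b <- locusAlignment(setNames(strrep("C", 150), "s1"), name = "g2")
  y <- concatenateLoci(multiLocusAlignment(list(a, b)))
  expect_identical(nCols(y), 250L)
  expect_identical(getPartitions(y)$start, c(1L, 101L))
  expect_identical(getPartitions(y)$end, c(100L, 250L))
  expect_identical(partitionText(y), c("DNA, g1 = 1-100", "DNA, g2 = 101-250"))
})

test_that("sequence-count and name accessors honour exclude.gap.only", {
  set.seed(3)
  f <- randPresenceLoci(n.ind = 9L, n.loc = 3L)
  x <- multiLocusAlignment(f$loci)
  # default counts match a brute-force all-gap row scan
  counts <- getNumSequences(x)
  for (k in seq_along(x@loci)) {
    gap <- vapply(x@loci[[k]]@sequences, function(z)
      z == strrep("-", nchar(z)), logical(1))
    expect_identical(unname(counts[k]), as.integer(sum(!gap)))
    expect_identical(getSequenceNames(x)[[k]], names(which(!gap)))
  }
  # exclude.gap.only = FALSE returns n.ind everywhere
  expect_identical(unname(getNumSequences(x, exclude.gap.only = FALSE)),
                   rep(x@nInd, 3L))
  expect_error(getNumSequences(x, loci = "nope"), "unknown locus")
})

test_that("getSequences simplifies single-locus results and filters ids", {
  set.seed(4)
  f <- randPresenceLoci(n.ind = 6L, n.loc = 3L)
  x <- multiLocusAlignment(f$loci)
  one <- getSequences(x, loci = "loc2")
  expect_s4_class(one, "LocusAlignment")
  lst <- getSequences(x, loci = "loc2", simplify = FALSE)
  expect_type(lst, "list")
  expect_length(lst, 1L)
  two <- getSequences(x, ids = getLabels(x)[1:2], simplify = FALSE)
  expect_true(all(vapply(two, function(a) length(a@sequences), integer(1)) == 2L))
})

test_that("locus metadata: count, names, renaming", {
  set.seed(5)
  f <- randPresenceLoci(n.ind = 5L, n.loc = 4L)
  gi <- data.frame(len = 1:4, row.names = sprintf("loc%d", 1:4))
  x <- multiLocusAlignment(f$loci, gene.info = gi)
  expect_identical(getNumLoci(x), 4L)
  before <- lapply(x@loci, function(a) a@sequences)
  y <- setLocusNames(x, c("w", "x", "y", "z"))
  expect_identical(getLocusNames(y), c("w", "x", "y", "z"))
  expect_identical(rownames(y@geneInfo), c("w", "x", "y", "z"))
  # rename leaves sequence content identical
  expect_identical(unname(lapply(y@loci, function(a) a@sequences)),
                   unname(before))
  expect_error(setLocusNames(x, c("a", "b")), "expected 4")
  expect_error(setLocusNames(x, c("a", "a", "b", "c")), "unique")
})

test_that("site-pattern compression counts distinct columns and inverts", {
  # all-identical columns -> one pattern of full weight
  a <- locusAlignment(c(s1 = "AAAA", s2 = "CCCC"), name = "mono")
  t1 <- compressSitePatterns(a)
  expect_identical(t1@weights, 4L)

  # forced toy: columns AAB AAB ABB AAB ABB AAA over 3 individuals
  m <- matrix(c("A", "A", "B",  "A", "A", "B",  "A", "B", "B",
                "A", "A", "B",  "A", "B", "B",  "A", "A", "A"),
              nrow = 3)
  rownames(m) <- c("i1", "i2", "i3")
  toy <- locusAlignment(m, name = "toy", alphabet = "amino-acid")
  tt <- compressSitePatterns(toy)
  expect_identical(tt@weights, c(3L, 2L, 1L))

  # random alignments: weights sum to n_cols, pattern count = distinct columns,
  # expansion reproduces the column multiset
  set.seed(21)
  for (rep in 1:10) {
    x <- randLocus(5L, 30L)
    tab <- compressSitePatterns(x)
    expect_identical(sum(tab@weights), nCols(x))
    mm <- as.matrix(x)
    expect_identical(nrow(tab@patterns),
                     length(unique(apply(mm, 2, paste, collapse = ""))))
    back <- expandSitePatterns(tab)
    expect_identical(sort(apply(as.matrix(back), 2, paste, collapse = "")),
                     sort(apply(mm, 2, paste, collapse = "")))
  }
})

test_that("labels sort by plain code-point order, case-sensitive", {
  a <- locusAlignment(c(b = "AC", B = "AC", a10 = "AC", a2 = "AC"), name = "g")
  x <- multiLocusAlignment(list(a))
  expect_identical(getLabels(x), c("B", "a10", "a2", "b"))
})
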