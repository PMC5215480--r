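# direct closed-form evaluations, independent of the implementation
jc69_formula <- function(p) -0.75 * log(1 - 4 * p / 3)
k80_formula <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)

# build a 2-sequence alignment realizing exact (transition, transversion,
# identical) site counts
pairFromCounts <- function(nTs, nTv, nSame) {
  a <- c(rep("A", nTs), rep("A", nTv), rep("C", nSame))
  b <- c(rep("G", nTs), rep("T", nTv), rep("C", nSame))
  locusAlignment(rbind(x = a, y = b), name = "pair", alphabet = "nucleotide")
}

test_that("pairwise deletion restricts comparison to jointly determinate sites", {
  a <- locusAlignment(c(x = "ACGT-A", y = "ACCTNA"))
  expect_identical(unname(as.matrix(pairwiseDistance(a, "p"))[1, 2]), 0.2)
  expect_identical(unname(as.matrix(pairwiseDistance(a, "raw"))[1, 2]), 1)
  # identical rows are at distance zero under every model
  b <- locusAlignment(c(x = "ACGTN-", y = "ACGTN-"))
  for (m in c("raw", "p", "jc69", "k80"))
    expect_identical(unname(as.matrix(pairwiseDistance(b, m))[1, 2]), 0)
})

test_that("JC69 and K80 agree with their closed forms to 1e-12", {
  set.seed(81)
  for (rep in 1:100) {
    nc <- sample(50:400, 1)
    mism <- sample.int(max(1L, floor(nc * 0.7)), 1)  # keep inside the domain
    nTs <- sample.int(mism, 1) - 1L
    nTv <- mism - nTs
    if (1 - 2 * (nTs / nc) - nTv / nc <= 0 || 1 - 2 * (nTv / nc) <= 0) next
    a <- pairFromCounts(nTs, nTv, nc - mism)
    p <- mism / nc
    expect_equal(unname(as.matrix(pairwiseDistance(a, "p"))[1, 2]), p,
                 tolerance = 1e-12)
    expect_equal(unname(as.matrix(pairwiseDistance(a, "jc69"))[1, 2]),
                 jc69_formula(p), tolerance = 1e-12)
    expect_equal(unname(as.matrix(pairwiseDistance(a, "k80"))[1, 2]),
                 k80_formula(nTs / nc, nTv / nc), tolerance = 1e-12)
  }
  # spot value: p = 0.25 under JC69
  a <- pairFromCounts(1L, 0L, 3L)
  expect_equal(unname(as.matrix(pairwiseDistance(a, "jc69"))[1, 2]),
               -0.75 * log(1 - 1 / 3), tolerance = 1e-12)
})

test_that("site counting matches a per-column brute-force scan on gappy data", {
  set.seed(91)
  for (rep in 1:25) {
    x <- randLocus(6L, 40L, gap.prob = 0.15, amb.prob = 0.1)
    m <- as.matrix(x)
    dp <- as.matrix(pairwiseDistance(x, "p"))
    dr <- as.matrix(pairwiseDistance(x, "raw"))
    for (i in 1:5) for (j in (i + 1):6) {
      bf <- bfPairCounts(m[i, ], m[j, ])
      expect_identical(dr[i, j], as.numeric(bf$mismatches))
      if (bf$compared == 0L) expect_true(is.na(dp[i, j]))
      else expect_equal(dp[i, j], bf$mismatches / bf$compared)
    }
  }
})

test_that("distance matrices are symmetric with zero diagonal for all models", {
  set.seed(101)
  x <- randLocus(7L, 60L, gap.prob = 0.05)
  for (m in c("raw", "p", "jc69", "k80")) {
    dm <- as.matrix(pairwiseDistance(x, m))
    expect_identical(dm, t(dm))
    expect_identical(unname(diag(dm)), rep(0, 7))
  }
})

test_that("undefined and saturated pairs are flagged, not zeroed", {
  a <- locusAlignment(c(x = "AC--", y = "--GT", z = "ACGT"))
  d <- pairwiseDistance(a, "p")
  f <- flaggedPairs(d)
  expect_identical(f$status, "undefined")
  expect_setequal(c(f$a, f$b), c("x", "y"))
  expect_true(is.na(as.matrix(d)["x", "y"]))

  # p = 0.75 saturates the JC69 log
  sat <- locusAlignment(rbind(x = c("A", "A", "A", "A"),
                              y = c("C", "G", "T", "C")))
  ds <- pairwiseDistance(sat, "jc69")
  expect_identical(flaggedPairs(ds)$status, "saturated")
})

test_that("K80 equals JC69 when transitions:transversions is 1:2", {
  # equal substitution rates imply one third of mismatches are transitions
  a <- pairFromCounts(10L, 20L, 270L)
  expect_equal(unname(as.matrix(pairwiseDistance(a, "k80"))[1, 2]),
               unname(as.matrix(pairwiseDistance(a, "jc69"))[1, 2]),
               tolerance = 1e-12)
})

test_that("JC69 agrees with p to first order as p -> 0", {
  a <- pairFromCounts(1L, 0L, 999L)  # p = 0.001
  d <- unname(as.matrix(pairwiseDistance(a, "jc69"))[1, 2])
  expect_lt(abs(d - 0.001) / 0.001, 0.01)
})

test_that("distances cross-check against ape::dist.dna on clean data", {
  set.seed(111)
  # low divergence so the model transforms stay inside their domain
  base <- sample(NT, 200L, replace = TRUE)
  m <- t(replicate(6, {
    mut <- runif(200L) < 0.08
    out <- base
    out[mut] <- sample(NT, sum(mut), replace = TRUE)
    out
  }))
  rownames(m) <- sprintf("t%d", 1:6)
  x <- locusAlignment(m, name = "clean", alphabet = "nucleotide")
  bin <- ape::as.DNAbin(as.matrix(x))
  for (pair in list(c("raw", "N"), c("p", "raw"), c("jc69", "JC69"),
                    c("k80", "K80"))) {
    mine <- as.matrix(pairwiseDistance(x, pair[1]))
    theirs <- as.matrix(ape::dist.dna(bin, model = pair[2],
                                      pairwise.deletion = TRUE))
    expect_equal(mine, theirs[rownames(mine), colnames(mine)],
                 tolerance = 1e-10)
  }
})

test_that("multi-locus distances pool via concatenation", {
  set.seed(121)
  # single-locus container: pooled equals per-locus
  f1 <- randPresenceLoci(n.ind = 5L, n.loc = 1L, m = 30L)
  x1 <- multiLocusAlignment(f1$loci)
  expect_equal(as.matrix(distMultiLocus(x1, pool = TRUE)),
               as.matrix(distMultiLocus(x1)[[1]]))

  # duplicated locus: pooled p-distance unchanged
  a <- f1$loci[[1]]
  b <- a; b@name <- "copy"
  x2 <- multiLocusAlignment(list(a, b))
  expect_equal(as.matrix(distMultiLocus(x2, pool = TRUE)),
               as.matrix(pairwiseDistance(a, "p")))

  # complete data: pooled raw counts = sum of per-locus raw counts
  labs <- sprintf("t%d", 1:5)
  loci <- lapply(1:3, function(k)
    locusAlignment(randAlnMatrix(5, 25, gap.prob = 0, amb.prob = 0,
                                 labels = labs),
                   name = paste0("g", k), alphabet = "nucleotide"))
  x3 <- multiLocusAlignment(loci)
  per <- distMultiLocus(x3, model = "raw")
  expect_equal(as.matrix(distMultiLocus(x3, pool = TRUE, model = "raw")),
               Reduce(`+`, lapply(per, as.matrix)))
})
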