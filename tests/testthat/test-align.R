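test_that("global alignment handles identity, normalization and bad input", {
  al <- globalAlign("ACGU", "ACGU")
  expect_equal(alignmentScore(al), 8)           # 4 * match(+2)
  expect_equal(alignedSeqs(al), c("ACGU", "ACGU"))
  # DNA/lowercase input is normalized before alignment
  expect_equal(alignedSeqs(globalAlign("acgt", "ACGU")), c("ACGU", "ACGU"))
  expect_error(globalAlign("ACGU", ""), "non-empty")
  expect_error(globalAlign("ACGU", "ACGB"), "invalid character")
})

test_that("aligned strings degap to their inputs with no gap-gap column", {
  set.seed(31)
  for (i in 1:25) {
    a <- randRNA(sample(3:40, 1))
    b <- randRNA(sample(3:40, 1))
    al <- globalAlign(a, b)
    s <- alignedSeqs(al)
    expect_equal(gsub("-", "", s[1]), a)
    expect_equal(gsub("-", "", s[2]), b)
    ca <- strsplit(s[1], "")[[1]]; cb <- strsplit(s[2], "")[[1]]
    expect_false(any(ca == "-" & cb == "-"))
    # the reported score equals the score of the reported alignment
    expect_equal(scoreAlignment(s[1], s[2]), alignmentScore(al))
  }
})

test_that("alignment score equals the exhaustive-enumeration optimum (short pairs)", {
  set.seed(17)
  for (i in 1:60) {
    a <- randRNA(sample(2:6, 1))
    b <- randRNA(sample(2:6, 1))
    expect_equal(alignmentScore(globalAlign(a, b)), enumAlignScore(a, b),
                 info = paste(a, b))
  }
})

test_that("alignment score is an upper bound for hand-built alignments", {
  a <- "ACGUACGU"; b <- "ACGACGU"
  best <- alignmentScore(globalAlign(a, b))
  expect_gte(best, scoreAlignment("ACGUACGU", "ACG-ACGU"))
  expect_gte(best, scoreAlignment("ACGUACGU", "ACGACGU-"))
  expect_gte(best, scoreAlignment("ACGUACGU", "-ACGACGU"))
})

test_that("p-distance counts mismatches over comparable columns only", {
  expect_equal(pDistance("ACGUACGUACGUACGUACGU", "ACGUACGUACGUACGUACGU"), 0)
  expect_equal(pDistance("ACGU", "ACGA"), 0.25)
  expect_equal(pDistance("AC-GU", "ACAGU"), 0)
  expect_equal(pDistance("ACNU", "ACGU"), 0)       # N column not comparable
  expect_error(pDistance("---", "AC"), "equal length")
  expect_error(pDistance("--N", "A-N"), "comparable")
  # symmetry and range on random gapped rows
  set.seed(7)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "U", "-"), 30, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), 30, TRUE), collapse = "")
    d <- pDistance(a, b)
    expect_equal(d, pDistance(b, a))
    expect_true(d >= 0 && d <= 1)
  }
})

test_that("UPGMA guide tree recovers ultrametric topology and ladders ties", {
  # ((1,2),(3,4)) with within-pair distance 2, across-pair 6
  d <- matrix(6, 4, 4); d[1, 2] <- d[2, 1] <- 2; d[3, 4] <- d[4, 3] <- 2
  diag(d) <- 0
  g <- buildGuideTree(d)
  leavesOf <- function(node) {
    if (!is.null(node$leaf)) return(node$leaf)
    c(leavesOf(node$left), leavesOf(node$right))
  }
  expect_setequal(leavesOf(g$left), c(1, 2))
  expect_setequal(leavesOf(g$right), c(3, 4))

  # all-equal distances: left-to-right ladder by taxon index
  d2 <- matrix(1, 4, 4); diag(d2) <- 0
  g2 <- buildGuideTree(d2)
  expect_equal(leavesOf(g2$right), 4)
  expect_equal(leavesOf(g2$left$right), 3)
  expect_setequal(leavesOf(g2$left$left), c(1, 2))

  # 2 taxa: single cherry
  g3 <- buildGuideTree(matrix(c(0, 1, 1, 0), 2))
  expect_setequal(leavesOf(g3), c(1, 2))
  expect_error(buildGuideTree(matrix(0, 1, 1)), "2 taxa")
})

test_that("progressive MSA degenerates correctly and keeps rows recoverable", {
  s <- stats::setNames(rep("ACGUACGUACGUACGUACGU", 4), paste0("x", 1:4))
  m <- progressiveMsa(s)
  expect_true(all(!grepl("-", msaRows(m))))
  D <- msaDistanceMatrix(m)
  expect_true(all(D == 0))

  # two sequences: identical to the pairwise global alignment
  a <- "ACGUACGGACGU"; b <- "ACGUACGU"
  m2 <- progressiveMsa(c(p = a, q = b))
  al <- globalAlign(a, b)
  expect_equal(unname(msaRows(m2)), alignedSeqs(al))

  # random families: every row degaps to its input, in input order
  set.seed(12)
  seqs <- stats::setNames(replicate(5, randRNA(sample(25:35, 1))),
                          paste0("s", 1:5))
  m3 <- progressiveMsa(seqs)
  expect_equal(names(msaRows(m3)), names(seqs))
  expect_equal(gsub("-", "", msaRows(m3)), seqs)
})

test_that("no-indel families align gap-free with ancestor-homologous columns", {
  set.seed(21)
  anc <- randRNA(80)
  seqs <- stats::setNames(
    c(vapply(c(0.02, 0.03, 0.05, 0.04), function(p) evolveSeq(anc, p),
             character(1))),
    c("hsa-mir-9", "bta-mir-9", "gga-mir-9", "ssc-mir-9"))
  m <- progressiveMsa(seqs)
  expect_equal(unname(nchar(msaRows(m)[1])), 80L)  # gap-free => ancestor width
  expect_true(all(!grepl("-", msaRows(m))))
  D <- msaDistanceMatrix(m)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
})

test_that("MSA distance matrix matches direct pairwise p-distances", {
  m <- methods::new("MirnaMsa",
                    rows = c(a = "ACGU-ACGU", b = "ACGUAACGU", c = "ACGUAACGA"))
  D <- msaDistanceMatrix(m)
  expect_equal(D["a", "b"], pDistance("ACGU-ACGU", "ACGUAACGU"))
  expect_equal(D["b", "c"], pDistance("ACGUAACGU", "ACGUAACGA"))
  expect_error(msaDistanceMatrix(methods::new("MirnaMsa", rows = c(x = "ACGU"))),
               "2 rows")
})
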