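test_that("miRBase-dialect FASTA headers and sequences are parsed and normalized", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(
    ">hsa-miR-1-3p MIMAT0000416",
    "UGGAAUGUAAAGAAGUAUGUAU",
    ">cfa-miR-143",
    "tgagatgaagcactg",
    ">bta-miR-9 MIMAT0003834 Bos taurus miR-9 extra tokens ignored",
    "UCUUUGGUUAUCUAGCUGUAUGA"
  ), fa)
  x <- suppressWarnings(readMirnaFasta(fa, "mature"))
  expect_equal(length(x), 3L)
  expect_equal(mirnaID(x), c("hsa-miR-1-3p", "cfa-miR-143", "bta-miR-9"))
  expect_equal(accession(x), c("MIMAT0000416", "", "MIMAT0003834"))
  expect_equal(speciesCode(x), c("hsa", "cfa", "bta"))
  expect_equal(mirnaArm(x), c("3p", "unspecified", "unspecified"))
  expect_equal(unname(sequences(x))[2], "UGAGAUGAAGCACUG")
})

test_that("invalid FASTA records are rejected record-wise, bad headers fatally", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(
    ">hsa-miR-21-5p", "UAGCUUAUCAGACUGAUGUUGA",
    ">ssc-miR-x", "UGAXGUA",          # non-IUPAC character
    ">eca-miR-y", "",                  # empty sequence
    ">gga-miR-n", "UGANNGUAAGUAAGUAU"  # N retained but flagged
  ), fa)
  expect_warning(expect_warning(x <- readMirnaFasta(fa, "mature")))
  expect_equal(mirnaID(x), c("hsa-miR-21-5p", "gga-miR-n"))
  expect_equal(mirnaInfo(x)$has_n, c(FALSE, TRUE))

  bad <- tempfile(fileext = ".fa")
  writeLines(c(">", "ACGU"), bad)
  expect_error(readMirnaFasta(bad, "mature"), "header")
})

test_that("unknown species codes are flagged, never dropped", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">mmu-miR-1-3p", "UGGAAUGUAAAGAAGUAUGUAU"), fa)
  x <- readMirnaFasta(fa, "mature")
  expect_equal(length(x), 1L)
  expect_false(mirnaInfo(x)$known_species)
})

test_that("FASTA write/read round-trips a 100-record synthetic set byte-identically", {
  set.seed(11)
  cfg <- simConfig(seed = 11, nFamilies = 10)
  b <- simulateDataset(cfg)
  allmat <- mirnaSet(c(mirnaID(b$matureHuman), mirnaID(b$matureAnimal)),
                     c(unname(sequences(b$matureHuman)),
                       unname(sequences(b$matureAnimal))),
                     c(accession(b$matureHuman), accession(b$matureAnimal)))
  expect_equal(length(allmat), 60L)
  f1 <- tempfile(); f2 <- tempfile()
  writeMirnaFasta(allmat, f1)
  back <- readMirnaFasta(f1, "mature")
  writeMirnaFasta(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(mirnaID(back), mirnaID(allmat))
  expect_equal(sequences(back), sequences(allmat))
})

test_that("writeMirnaFasta handles empty and single-record sets", {
  empty <- mirnaSet(character(0), character(0))
  expect_equal(writeMirnaFasta(empty), "")
  one <- mirnaSet("hsa-miR-1-3p", "UGGAAUGUAAAGAAGUAUGUAU", "MIMAT0000416")
  expect_equal(length(strsplit(writeMirnaFasta(one), "\n")[[1]]), 2L)
})

test_that("disease tables split pipe cells and reject bad rows", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "mirna_id\tdisease\tpmid",
    "hsa-miR-21-5p\tglioblastoma\t16461460",
    "hsa-miR-1-3p\tdiseaseA|diseaseB\t123",
    "hsa-miR-2-3p\theart failure\tabc",
    "mmu-miR-3-3p\tsome disease\t99"
  ), tsv)
  expect_warning(expect_warning(d <- readDiseaseTable(tsv)))
  expect_equal(nrow(d), 3L)
  expect_equal(d$disease[d$mirna_id == "hsa-miR-1-3p"],
               c("diseaseA", "diseaseB"))
  expect_equal(d$pmid[d$mirna_id == "hsa-miR-1-3p"], c(123L, 123L))
  expect_true(all(startsWith(d$mirna_id, "hsa-")))
})

test_that("a missing mandatory disease column is a hard error naming it", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("mirna_id\tdisease", "hsa-miR-21-5p\tglioblastoma"), tsv)
  expect_error(readDiseaseTable(tsv), "pmid")
})

test_that("newick serialization covers single leaves, trees and duplicate labels", {
  expect_equal(writeNewick("hsa-mir-1"), "hsa-mir-1:0.000000;")

  d <- matrix(c(0, .2, .4, .2, 0, .4, .4, .4, 0), 3,
              dimnames = list(c("hsa-mir-5", "bta-mir-5", "gga-mir-5"),
                              c("hsa-mir-5", "bta-mir-5", "gga-mir-5")))
  tr <- njTree(d)
  txt <- writeNewick(tr)
  expect_match(txt, ";$")
  back <- ape::read.tree(text = txt)
  expect_setequal(back$tip.label, rownames(d))
  # every branch length carries exactly six decimals
  lens <- regmatches(txt, gregexpr(":[0-9.]+", txt))[[1]]
  expect_true(all(grepl("^:[0-9]+\\.[0-9]{6}$", lens)))

  dup <- tr; dup$tip.label <- c("a", "a", "b")
  expect_error(writeNewick(dup), "duplicate")
})

test_that("presence matrices round-trip through the +/- dialect", {
  m <- matrix(c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE), nrow = 2,
              dimnames = list(c("hsa-miR-1-3p", "hsa-miR-2-5p"),
                              c("bta", "gga", "ssc")))
  pm <- presenceMatrix(m)
  f <- tempfile()
  writePresenceMatrix(pm, f)
  back <- readPresenceMatrix(f)
  expect_equal(presenceCells(back), presenceCells(pm))
  expect_equal(attr(back, "printed_total"), as.integer(rowSums(m)))
  expect_identical(writePresenceMatrix(back), writePresenceMatrix(pm))
})

test_that("family maps read with or without a header row", {
  tsv <- tempfile()
  writeLines(c("family_id\tpre_id", "mir-154\thsa-mir-494", "mir-154\teca-mir-494"), tsv)
  fam <- readFamilyMap(tsv)
  expect_equal(nrow(fam), 2L)
  expect_equal(fam$family_id, c("mir-154", "mir-154"))
  tsv2 <- tempfile()
  writeLines(c("mir-1\thsa-mir-1"), tsv2)
  expect_equal(readFamilyMap(tsv2)$pre_id, "hsa-mir-1")
})
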