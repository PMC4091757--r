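test_that("sequence normalization is idempotent and strict", {
  expect_equal(normalizeSequence("ugagGUa"), "UGAGGUA")
  expect_equal(normalizeSequence("TGAGGTA"), "UGAGGUA")
  expect_error(normalizeSequence("UGAX"), "invalid character")
  expect_error(normalizeSequence(""), "empty")
  set.seed(5)
  for (i in 1:20) {
    s <- paste(sample(c("a", "c", "g", "t", "U", "N"), 25, TRUE), collapse = "")
    expect_identical(normalizeSequence(normalizeSequence(s)),
                     normalizeSequence(s))
  }
})

test_that("exact matching requires full-length identity and excludes N", {
  human <- mirnaSet(c("hsa-miR-1-3p", "hsa-miR-2-5p"),
                    c("UGAGGUAGUAGGUUGUAUAGUU", "UGGAAUGUAAAGAAGUAUGUAU"))
  animals <- suppressWarnings(mirnaSet(
    c("bta-miR-1-3p", "gga-miR-1-3p", "ssc-miR-1-3p", "eca-miR-2-5p",
      "cfa-miR-2-5p"),
    c("UGAGGUAGUAGGUUGUAUAGUU",   # exact
      "UGAGGUAGUAGGUUGUAUAGUC",   # single terminal mismatch
      "UGAGGUAGUAGGUUGUAUAGUUA",  # human 22-mer contained in 23-mer: no match
      "TGGAATGTAAAGAAGTATGTAT",   # DNA form of human seq: matches
      "UGGAAUGUAAAGAAGUNUGUAU"))) # N can never certify identity
  map <- findExactHomologs(human, animals)
  mm <- hdmacMatches(map)
  expect_equal(nrow(mm), 2L)
  expect_setequal(paste(mm$human_id, mm$animal_id),
                  c("hsa-miR-1-3p bta-miR-1-3p", "hsa-miR-2-5p eca-miR-2-5p"))
  expect_equal(sort(hdmacHuman(map)$mirna_id),
               c("hsa-miR-1-3p", "hsa-miR-2-5p"))
})

test_that("hash-based matching equals the brute-force all-pairs oracle", {
  set.seed(42)
  for (rep in 1:3) {
    pool <- replicate(30, randRNA(sample(20:23, 1)))
    hseqs <- sample(pool, 60, replace = TRUE)
    aseqs <- sample(pool, 140, replace = TRUE)
    human <- mirnaSet(paste0("hsa-miR-", seq_along(hseqs), "-3p"), hseqs)
    sp <- sample(c("bta", "gga", "ssc", "eca", "cfa"), length(aseqs), TRUE)
    animals <- mirnaSet(paste0(sp, "-miR-", seq_along(aseqs), "-3p"), aseqs)
    mm <- hdmacMatches(findExactHomologs(human, animals))
    expect_identical(sort(paste(mm$human_id, mm$animal_id)),
                     bruteForceMatches(human, animals))
  }
})

test_that("matching is an equivalence on normalized sequences", {
  set.seed(9)
  seqs <- replicate(40, randRNA(22))
  human <- mirnaSet(paste0("hsa-miR-", 1:40, "-3p"), seqs)
  animals <- mirnaSet(paste0(rep(c("bta", "cfa"), 20), "-miR-", 1:40, "-3p"),
                      sample(seqs))
  mm <- hdmacMatches(findExactHomologs(human, animals))
  # any two animals matching the same human match each other
  for (h in unique(mm$human_id)) {
    s <- unique(mm$sequence[mm$human_id == h])
    expect_length(s, 1L)
  }
})

test_that("presence matrix cells, counts and totals are consistent with the map", {
  human <- mirnaSet(c("hsa-miR-1-3p", "hsa-miR-2-5p"),
                    c("UGAGGUAGUAGGUUGUAUAGUU", "UGGAAUGUAAAGAAGUAUGUAU"))
  animals <- mirnaSet(
    c("bta-miR-1-3p", "bta-miR-1b-3p", "gga-miR-1-3p", "ssc-miR-2-5p"),
    c("UGAGGUAGUAGGUUGUAUAGUU", "UGAGGUAGUAGGUUGUAUAGUU",
      "UGAGGUAGUAGGUUGUAUAGUU", "UGGAAUGUAAAGAAGUAUGUAU"))
  map <- findExactHomologs(human, animals)
  pm <- buildPresenceMatrix(map)
  expect_equal(dim(presenceCells(pm)), c(2L, 5L))
  expect_equal(unname(speciesCount(pm)[c("hsa-miR-1-3p", "hsa-miR-2-5p")]),
               c(2L, 1L))
  # sum of species counts = number of matched (human, species) pairs
  mm <- hdmacMatches(map)
  expect_equal(sum(speciesCount(pm)),
               nrow(unique(mm[, c("human_id", "species_code")])))
  # empty map -> empty matrix
  emptyMap <- findExactHomologs(mirnaSet(character(0), character(0)),
                                mirnaSet(character(0), character(0)))
  expect_equal(length(buildPresenceMatrix(emptyMap)), 0L)
})

test_that("conservation filters implement their definitions and are disjoint", {
  m <- matrix(c(TRUE, TRUE, TRUE, TRUE, TRUE,    # all five
                TRUE, FALSE, TRUE, TRUE, TRUE,   # mammals only
                TRUE, TRUE, FALSE, TRUE, TRUE,   # missing a mammal
                FALSE, FALSE, TRUE, TRUE, TRUE), # neither
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("hsa-miR-", 1:4, "-3p"),
                              c("bta", "gga", "ssc", "eca", "cfa")))
  pm <- presenceMatrix(m)
  expect_equal(filterConserved(pm, "all_species"), "hsa-miR-1-3p")
  expect_equal(filterConserved(pm, "mammals_only"), "hsa-miR-2-3p")
  expect_length(intersect(filterConserved(pm, "all_species"),
                          filterConserved(pm, "mammals_only")), 0L)
  expect_error(filterConserved(pm, "everything"), "unknown mode")
  noGga <- presenceMatrix(m[, c("bta", "ssc"), drop = FALSE])
  expect_error(filterConserved(noGga, "mammals_only"), "gga")
})

test_that("coverage statistics count distinct IDs and use the given totals", {
  human <- mirnaSet("hsa-miR-1-3p", "UGAGGUAGUAGGUUGUAUAGUU")
  animals <- mirnaSet(c("bta-miR-1-3p", "bta-miR-1b-3p", "gga-miR-9-5p"),
                      c("UGAGGUAGUAGGUUGUAUAGUU", "UGAGGUAGUAGGUUGUAUAGUU",
                        "UCUUUGGUUAUCUAGCUGUAUG"))
  map <- findExactHomologs(human, animals)
  cov <- coverageStats(map, c(bta = 10, gga = 20, eca = 4))
  expect_equal(cov$matched[cov$species_code == "bta"], 2L)
  expect_equal(cov$percent[cov$species_code == "bta"], 20)
  expect_equal(cov$percent[cov$species_code == "gga"], 0)
  expect_equal(cov$percent[cov$species_code == "eca"], 0)
  expect_error(coverageStats(map, c(gga = 20)), "bta")
})

test_that("planted per-species match rates are recovered by coverage stats", {
  cfg <- simConfig(seed = 23, nFamilies = 40)
  b <- simulateDataset(cfg)
  map <- findExactHomologs(b$matureHuman, b$matureAnimal)
  totals <- stats::setNames(as.numeric(b$truth$matureTotals),
                            names(b$truth$matureTotals))
  cov <- coverageStats(map, totals)
  planted <- table(factor(b$truth$exactMatches$species_code,
                          levels = cov$species_code))
  expect_equal(cov$matched, unname(as.integer(planted)))
  expect_equal(cov$percent, unname(100 * as.integer(planted) / totals[cov$species_code]))
})

test_that("length distributions report per-species modes", {
  x <- mirnaSet(paste0(c("bta", "bta", "bta", "gga"), "-miR-", 1:4, "-3p"),
                c(randRNA(22), randRNA(22), randRNA(21), randRNA(24)))
  ld <- lengthDistribution(x)
  expect_equal(unname(ld$modal["bta"]), 22L)
  expect_equal(unname(ld$modal["gga"]), 24L)
  expect_equal(sum(ld$counts), 4L)
  emp <- lengthDistribution(mirnaSet(character(0), character(0)))
  expect_equal(length(emp$modal), 0L)
})
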