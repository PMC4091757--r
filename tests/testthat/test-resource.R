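makeMapFixture <- function() {
  human <- mirnaSet("hsa-miR-1-3p", "UGAGGUAGUAGGUUGUAUAGUU", "MIMAT0001")
  animals <- mirnaSet(c("bta-miR-1-3p", "cfa-miR-1-3p"),
                      rep("UGAGGUAGUAGGUUGUAUAGUU", 2),
                      c("MIMAT0002", "MIMAT0003"))
  findExactHomologs(human, animals)
}

diseaseFixture <- function() {
  data.frame(mirna_id = rep("hsa-miR-1-3p", 3),
             disease = c("glioblastoma", "heart failure", "asthma"),
             pmid = c(111L, 222L, 333L),
             experiment = "qRT-PCR", tissue = "serum",
             stringsAsFactors = FALSE)
}

test_that("resource records are the (animal, human, disease) cross product", {
  recs <- buildResource(makeMapFixture(), diseaseFixture())
  expect_equal(nrow(recs), 6L)   # 2 animals x 3 diseases
  expect_equal(colnames(recs), c(resourceFields(), "human_homolog"))
  expect_equal(sort(unique(recs$mature_mirna_id)),
               c("bta-miR-1-3p", "cfa-miR-1-3p"))
  # deterministic sort by (species, mirna_id, pmid)
  expect_equal(recs$pubmed_id, rep(c(111L, 222L, 333L), 2))
  expect_equal(recs$mature_mirna_id,
               rep(c("bta-miR-1-3p", "cfa-miR-1-3p"), each = 3))
})

test_that("empty disease tables and unmatched miRNAs are handled gracefully", {
  expect_warning(r0 <- buildResource(makeMapFixture(), diseaseFixture()[0, ]),
                 "empty disease table")
  expect_equal(nrow(r0), 0L)
  d <- diseaseFixture()
  d$mirna_id[1] <- "hsa-miR-999-5p"   # no animal counterpart
  expect_message(r <- buildResource(makeMapFixture(), d), "excluded")
  expect_equal(nrow(r), 4L)
})

test_that("record validation names the offending fields", {
  recs <- buildResource(makeMapFixture(), diseaseFixture())
  expect_length(validateRecord(recs[1, ]), 0L)

  bad <- recs[1, ]; bad$pubmed_id <- 0L
  v <- validateRecord(bad)
  expect_length(v, 1L)
  expect_match(v, "field 12")

  bad2 <- recs[1, ]; bad2$genomic_coordinates <- "500-100"
  expect_match(validateRecord(bad2), "field 10")

  bad3 <- recs[1, ]; bad3$mature_mirna_id <- "hsa-miR-1-3p"
  expect_match(validateRecord(bad3), "field 1")

  bad4 <- recs[1, ]; bad4$strand <- "?"
  expect_match(validateRecord(bad4), "field 11")
})

test_that("the writer emits 28 columns, refuses invalid records, and round-trips", {
  recs <- buildResource(makeMapFixture(), diseaseFixture())
  txt <- writeResourceTable(recs)
  header <- strsplit(strsplit(txt, "\n")[[1]][1], "\t")[[1]]
  expect_length(header, 28L)
  expect_equal(header, resourceFields())

  f <- tempfile()
  writeResourceTable(recs, f)
  back <- readResourceTable(f)
  expect_equal(nrow(back), 6L)
  f2 <- tempfile()
  back$human_homolog <- NA   # writer must not need the auxiliary column
  expect_error(writeResourceTable(back, f2), NA)
  expect_identical(readLines(f), readLines(f2))

  bad <- recs; bad$pubmed_id[2] <- -5L
  expect_error(writeResourceTable(bad), "invalid resource record")

  # empty table: header only
  expect_warning(r0 <- buildResource(makeMapFixture(), diseaseFixture()[0, ]))
  expect_equal(writeResourceTable(r0), paste(resourceFields(), collapse = "\t"))
})

test_that("building the resource is deterministic and idempotent", {
  r1 <- buildResource(makeMapFixture(), diseaseFixture())
  r2 <- buildResource(makeMapFixture(), diseaseFixture())
  expect_identical(writeResourceTable(r1), writeResourceTable(r2))
})

test_that("summaries report distinct counts over the key fields", {
  recs <- buildResource(makeMapFixture(), diseaseFixture())
  s <- summarizeResource(recs)
  expect_equal(s$n_records, 6L)
  expect_equal(s$n_animal_mirnas, 2L)
  expect_equal(s$n_human_mirnas, 1L)
  expect_equal(s$n_diseases, 3L)
  expect_equal(s$n_pmids, 3L)
  expect_equal(unname(s$per_species[c("bta", "cfa")]), c(3L, 3L))

  s0 <- summarizeResource(NULL)
  expect_equal(s0$n_records, 0L)

  # distinct human miRNAs never exceed presence-matrix rows
  pm <- buildPresenceMatrix(makeMapFixture())
  expect_lte(s$n_human_mirnas, length(pm))
})

test_that("location, precursor, family and ortholog fields are filled when supplied", {
  map <- makeMapFixture()
  pre <- mirnaSet(c("bta-mir-1", "cfa-mir-1"),
                  c(paste0(randRNA(30), "UGAGGUAGUAGGUUGUAUAGUU", randRNA(10)),
                    paste0(randRNA(28), "UGAGGUAGUAGGUUGUAUAGUU", randRNA(12))),
                  c("MI0001", "MI0002"), kind = "precursor")
  fam <- data.frame(family_id = "mir-1", pre_id = c("bta-mir-1", "cfa-mir-1"))
  loc <- data.frame(mirna_id = "bta-miR-1-3p", chromosome = "12",
                    start = 100L, end = 121L, strand = "+")
  orth <- data.frame(human_gene = "AKT1", animal_gene = "AKT1_BTA",
                     species_code = "bta", identity_h2a = 98,
                     identity_a2h = 97.5, confidence = 1L,
                     one_to_one = TRUE, mirna_id = "hsa-miR-1-3p")
  recs <- buildResource(map, diseaseFixture(), locations = loc,
                        orthologs = orth, precursors = pre, families = fam)
  bta <- recs[recs$mature_mirna_id == "bta-miR-1-3p", ][1, ]
  expect_equal(bta$pre_mirna_id, "bta-mir-1")
  expect_equal(bta$pre_mirna_ac, "MI0001")
  expect_equal(bta$family_id, "mir-1")
  expect_equal(bta$genomic_coordinates, "100-121")
  expect_equal(bta$strand, "+")
  expect_equal(bta$target_gene, "AKT1")
  expect_equal(bta$reciprocal_identity, "97.5")
  expect_equal(bta$orthology_confidence, "1")
  cfa <- recs[recs$mature_mirna_id == "cfa-miR-1-3p", ][1, ]
  expect_equal(cfa$genomic_coordinates, "")   # no location supplied
  expect_equal(cfa$target_gene, "")           # ortholog was bta-specific
  expect_length(validateRecord(bta), 0L)
})
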