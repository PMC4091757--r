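# Deterministic generator of cross-species miRNA families with known
# ground truth: an ancestral hairpin is evolved along the fixed species
# tree ((((hsa,ssc),(eca,cfa)),bta),gga) under a uniform point-substitution
# model (each hit site moves to one of the 3 other bases uniformly; no
# indels), the animal mature arm is optionally overwritten with the human
# mature sequence to plant exact matches, and disease/location/protein
# tables are drawn with controlled cardinalities and identity levels.

# edges from each leaf up to the root of ((((hsa,ssc),(eca,cfa)),bta),gga)
.TREE_PATHS <- list(
  hsa = c("hsa", "intC", "intB", "intA"),
  ssc = c("ssc", "intC", "intB", "intA"),
  eca = c("eca", "intD", "intB", "intA"),
  cfa = c("cfa", "intD", "intB", "intA"),
  bta = c("bta", "intA"),
  gga = c("gga")
)

.DISEASE_POOL <- c(
  "glioblastoma", "type 2 diabetes", "hepatocellular carcinoma",
  "breast neoplasms", "cardiac hypertrophy", "colorectal carcinoma",
  "acute myeloid leukemia", "pulmonary hypertension", "osteosarcoma",
  "chronic hepatitis B", "gastric neoplasms", "ovarian neoplasms",
  "melanoma", "Alzheimer disease", "myocardial infarction",
  "rheumatoid arthritis", "prostate neoplasms", "asthma",
  "pancreatic neoplasms", "dilated cardiomyopathy", "sepsis",
  "psoriasis", "endometriosis", "ischemic stroke",
  "non-small cell lung carcinoma", "multiple sclerosis",
  "chronic lymphocytic leukemia", "ulcerative colitis",
  "kidney fibrosis", "heart failure", "atherosclerosis", "obesity",
  "epilepsy", "glaucoma", "osteoarthritis", "preeclampsia",
  "thyroid carcinoma", "bladder neoplasms", "cervical carcinoma",
  "medulloblastoma"
)

.TISSUE_POOL <- c("serum", "plasma", "liver", "heart", "brain",
                  "skeletal muscle", "kidney", "lung")
.EXPERIMENT_POOL <- c("qRT-PCR", "microarray", "Northern blot",
                      "small RNA sequencing")
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: miRNA families
#' evolved along the fixed species tree `((((hsa,ssc),(eca,cfa)),bta),gga)`
#' with per-branch substitution probabilities, per-species probabilities
#' that the animal mature arm is copied unmutated from human (planting an
#' exact match), a disease-association table, and target-protein pairs at
#' fixed identity levels.
#'
#' @param seed integer RNG seed; fixed seed implies full reproducibility
#'   of every downstream number.
#' @param nFamilies number of miRNA families.
#' @param preLength hairpin length (nt).
#' @param matureLength mature length (nt), `< preLength`.
#' @param arm `"5p"` or `"3p"`: which end of the hairpin carries the
#'   mature sequence.
#' @param branchProbs named per-branch substitution probabilities; names
#'   `internal` (all four internal edges) plus the six terminal edges
#'   `hsa`, `ssc`, `eca`, `cfa`, `bta`, `gga`.
#' @param fractionExactMature named per-species probability that the
#'   animal mature window is overwritten with the human mature sequence.
#' @param associationsPerMirna integer range (min, max) of disease
#'   associations drawn per human miRNA.
#' @param pipeCellProb probability an association row carries a second
#'   disease in the same cell (serialized pipe-separated).
#' @param proteinLength target-protein length (aa).
#' @param identityLevels planted reciprocal-identity percentages for the
#'   target-ortholog pairs.
#' @return a validated `SimConfig` list.
#' @export
simConfig <- function(seed = 1L,
                      nFamilies = 30L,
                      preLength = 90L,
                      matureLength = 22L,
                      arm = "3p",
                      branchProbs = c(internal = 0.005, hsa = 0.005,
                                      ssc = 0.010, eca = 0.008, cfa = 0.010,
                                      bta = 0.015, gga = 0.100),
                      fractionExactMature = c(bta = 0.45, gga = 0.05,
                                              ssc = 0.50, eca = 0.62,
                                              cfa = 0.50),
                      associationsPerMirna = c(1L, 3L),
                      pipeCellProb = 0.15,
                      proteinLength = 300L,
                      identityLevels = c(100, 98, 71, 70, 60)) {
  stopifnot(matureLength < preLength, preLength > 0,
            arm %in% c("5p", "3p"),
            all(branchProbs >= 0 & branchProbs <= 1),
            all(fractionExactMature >= 0 & fractionExactMature <= 1),
            all(c("internal", names(.TREE_PATHS)) %in% names(branchProbs)),
            all(names(fractionExactMature) %in%
                  c("bta", "gga", "ssc", "eca", "cfa")),
            pipeCellProb >= 0 && pipeCellProb <= 1,
            proteinLength > 0,
            all(identityLevels >= 0 & identityLevels <= 100))
  structure(list(seed = as.integer(seed), nFamilies = as.integer(nFamilies),
                 preLength = as.integer(preLength),
                 matureLength = as.integer(matureLength), arm = arm,
                 branchProbs = branchProbs,
                 fractionExactMature = fractionExactMature,
                 associationsPerMirna = as.integer(associationsPerMirna),
                 pipeCellProb = pipeCellProb,
                 proteinLength = as.integer(proteinLength),
                 identityLevels = identityLevels),
            class = "SimConfig")
}

.edgeProb <- function(config, edge) {
  bp <- config$branchProbs
  if (edge %in% names(bp)) unname(bp[edge]) else unname(bp["internal"])
}

#' Evolve a sequence by uniform point substitution
#'
#' Each site is independently substituted with probability `pSub` to one
#' of the three other bases, uniformly. Length is preserved; there are no
#' indels.
#'
#' @param seq RNA string over \{A,C,G,U\}.
#' @param pSub substitution probability in \[0, 1\].
#' @return the evolved RNA string.
#' @export
evolveSeq <- function(seq, pSub) {
  stopifnot(pSub >= 0, pSub <= 1)
  ch <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(ch)) < pSub
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "U"), b), 1), character(1))
  }
  paste(ch, collapse = "")
}

#' Compose substitution probabilities along consecutive branches
#'
#' Under the uniform 3-way substitution model, the probability that a site
#' differs across two consecutive edges with per-edge probabilities p and
#' q is `p + q - (4/3) p q`.
#'
#' @param p,q per-edge substitution probabilities.
#' @return the composed probability.
#' @export
composeBranchProb <- function(p, q) p + q - (4 / 3) * p * q

#' Expected p-distance between two leaves
#'
#' Two leaves whose paths from the common ancestor carry substitution
#' probabilities `p1` and `p2` differ at a site with probability
#' `p1 (1 - p2) + p2 (1 - p1) + (2/3) p1 p2`: both-mutated sites collide
#' on the same base with probability 1/3. For multi-edge paths, compose
#' the per-edge probabilities with [composeBranchProb()] first.
#'
#' @param p1,p2 path substitution probabilities in \[0, 1\].
#' @return expected divergence proportion.
#' @examples
#' expectedPairwiseDivergence(0.02, 0.02)  # 0.0394666...
#' @export
expectedPairwiseDivergence <- function(p1, p2) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  p1 * (1 - p2) + p2 * (1 - p1) + (2 / 3) * p1 * p2
}

#' Expected divergence between two species under a configuration
#'
#' Composes the per-edge probabilities along each species' path to the
#' most recent common ancestor and applies
#' [expectedPairwiseDivergence()].
#'
#' @param config a [simConfig()].
#' @param sp1,sp2 species codes (including `hsa`).
#' @return expected p-distance between the two leaves.
#' @export
expectedLeafDivergence <- function(config, sp1, sp2) {
  e1 <- .TREE_PATHS[[sp1]]
  e2 <- .TREE_PATHS[[sp2]]
  own1 <- setdiff(e1, e2)
  own2 <- setdiff(e2, e1)
  p1 <- Reduce(composeBranchProb, vapply(own1, .edgeProb,
                                         numeric(1), config = config), 0)
  p2 <- Reduce(composeBranchProb, vapply(own2, .edgeProb,
                                         numeric(1), config = config), 0)
  expectedPairwiseDivergence(p1, p2)
}

.matureWindow <- function(config) {
  if (config$arm == "3p")
    (config$preLength - config$matureLength + 1):config$preLength
  else seq_len(config$matureLength)
}

#' Simulate one miRNA family across the species panel
#'
#' Draws a uniform ancestral hairpin, evolves it along the species tree,
#' and, per animal species with probability `fractionExactMature`,
#' overwrites the animal mature window with the human mature sequence
#' (planting an exact-match ground truth). IDs follow miRBase naming
#' (`<sp>-mir-N` hairpins, `<sp>-miR-N-<arm>` matures).
#'
#' @param config a [simConfig()]. Uses the current RNG stream; seed it
#'   (or call via [simulateDataset()]) for reproducibility.
#' @param familyIndex integer family number.
#' @return list with data.frames `precursors`, `matures` and the ground
#'   truth slice `truth` (one row per animal: `human_id`, `animal_id`,
#'   `species_code`, `copied`, `exact`).
#' @export
simulateFamily <- function(config, familyIndex) {
  L <- config$preLength
  win <- .matureWindow(config)
  anc <- paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
               collapse = "")
  nodeA <- evolveSeq(anc, .edgeProb(config, "intA"))
  gga <- evolveSeq(anc, .edgeProb(config, "gga"))
  bta <- evolveSeq(nodeA, .edgeProb(config, "bta"))
  nodeB <- evolveSeq(nodeA, .edgeProb(config, "intB"))
  nodeC <- evolveSeq(nodeB, .edgeProb(config, "intC"))
  nodeD <- evolveSeq(nodeB, .edgeProb(config, "intD"))
  hsa <- evolveSeq(nodeC, .edgeProb(config, "hsa"))
  ssc <- evolveSeq(nodeC, .edgeProb(config, "ssc"))
  eca <- evolveSeq(nodeD, .edgeProb(config, "eca"))
  cfa <- evolveSeq(nodeD, .edgeProb(config, "cfa"))
  pre <- c(hsa = hsa, bta = bta, gga = gga, ssc = ssc, eca = eca, cfa = cfa)

  humanMature <- substr(pre[["hsa"]], min(win), max(win))
  animals <- c("bta", "gga", "ssc", "eca", "cfa")
  copied <- stats::setNames(logical(length(animals)), animals)
  matures <- stats::setNames(character(length(animals)), animals)
  for (sp in animals) {
    copied[sp] <- stats::runif(1) < config$fractionExactMature[[sp]]
    if (copied[sp]) {
      s <- strsplit(pre[[sp]], "")[[1]]
      s[win] <- strsplit(humanMature, "")[[1]]
      pre[[sp]] <- paste(s, collapse = "")
    }
    matures[sp] <- substr(pre[[sp]], min(win), max(win))
  }

  k <- familyIndex
  sps <- c("hsa", animals)
  accBase <- (k - 1L) * length(sps)
  preDF <- data.frame(
    pre_id = paste0(sps, "-mir-", k),
    accession = sprintf("MI%07d", accBase + seq_along(sps)),
    species_code = sps,
    sequence = unname(pre[sps]),
    family_id = paste0("mir-", k),
    stringsAsFactors = FALSE
  )
  matDF <- data.frame(
    mirna_id = paste0(sps, "-miR-", k, "-", config$arm),
    accession = sprintf("MIMAT%07d", accBase + seq_along(sps)),
    species_code = sps,
    sequence = c(humanMature, unname(matures[animals])),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    human_id = paste0("hsa-miR-", k, "-", config$arm),
    animal_id = paste0(animals, "-miR-", k, "-", config$arm),
    species_code = animals,
    copied = unname(copied),
    exact = unname(matures[animals] == humanMature),
    stringsAsFactors = FALSE
  )
  list(precursors = preDF, matures = matDF, truth = truth)
}

#' Simulate a complete fixture bundle
#'
#' Generates `nFamilies` families, a disease-association table over the
#' human matures (with some pipe-separated multi-disease cells), genomic
#' locations for the animal matures, and target-protein pairs at the
#' planted identity levels (plus one deliberately non-one-to-one human
#' gene). Deterministic for a fixed seed. When `dir` is given the bundle
#' is also written as the plain-text files every pipeline stage consumes.
#'
#' @param config a [simConfig()].
#' @param dir optional output directory.
#' @return list with `matureHuman`, `matureAnimal`, `precursors`
#'   ([MirnaSet-class] objects), `familyMap`, `diseasesRaw` (pipe cells
#'   merged, as serialized), `locations`, `proteins` (named character),
#'   `candidatePairs`, `truth` (ground-truth list) and `files` (paths,
#'   when written).
#' @export
simulateDataset <- function(config = simConfig(), dir = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  fams <- lapply(seq_len(config$nFamilies), function(k)
    simulateFamily(config, k))
  preDF <- do.call(rbind, lapply(fams, `[[`, "precursors"))
  matDF <- do.call(rbind, lapply(fams, `[[`, "matures"))
  truthDF <- do.call(rbind, lapply(fams, `[[`, "truth"))

  isHum <- matDF$species_code == "hsa"
  matureHuman <- mirnaSet(matDF$mirna_id[isHum], matDF$sequence[isHum],
                          matDF$accession[isHum], kind = "mature")
  matureAnimal <- mirnaSet(matDF$mirna_id[!isHum], matDF$sequence[!isHum],
                           matDF$accession[!isHum], kind = "mature")
  precursors <- mirnaSet(preDF$pre_id, preDF$sequence, preDF$accession,
                         kind = "precursor", family = preDF$family_id)
  familyMap <- data.frame(family_id = preDF$family_id,
                          pre_id = preDF$pre_id, stringsAsFactors = FALSE)

  # disease associations over human matures; one row per serialized cell
  humIDs <- matDF$mirna_id[isHum]
  rawRows <- list()
  triples <- list()
  nAssocRange <- config$associationsPerMirna
  for (h in humIDs) {
    n <- nAssocRange[1] + sample.int(nAssocRange[2] - nAssocRange[1] + 1L, 1) - 1L
    for (a in seq_len(n)) {
      pmid <- 1000000L + sample.int(9000000L, 1) - 1L
      ds <- sample(.DISEASE_POOL, 1)
      if (stats::runif(1) < config$pipeCellProb)
        ds <- c(ds, sample(setdiff(.DISEASE_POOL, ds), 1))
      rawRows[[length(rawRows) + 1L]] <- data.frame(
        mirna_id = h, disease = paste(ds, collapse = "|"), pmid = pmid,
        experiment = sample(.EXPERIMENT_POOL, 1),
        tissue = sample(.TISSUE_POOL, 1), stringsAsFactors = FALSE)
      triples[[length(triples) + 1L]] <- data.frame(
        mirna_id = h, disease = ds, pmid = pmid, stringsAsFactors = FALSE)
    }
  }
  diseasesRaw <- do.call(rbind, rawRows)
  tripleDF <- do.call(rbind, triples)

  locations <- data.frame(
    mirna_id = matDF$mirna_id[!isHum],
    chromosome = sample(c(as.character(1:22), "X"), sum(!isHum),
                        replace = TRUE),
    start = 99999L + sample.int(99900001L, sum(!isHum)),
    stringsAsFactors = FALSE
  )
  locations$end <- locations$start + config$matureLength - 1L
  locations$strand <- sample(c("+", "-"), nrow(locations), replace = TRUE)

  # target proteins at planted identity levels + one non-one-to-one gene
  Lp <- config$proteinLength
  mamm <- c("ssc", "eca", "cfa", "bta")
  proteins <- character(0)
  pairRows <- list()
  mkProt <- function() paste(sample(.AA20, Lp, replace = TRUE), collapse = "")
  mutate <- function(seq, nsub) {
    ch <- strsplit(seq, "")[[1]]
    pos <- sample(length(ch), nsub)
    ch[pos] <- vapply(ch[pos], function(x)
      sample(setdiff(.AA20, x), 1), character(1))
    paste(ch, collapse = "")
  }
  linkMirnas <- rep(humIDs, length.out = length(config$identityLevels) + 1)
  for (i in seq_along(config$identityLevels)) {
    lev <- config$identityLevels[i]
    gene <- sprintf("GENE%02d", i)
    sp <- mamm[(i - 1) %% length(mamm) + 1]
    hseq <- mkProt()
    nsub <- round((100 - lev) / 100 * Lp)
    aseq <- if (nsub == 0) hseq else mutate(hseq, nsub)
    proteins[gene] <- hseq
    agene <- paste0(gene, "_", toupper(sp))
    proteins[agene] <- aseq
    pairRows[[length(pairRows) + 1L]] <- data.frame(
      human_gene = gene, animal_gene = agene, species_code = sp,
      human_seq_id = gene, animal_seq_id = agene,
      confidence = as.integer(lev >= 90), mirna_id = linkMirnas[i],
      planted_identity = lev, stringsAsFactors = FALSE)
  }
  # a high-identity human gene with two animal partners in one species:
  # must be dropped by the one-to-one rule regardless of identity
  dupGene <- "GENEDUP"
  dupSeq <- mkProt()
  proteins[dupGene] <- dupSeq
  for (suffix in c("A", "B")) {
    agene <- paste0(dupGene, "_SSC", suffix)
    proteins[agene] <- mutate(dupSeq, round(0.05 * Lp))
    pairRows[[length(pairRows) + 1L]] <- data.frame(
      human_gene = dupGene, animal_gene = agene, species_code = "ssc",
      human_seq_id = dupGene, animal_seq_id = agene, confidence = 1L,
      mirna_id = linkMirnas[length(linkMirnas)], planted_identity = 95,
      stringsAsFactors = FALSE)
  }
  candidatePairs <- do.call(rbind, pairRows)

  truth <- list(
    exactMatches = truthDF[truthDF$exact, c("human_id", "animal_id",
                                            "species_code")],
    allPairs = truthDF,
    triples = tripleDF,
    matureTotals = table(matDF$species_code[!isHum]),
    expectedKeptGenes = sprintf("GENE%02d",
                                which(config$identityLevels > 70)),
    config = config
  )
  # expected resource rows: every planted triple crossed with the human
  # miRNA's exact animal matches
  nMatch <- table(truth$exactMatches$human_id)
  truth$expectedResourceRows <- sum(ifelse(
    tripleDF$mirna_id %in% names(nMatch), nMatch[tripleDF$mirna_id], 0))

  bundle <- list(matureHuman = matureHuman, matureAnimal = matureAnimal,
                 precursors = precursors, familyMap = familyMap,
                 diseasesRaw = diseasesRaw, locations = locations,
                 proteins = proteins, candidatePairs = candidatePairs,
                 truth = truth)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(dir, f)
    writeMirnaFasta(matureHuman, p("mature_human.fa"))
    writeMirnaFasta(matureAnimal, p("mature_animal.fa"))
    writeMirnaFasta(precursors, p("precursor_all.fa"))
    writeFamilyMap(familyMap, p("families.tsv"))
    utils::write.table(diseasesRaw, p("diseases.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(locations, p("locations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(paste0(">", names(proteins), "\n", unname(proteins)),
               p("proteins.fa"))
    utils::write.table(
      candidatePairs[, c("human_gene", "animal_gene", "species_code",
                         "human_seq_id", "animal_seq_id", "confidence",
                         "mirna_id")],
      p("pairs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    bundle$files <- list(
      humanMatureFa = p("mature_human.fa"),
      animalMatureFa = p("mature_animal.fa"),
      precursorFa = p("precursor_all.fa"),
      familyTsv = p("families.tsv"),
      diseaseTsv = p("diseases.tsv"),
      locationsTsv = p("locations.tsv"),
      proteinFa = p("proteins.fa"),
      pairsTsv = p("pairs.tsv")
    )
  }
  bundle
}
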