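# Integration of exact-match maps, disease associations, conservation
# calls, genomic locations and filtered ortholog pairs into the 28-field
# animal disease-miRNA resource table, plus its TSV serialization and the
# end-to-end pipeline driver.

#' The 28 canonical resource fields, in order
#'
#' Grouped MicroRNA (1-8), Location (9-11), Reference (12-15),
#' Disease (16-24) and Target (25-28). Field 10 holds the 1-based
#' inclusive coordinates as `<start>-<end>` so the table always has
#' exactly 28 columns.
#'
#' @return character vector of length 28.
#' @export
resourceFields <- function() c(
  "mature_mirna_id",       #  1
  "mature_mirna_ac",       #  2
  "mature_rna_sequence",   #  3
  "pre_mirna_id",          #  4
  "pre_mirna_ac",          #  5
  "pre_mirna_sequence",    #  6
  "family_id",             #  7
  "family_ac",             #  8
  "chromosome",            #  9
  "genomic_coordinates",   # 10
  "strand",                # 11
  "pubmed_id",             # 12
  "pmc_id",                # 13
  "pubmed_title",          # 14
  "pubmed_date",           # 15
  "disease_phenotype",     # 16
  "relevance_in_animal",   # 17
  "omim_omia_name",        # 18
  "omim_omia_id",          # 19
  "disease_ontology",      # 20
  "tissue_cell_type",      # 21
  "bto_name",              # 22
  "bto_id",                # 23
  "association_method",    # 24
  "target_gene",           # 25
  "animal_ortholog",       # 26
  "reciprocal_identity",   # 27
  "orthology_confidence"   # 28
)

#' Derive the precursor (hairpin) ID of a mature miRNA
#'
#' miRBase nomenclature: lowercase `mir`, arm suffix stripped
#' (`cfa-miR-143-3p` comes from `cfa-mir-143`).
#'
#' @param matureID character vector of mature IDs.
#' @return character vector of hairpin IDs.
#' @export
matureToPrecursorID <- function(matureID) {
  sub("-(5p|3p)$", "", sub("-miR-", "-mir-", matureID))
}

.emptyResource <- function() {
  cols <- c(resourceFields(), "human_homolog")
  df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                      cols), stringsAsFactors = FALSE)
  df$pubmed_id <- integer(0)
  df
}

#' Build the integrated animal disease-miRNA resource
#'
#' One record per (animal mature miRNA, human homolog, disease
#' association) triple — the finest grain the resource supports. Disease
#' associations whose human miRNA has no animal counterpart are excluded
#' (counted in a message, not an error). Fields absent from the inputs are
#' serialized as empty strings. The result is deterministically sorted by
#' (species, miRNA ID, PMID) and carries the linking `human_homolog` as an
#' auxiliary 29th column that [writeResourceTable()] does not serialize.
#'
#' @param map an [HdmacMap-class].
#' @param diseases disease-association data.frame from
#'   [readDiseaseTable()].
#' @param calls optional conservation calls from [conservationProfile()].
#'   (Carried for consumers; conservation does not alter the record grain.)
#' @param locations optional data.frame (`mirna_id`, `chromosome`,
#'   `start`, `end`, `strand`) for the animal mature miRNAs; coordinates
#'   are 1-based inclusive pass-through data, never computed.
#' @param orthologs optional kept pairs from [filterOrthologs()], with an
#'   extra `mirna_id` column linking each target to its human miRNA.
#' @param precursors optional precursor [MirnaSet-class] used to fill the
#'   hairpin fields.
#' @param families optional family map (`family_id`, `pre_id`).
#' @return data.frame of validated resource records.
#' @export
buildResource <- function(map, diseases, calls = NULL, locations = NULL,
                          orthologs = NULL, precursors = NULL,
                          families = NULL) {
  stopifnot(methods::is(map, "HdmacMap"))
  if (is.null(diseases) || nrow(diseases) == 0) {
    warning("empty disease table: 0 resource records")
    return(.emptyResource())
  }
  mm <- hdmacMatches(map)
  has_counterpart <- diseases$mirna_id %in% mm$human_id
  n_excluded <- sum(!has_counterpart)
  if (n_excluded > 0)
    message(n_excluded,
            " disease association(s) without an animal counterpart excluded")
  dis <- diseases[has_counterpart, , drop = FALSE]
  if (nrow(dis) == 0) return(.emptyResource())

  preSeq <- preAcc <- preFam <- character(0)
  if (!is.null(precursors)) {
    preSeq <- sequences(precursors)
    preAcc <- stats::setNames(accession(precursors), mirnaID(precursors))
    preFam <- stats::setNames(familyID(precursors), mirnaID(precursors))
  }
  famOf <- character(0)
  if (!is.null(families))
    famOf <- stats::setNames(families$family_id, families$pre_id)
  locOf <- NULL
  if (!is.null(locations) && nrow(locations) > 0) {
    locOf <- locations
    rownames(locOf) <- locations$mirna_id
  }

  opt <- function(row, col) {
    if (col %in% names(row) && !is.na(row[[col]])) as.character(row[[col]])
    else ""
  }

  recs <- vector("list", nrow(dis))
  for (r in seq_len(nrow(dis))) {
    drow <- dis[r, , drop = FALSE]
    hits <- mm[mm$human_id == drow$mirna_id, , drop = FALSE]
    pre_id <- matureToPrecursorID(hits$animal_id)
    fam <- rep("", length(pre_id))
    hitFam <- pre_id %in% names(famOf)
    fam[hitFam] <- famOf[pre_id[hitFam]]
    fill <- !nzchar(fam) & pre_id %in% names(preFam)
    fam[fill] <- preFam[pre_id[fill]]
    chrom <- coord <- strand <- rep("", nrow(hits))
    if (!is.null(locOf)) {
      found <- hits$animal_id %in% rownames(locOf)
      if (any(found)) {
        lr <- locOf[hits$animal_id[found], , drop = FALSE]
        chrom[found] <- as.character(lr$chromosome)
        coord[found] <- paste0(lr$start, "-", lr$end)
        strand[found] <- as.character(lr$strand)
      }
    }
    tgene <- torth <- tid <- tconf <- rep("", nrow(hits))
    if (!is.null(orthologs) && nrow(orthologs) > 0 &&
        "mirna_id" %in% colnames(orthologs)) {
      for (k in seq_len(nrow(hits))) {
        o <- orthologs[orthologs$mirna_id == drow$mirna_id &
                       orthologs$species_code == hits$species_code[k], ,
                       drop = FALSE]
        if (nrow(o) > 0) {
          tgene[k] <- o$human_gene[1]
          torth[k] <- o$animal_gene[1]
          tid[k] <- sprintf("%g", round(min(o$identity_h2a[1],
                                            o$identity_a2h[1]), 2))
          tconf[k] <- as.character(o$confidence[1])
        }
      }
    }
    recs[[r]] <- data.frame(
      mature_mirna_id = hits$animal_id,
      mature_mirna_ac = hits$animal_accession,
      mature_rna_sequence = hits$sequence,
      pre_mirna_id = pre_id,
      pre_mirna_ac = ifelse(pre_id %in% names(preAcc), preAcc[pre_id], ""),
      pre_mirna_sequence = ifelse(pre_id %in% names(preSeq), preSeq[pre_id], ""),
      family_id = fam,
      family_ac = "",
      chromosome = chrom,
      genomic_coordinates = coord,
      strand = strand,
      pubmed_id = as.integer(drow$pmid),
      pmc_id = opt(drow, "pmc_id"),
      pubmed_title = opt(drow, "pubmed_title"),
      pubmed_date = opt(drow, "pubmed_date"),
      disease_phenotype = as.character(drow$disease),
      relevance_in_animal = opt(drow, "relevance_in_animal"),
      omim_omia_name = opt(drow, "omim_omia_name"),
      omim_omia_id = opt(drow, "omim_omia_id"),
      disease_ontology = opt(drow, "disease_ontology"),
      tissue_cell_type = opt(drow, "tissue"),
      bto_name = opt(drow, "bto_name"),
      bto_id = opt(drow, "bto_id"),
      association_method = opt(drow, "experiment"),
      target_gene = tgene,
      animal_ortholog = torth,
      reciprocal_identity = tid,
      orthology_confidence = tconf,
      human_homolog = drow$mirna_id,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, recs)
  sp <- sub("-.*$", "", out$mature_mirna_id)
  out <- out[order(sp, out$mature_mirna_id, out$pubmed_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate one resource record
#'
#' Returns a character vector of violations, each naming the offending
#' field by its number and name; an empty vector means the record is
#' valid.
#'
#' @param r a one-row data.frame (or list) with the 28 resource fields.
#' @param species animal species panel for the mature-ID prefix check.
#' @return character vector of violations.
#' @export
validateRecord <- function(r, species = speciesTable()) {
  v <- character(0)
  val <- function(col) if (col %in% names(r)) as.character(r[[col]]) else ""
  id <- val("mature_mirna_id")
  if (!nzchar(id) || !sub("-.*$", "", id) %in% species$code)
    v <- c(v, "field 1 (mature_mirna_id): missing or not an animal-prefixed ID")
  seqv <- val("mature_rna_sequence")
  if (!nzchar(seqv) || grepl("[^ACGUN]", seqv))
    v <- c(v, "field 3 (mature_rna_sequence): missing or not canonical RNA")
  coord <- val("genomic_coordinates")
  if (nzchar(coord)) {
    se <- suppressWarnings(as.numeric(strsplit(coord, "-", fixed = TRUE)[[1]]))
    if (length(se) != 2 || anyNA(se) || se[1] > se[2])
      v <- c(v, "field 10 (genomic_coordinates): start must not exceed end")
  }
  strand <- val("strand")
  if (nzchar(strand) && !strand %in% c("+", "-"))
    v <- c(v, "field 11 (strand): must be + or -")
  pmid <- suppressWarnings(as.numeric(val("pubmed_id")))
  if (is.na(pmid) || pmid != floor(pmid) || pmid <= 0)
    v <- c(v, "field 12 (pubmed_id): must be a positive integer")
  tid <- val("reciprocal_identity")
  if (nzchar(tid)) {
    x <- suppressWarnings(as.numeric(tid))
    if (is.na(x) || x < 0 || x > 100)
      v <- c(v, "field 27 (reciprocal_identity): must lie in [0, 100]")
    if (!nzchar(val("target_gene")))
      v <- c(v, "field 25 (target_gene): required when an ortholog is present")
  }
  conf <- val("orthology_confidence")
  if (nzchar(conf) && !conf %in% c("0", "1"))
    v <- c(v, "field 28 (orthology_confidence): must be 0 or 1")
  v
}

#' Summarize a resource table
#'
#' Distinct counts over the stated key fields: animal mature miRNAs
#' (field 1), human miRNAs (auxiliary `human_homolog`, `NA` when absent,
#' e.g. after a read-back), diseases (field 16), PMIDs (field 12), plus
#' per-species record totals.
#'
#' @param records resource data.frame from [buildResource()] or
#'   [readResourceTable()].
#' @return list of counts.
#' @export
summarizeResource <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    return(list(n_records = 0L, n_animal_mirnas = 0L, n_human_mirnas = 0L,
                n_diseases = 0L, n_pmids = 0L,
                per_species = stats::setNames(integer(0), character(0))))
  sp <- sub("-.*$", "", records$mature_mirna_id)
  list(
    n_records = nrow(records),
    n_animal_mirnas = length(unique(records$mature_mirna_id)),
    n_human_mirnas = if ("human_homolog" %in% colnames(records))
      length(unique(records$human_homolog)) else NA_integer_,
    n_diseases = length(unique(records$disease_phenotype)),
    n_pmids = length(unique(records$pubmed_id)),
    per_species = vapply(split(seq_along(sp), sp), length, integer(1))
  )
}

#' Write the 28-column resource TSV
#'
#' Validates every record first and refuses to write when any record is
#' invalid. The header is the 28 canonical field names in order; optional
#' empty fields are empty strings; the auxiliary `human_homolog` column is
#' not serialized.
#'
#' @param records resource data.frame.
#' @param file optional path.
#' @param species animal species panel for validation.
#' @return the TSV text, invisibly when written.
#' @export
writeResourceTable <- function(records, file = NULL, species = speciesTable()) {
  fields <- resourceFields()
  missing_col <- setdiff(fields, colnames(records))
  if (length(missing_col) > 0)
    stop("resource table is missing column(s): ",
         paste(missing_col, collapse = ", "))
  for (i in seq_len(nrow(records))) {
    v <- validateRecord(records[i, , drop = FALSE], species)
    if (length(v) > 0)
      stop("invalid resource record ", i, ": ", v[1])
  }
  df <- records[, fields, drop = FALSE]
  header <- paste(fields, collapse = "\t")
  if (nrow(df) == 0) {
    txt <- header
  } else {
    body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    txt <- paste(c(header, body), collapse = "\n")
  }
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read a 28-column resource TSV
#'
#' @param file path or text connection.
#' @return data.frame with the 28 canonical columns (`pubmed_id` integer).
#' @export
readResourceTable <- function(file) {
  path <- .asTextPath(file)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (!identical(colnames(df), resourceFields()))
    stop("resource table must have exactly the 28 canonical columns")
  df$pubmed_id <- as.integer(df$pubmed_id)
  df
}

# ---- end-to-end driver -----------------------------------------------------

#' Run the whole pipeline from input files
#'
#' Reads the miRBase-dialect FASTA files, the disease table and the family
#' map; finds exact homologs; builds the presence matrix; computes the
#' per-family conservation profile; scores and filters candidate ortholog
#' pairs if protein inputs are given; and integrates everything into the
#' resource table. When `outDir` is given, writes `resource.tsv`,
#' `presence_matrix.tsv`, `conservation_calls.tsv` and one Newick tree per
#' family under `trees/`.
#'
#' @param humanMatureFa,animalMatureFa,precursorFa FASTA paths (the
#'   precursor file holds human and animal hairpins together).
#' @param familyTsv family map path.
#' @param diseaseTsv disease-association table path.
#' @param locationsTsv optional locations TSV
#'   (`mirna_id  chromosome  start  end  strand`).
#' @param proteinFa optional protein FASTA (human + animal sequences).
#' @param pairsTsv optional candidate ortholog pairs TSV with columns
#'   `human_gene`, `animal_gene`, `species_code`, `human_seq_id`,
#'   `animal_seq_id`, `confidence`, `mirna_id`.
#' @param species animal species panel.
#' @param scheme nucleotide scoring scheme for the precursor alignments.
#' @param outDir optional output directory.
#' @return list with `map`, `presence`, `profile`, `orthologs`, `resource`
#'   and `summary`.
#' @export
runPipeline <- function(humanMatureFa, animalMatureFa, precursorFa,
                        familyTsv, diseaseTsv, locationsTsv = NULL,
                        proteinFa = NULL, pairsTsv = NULL,
                        species = speciesTable(),
                        scheme = scoringScheme(), outDir = NULL) {
  human <- readMirnaFasta(humanMatureFa, "mature", species)
  animals <- readMirnaFasta(animalMatureFa, "mature", species)
  pre <- readMirnaFasta(precursorFa, "precursor", species)
  fam <- readFamilyMap(familyTsv)
  diseases <- readDiseaseTable(diseaseTsv)
  locations <- if (!is.null(locationsTsv))
    utils::read.delim(locationsTsv, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE) else NULL

  map <- findExactHomologs(human, animals)
  presence <- buildPresenceMatrix(map, species)

  # restrict conservation analysis to precursors of matched miRNAs' families
  hdmacPre <- unique(c(matureToPrecursorID(hdmacHuman(map)$mirna_id),
                       matureToPrecursorID(hdmacMatches(map)$animal_id)))
  famKeep <- unique(fam$family_id[fam$pre_id %in% hdmacPre])
  famSub <- fam[fam$family_id %in% famKeep, , drop = FALSE]
  inFam <- mirnaID(pre) %in% famSub$pre_id
  humanPre <- pre[inFam & speciesCode(pre) == "hsa"]
  animalPre <- pre[inFam & speciesCode(pre) != "hsa"]
  profile <- if (length(humanPre) > 0 && length(animalPre) > 0)
    conservationProfile(humanPre, animalPre, famSub, scheme)
  else list(calls = NULL, binCounts = NULL, families = list())

  orthologs <- NULL
  if (!is.null(proteinFa) && !is.null(pairsTsv)) {
    prot <- Biostrings::readAAStringSet(proteinFa)
    protSeq <- stats::setNames(as.character(prot),
                               vapply(strsplit(names(prot), "\\s+"),
                                      `[`, character(1), 1))
    cand <- utils::read.delim(pairsTsv, header = TRUE, sep = "\t", quote = "",
                              stringsAsFactors = FALSE)
    pscheme <- scoringScheme(alphabet = "protein")
    ids <- t(vapply(seq_len(nrow(cand)), function(i) {
      percentIdentity(protSeq[[cand$human_seq_id[i]]],
                      protSeq[[cand$animal_seq_id[i]]], pscheme)
    }, numeric(2)))
    cand$identity_h2a <- ids[, 1]
    cand$identity_a2h <- ids[, 2]
    orthologs <- filterOrthologs(cand)
  }

  # attach family labels to precursors for the resource
  preFam <- stats::setNames(rep("", length(pre)), mirnaID(pre))
  hit <- fam$pre_id %in% names(preFam)
  preFam[fam$pre_id[hit]] <- fam$family_id[hit]
  pre@info$family_id <- unname(preFam[mirnaID(pre)])

  resource <- buildResource(map, diseases, calls = profile$calls,
                            locations = locations, orthologs = orthologs,
                            precursors = pre, families = fam)
  summ <- summarizeResource(resource)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeResourceTable(resource, file.path(outDir, "resource.tsv"), species)
    writePresenceMatrix(presence, file.path(outDir, "presence_matrix.tsv"))
    if (!is.null(profile$calls))
      utils::write.table(profile$calls, file.path(outDir,
                         "conservation_calls.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    if (length(profile$families) > 0) {
      dir.create(file.path(outDir, "trees"), showWarnings = FALSE)
      for (famID in names(profile$families))
        writeNewick(profile$families[[famID]]$tree,
                    file.path(outDir, "trees", paste0(famID, ".nwk")))
    }
  }
  list(map = map, presence = presence, profile = profile,
       orthologs = orthologs, resource = resource, summary = summ)
}
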