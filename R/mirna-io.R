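# Readers/writers for the miRBase-dialect FASTA, disease-association TSV,
# family map, Newick trees and +/- presence matrices. All tabular formats
# are TSV, UTF-8, unquoted (disease names contain commas).

.asTextPath <- function(x) {
  if (inherits(x, "connection")) {
    tf <- tempfile(fileext = ".txt")
    writeLines(readLines(x), tf)
    return(tf)
  }
  x
}

#' Read a miRBase-dialect FASTA of mature or precursor miRNAs
#'
#' The header's first whitespace token is the miRNA ID and the second, when
#' present, the accession; any further tokens (species name, description)
#' are ignored. Sequences are normalized to uppercase RNA (T becomes U).
#' Records with an empty sequence or with characters outside
#' \{A,C,G,T,U,N\} are rejected with a warning while parsing continues;
#' a header with no ID token is a hard error. `N` bases are retained but
#' flagged (`has_n`), and such records are excluded from exact matching
#' downstream. Records whose species prefix is not human or in the species
#' panel are flagged `known_species = FALSE`, never dropped.
#'
#' @param file path or text connection to a FASTA file.
#' @param kind `"mature"` or `"precursor"`.
#' @param species animal species panel (see [speciesTable()]).
#' @return a [MirnaSet-class]; input order is preserved.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">hsa-miR-1-3p MIMAT0000416", "UGGAAUGUAAAGAAGUAUGUAU"), fa)
#' readMirnaFasta(fa, "mature")
#' @export
readMirnaFasta <- function(file, kind = c("mature", "precursor"),
                           species = speciesTable()) {
  kind <- match.arg(kind)
  path <- .asTextPath(file)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0)
    return(mirnaSet(character(0), character(0), kind = kind, species = species))
  headers <- names(ss)
  ids <- vapply(strsplit(headers, "\\s+"), function(t) {
    t <- t[nzchar(t)]
    if (length(t) == 0) NA_character_ else t[1]
  }, character(1))
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("malformed FASTA header with no ID token")
  accs <- vapply(strsplit(headers, "\\s+"), function(t) {
    t <- t[nzchar(t)]
    if (length(t) >= 2) t[2] else ""
  }, character(1))
  raw <- as.character(ss)
  norm <- character(length(raw))
  keep <- logical(length(raw))
  for (i in seq_along(raw)) {
    if (nchar(raw[i]) == 0) {
      warning("empty sequence for '", headers[i], "': record rejected")
      next
    }
    norm[i] <- tryCatch(normalizeSequence(raw[i]), error = function(e) {
      warning("invalid sequence for '", headers[i], "': record rejected")
      NA_character_
    })
    keep[i] <- !is.na(norm[i])
  }
  mirnaSet(ids[keep], norm[keep], accs[keep], kind = kind, species = species)
}

#' Write miRNA records as FASTA
#'
#' One header line (`>id accession`) and one unwrapped sequence line per
#' record, in input order.
#'
#' @param x a [MirnaSet-class].
#' @param file optional path; when `NULL` the FASTA text is returned.
#' @return the FASTA text, invisibly when written to a file.
#' @export
writeMirnaFasta <- function(x, file = NULL) {
  stopifnot(methods::is(x, "MirnaSet"))
  if (length(x) == 0) {
    txt <- ""
  } else {
    hd <- ifelse(nzchar(accession(x)),
                 paste0(">", mirnaID(x), " ", accession(x)),
                 paste0(">", mirnaID(x)))
    txt <- paste(paste(hd, unname(sequences(x)), sep = "\n"), collapse = "\n")
  }
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read a disease-association table
#'
#' TSV with a header naming at least `mirna_id`, `disease` and `pmid`.
#' A cell listing several diseases separated by a pipe (`|`) is split into
#' one association per disease sharing the same PMID. Rows with a
#' non-integer or non-positive PMID, or a non-human miRNA ID, are rejected
#' with a warning; a missing mandatory column is a hard error. Optional
#' columns (`experiment`, `tissue`, PMC/title/date, OMIM/OMIA/DO/BTO
#' fields, `relevance_in_animal`) are carried through as opaque strings.
#'
#' @param file path or text connection.
#' @return a data.frame with one row per (miRNA, disease, PMID) association.
#' @export
readDiseaseTable <- function(file) {
  path <- .asTextPath(file)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = TRUE,
                          stringsAsFactors = FALSE)
  mandatory <- c("mirna_id", "disease", "pmid")
  missing_col <- setdiff(mandatory, colnames(df))
  if (length(missing_col) > 0)
    stop("disease table is missing mandatory column(s): ",
         paste(missing_col, collapse = ", "))
  optional <- c("experiment", "tissue", "pmc_id", "pubmed_title",
                "pubmed_date", "relevance_in_animal", "omim_omia_name",
                "omim_omia_id", "disease_ontology", "bto_name", "bto_id")
  for (col in optional) if (!col %in% colnames(df)) df[[col]] <- ""
  pmid_num <- suppressWarnings(as.numeric(df$pmid))
  ok <- !is.na(pmid_num) & pmid_num == floor(pmid_num) & pmid_num > 0
  if (any(!ok))
    warning(sum(!ok), " row(s) with invalid PMID rejected")
  human <- startsWith(df$mirna_id, "hsa-")
  if (any(ok & !human))
    warning(sum(ok & !human), " non-human row(s) rejected")
  df <- df[ok & human, , drop = FALSE]
  if (nrow(df) == 0) {
    df$pmid <- integer(0)
    return(df[, c(mandatory, optional)])
  }
  # split pipe-separated multi-disease cells into one row per disease
  parts <- strsplit(df$disease, "|", fixed = TRUE)
  idx <- rep(seq_len(nrow(df)), lengths(parts))
  out <- df[idx, , drop = FALSE]
  out$disease <- trimws(unlist(parts))
  out$pmid <- as.integer(as.numeric(out$pmid))
  rownames(out) <- NULL
  out[, c(mandatory, optional)]
}

#' Read a miRNA family map
#'
#' Two-column TSV (`family_id<TAB>pre_id`); a header row naming the two
#' columns is recognised and skipped.
#'
#' @param file path or text connection.
#' @return data.frame with columns `family_id`, `pre_id`.
#' @export
readFamilyMap <- function(file) {
  path <- .asTextPath(file)
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("family map must have two tab-separated columns")
  df <- df[, 1:2]
  colnames(df) <- c("family_id", "pre_id")
  if (nrow(df) > 0 && df$family_id[1] == "family_id")
    df <- df[-1, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a family map
#' @param fam data.frame with `family_id`, `pre_id`.
#' @param file output path.
#' @export
writeFamilyMap <- function(fam, file) {
  utils::write.table(fam[, c("family_id", "pre_id")], file, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(file)
}

# ---- Newick ----------------------------------------------------------------

#' Serialize a phylogenetic tree as Newick
#'
#' Leaf labels are pre-miRNA IDs; branch lengths are written with six
#' decimals; the string terminates with `;`. Duplicate leaf labels are a
#' hard error. A single label (character scalar) is serialized as the
#' trivial one-leaf tree.
#'
#' @param tree an [ape::phylo] tree, or a character scalar for a single
#'   leaf.
#' @param file optional path.
#' @return the Newick string.
#' @examples
#' writeNewick("hsa-mir-1")
#' @export
writeNewick <- function(tree, file = NULL) {
  if (is.character(tree) && length(tree) == 1) {
    txt <- sprintf("%s:%.6f;", tree, 0)
  } else {
    stopifnot(inherits(tree, "phylo"))
    if (anyDuplicated(tree$tip.label) > 0)
      stop("duplicate leaf labels in tree")
    ntip <- length(tree$tip.label)
    edge <- tree$edge
    len <- tree$edge.length
    if (is.null(len)) len <- rep(0, nrow(edge))
    kids <- split(seq_len(nrow(edge)), edge[, 1])
    rec <- function(node) {
      if (node <= ntip) return(tree$tip.label[node])
      rows <- kids[[as.character(node)]]
      sub <- vapply(rows, function(r)
        sprintf("%s:%.6f", rec(edge[r, 2]), len[r]), character(1))
      paste0("(", paste(sub, collapse = ","), ")")
    }
    root <- setdiff(edge[, 1], edge[, 2])[1]
    txt <- paste0(rec(root), ";")
  }
  if (!is.null(file)) writeLines(txt, file)
  txt
}

# ---- presence matrix (+/- dialect) ----------------------------------------

#' Write a presence/absence matrix with +/- cells
#'
#' Emits the tabular dialect used for distributing conservation matrices:
#' `human_homolog`, one `+`/`-` column per species, and the
#' `total_animal_species` count.
#'
#' @param x a [PresenceMatrix-class].
#' @param file optional path.
#' @return the TSV text, invisibly when written.
#' @export
writePresenceMatrix <- function(x, file = NULL) {
  stopifnot(methods::is(x, "PresenceMatrix"))
  m <- presenceCells(x)
  header <- paste(c("human_homolog", colnames(m), "total_animal_species"),
                  collapse = "\t")
  if (nrow(m) == 0) {
    txt <- header
  } else {
    cells <- ifelse(m, "+", "-")
    rows <- vapply(seq_len(nrow(m)), function(i)
      paste(c(rownames(m)[i], cells[i, ], sum(m[i, ])), collapse = "\t"),
      character(1))
    txt <- paste(c(header, rows), collapse = "\n")
  }
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read a presence/absence matrix with +/- cells
#'
#' Recognises any column whose cells are all `+` or `-` as a species
#' column; the first column holds the human miRNA IDs. A printed total
#' column, if present, is returned in attribute `printed_total` for
#' cross-checking but the object's `speciesCount` is always recomputed.
#'
#' @param file path or text connection.
#' @return a [PresenceMatrix-class].
#' @export
readPresenceMatrix <- function(file) {
  path <- .asTextPath(file)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("presence matrix needs an ID column and species columns")
  is_pm <- vapply(df, function(col) all(col %in% c("+", "-")), logical(1))
  is_pm[1] <- FALSE
  if (!any(is_pm)) stop("no +/- species columns found")
  m <- as.matrix(df[, is_pm, drop = FALSE]) == "+"
  rownames(m) <- df[[1]]
  out <- presenceMatrix(m)
  if ("total_animal_species" %in% colnames(df))
    attr(out, "printed_total") <- as.integer(df$total_animal_species)
  out
}
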