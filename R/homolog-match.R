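# Exact-sequence matching of animal mature miRNAs against human
# disease-associated mature miRNAs, and the derived presence/absence
# statistics.

#' Normalize a nucleotide sequence to canonical RNA
#'
#' Uppercases and converts T to U; no other characters change. Characters
#' outside \{A,C,G,T,U,N\} (any case) are an error.
#'
#' @param seq a non-empty string.
#' @return the canonical RNA string.
#' @examples
#' normalizeSequence("TGAGGTA")  # "UGAGGUA"
#' @export
normalizeSequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) == 0) stop("empty sequence")
  up <- chartr("T", "U", toupper(seq))
  if (grepl("[^ACGUN]", up))
    stop("invalid character in sequence: ",
         sub(".*?([^ACGUN]).*", "\\1", up))
  up
}

#' Find animal mature miRNAs 100% identical to human disease miRNAs
#'
#' A human miRNA enters the map iff at least one animal mature sequence
#' equals its sequence exactly: full length, no mismatch, no offset.
#' Matching is on normalized sequence only (IDs, arms and families are
#' annotation); case and T/U differences never block a match because both
#' sets are normalized on construction. Sequences containing `N` can never
#' certify 100% identity and are excluded from matching on either side.
#' Duplicate sequences within one species (distinct IDs) are each reported.
#'
#' @param human a mature [MirnaSet-class], all `hsa-` records.
#' @param animals a mature [MirnaSet-class], all non-`hsa` records.
#' @return an [HdmacMap-class].
#' @export
findExactHomologs <- function(human, animals) {
  stopifnot(methods::is(human, "MirnaSet"), methods::is(animals, "MirnaSet"))
  if (length(human) > 0 && any(speciesCode(human) != "hsa"))
    stop("'human' must contain only hsa- records")
  if (length(animals) > 0 && any(speciesCode(animals) == "hsa"))
    stop("'animals' must not contain hsa- records")
  hinfo <- mirnaInfo(human)
  ainfo <- mirnaInfo(animals)
  hseq <- unname(sequences(human))
  aseq <- unname(sequences(animals))
  husable <- if (length(human) > 0) !hinfo$has_n else logical(0)
  ausable <- if (length(animals) > 0) !ainfo$has_n else logical(0)
  rows <- vector("list", length(hseq))
  for (i in seq_along(hseq)) {
    if (!husable[i]) next
    hit <- which(ausable & aseq == hseq[i])
    if (length(hit) == 0) next
    rows[[i]] <- data.frame(
      human_id = hinfo$mirna_id[i],
      animal_id = ainfo$mirna_id[hit],
      species_code = ainfo$species_code[hit],
      animal_accession = ainfo$accession[hit],
      sequence = hseq[i],
      stringsAsFactors = FALSE
    )
  }
  matched <- !vapply(rows, is.null, logical(1))
  matches <- if (any(matched)) do.call(rbind, rows[matched])
             else data.frame(human_id = character(0), animal_id = character(0),
                             species_code = character(0),
                             animal_accession = character(0),
                             sequence = character(0), stringsAsFactors = FALSE)
  rownames(matches) <- NULL
  humtab <- data.frame(
    mirna_id = hinfo$mirna_id[matched],
    accession = hinfo$accession[matched],
    sequence = hseq[matched],
    stringsAsFactors = FALSE
  )
  methods::new("HdmacMap", matches = matches, human = humtab)
}

#' Build the human miRNA x species presence/absence matrix
#'
#' Cell (h, s) is `TRUE` iff some exact animal match of human miRNA h
#' belongs to species s. Row order follows the map's human record order,
#' column order the species panel.
#'
#' @param map an [HdmacMap-class].
#' @param species animal species panel.
#' @return a [PresenceMatrix-class].
#' @export
buildPresenceMatrix <- function(map, species = speciesTable()) {
  stopifnot(methods::is(map, "HdmacMap"))
  hum <- hdmacHuman(map)$mirna_id
  m <- matrix(FALSE, nrow = length(hum), ncol = nrow(species),
              dimnames = list(hum, species$code))
  mm <- hdmacMatches(map)
  for (i in seq_len(nrow(mm))) {
    if (mm$species_code[i] %in% colnames(m))
      m[mm$human_id[i], mm$species_code[i]] <- TRUE
  }
  presenceMatrix(m)
}

#' Select human miRNAs by conservation pattern
#'
#' `all_species` keeps rows conserved in every species of the matrix;
#' `mammals_only` keeps rows conserved in every species except chicken
#' (`gga`), with the chicken cell absent — it therefore requires a `gga`
#' column. The two selections are disjoint by construction.
#'
#' @param x a [PresenceMatrix-class].
#' @param mode `"all_species"` or `"mammals_only"`.
#' @return character vector of human miRNA IDs.
#' @export
filterConserved <- function(x, mode = c("all_species", "mammals_only")) {
  stopifnot(methods::is(x, "PresenceMatrix"))
  if (length(mode) != 1 || !mode %in% c("all_species", "mammals_only"))
    stop("unknown mode: ", paste(mode, collapse = ","))
  m <- presenceCells(x)
  if (nrow(m) == 0) return(character(0))
  if (mode == "all_species") {
    rownames(m)[rowSums(m) == ncol(m)]
  } else {
    if (!"gga" %in% colnames(m))
      stop("'mammals_only' requires a gga (chicken) column")
    mam <- m[, setdiff(colnames(m), "gga"), drop = FALSE]
    rownames(m)[rowSums(mam) == ncol(mam) & !m[, "gga"]]
  }
}

#' Per-species exact-match coverage
#'
#' For each species, the number of distinct animal mature miRNA IDs that
#' matched some human disease miRNA, and that count as a percentage of the
#' species' total mature miRNA count.
#'
#' @param map an [HdmacMap-class].
#' @param totals named numeric vector, total mature miRNA count per
#'   species code; all positive. Every species occurring in the map must
#'   be present.
#' @return data.frame with `species_code`, `matched`, `total`, `percent`.
#' @export
coverageStats <- function(map, totals) {
  stopifnot(methods::is(map, "HdmacMap"))
  if (is.null(names(totals)) || any(totals <= 0))
    stop("'totals' must be a named vector of positive counts")
  mm <- hdmacMatches(map)
  missing_sp <- setdiff(unique(mm$species_code), names(totals))
  if (length(missing_sp) > 0)
    stop("species in map missing from totals: ",
         paste(missing_sp, collapse = ", "))
  matched <- vapply(names(totals), function(sp)
    length(unique(mm$animal_id[mm$species_code == sp])), integer(1))
  data.frame(species_code = names(totals), matched = matched,
             total = as.numeric(totals),
             percent = 100 * matched / as.numeric(totals),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mature miRNA length distribution per species
#'
#' @param x a mature [MirnaSet-class].
#' @return list with `counts` (species x length contingency table) and
#'   `modal` (named integer vector, per-species modal length; smallest
#'   length wins ties).
#' @export
lengthDistribution <- function(x) {
  stopifnot(methods::is(x, "MirnaSet"))
  if (length(x) == 0)
    return(list(counts = table(character(0), integer(0)),
                modal = stats::setNames(integer(0), character(0))))
  len <- nchar(unname(sequences(x)))
  sp <- speciesCode(x)
  counts <- table(species = sp, length = len)
  modal <- apply(counts, 1, function(row)
    as.integer(colnames(counts)[which.max(row)]))
  list(counts = counts, modal = modal)
}
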