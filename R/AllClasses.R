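#' @include mirCons-package.R
NULL

.RNA_ALPHABET <- c("A", "C", "G", "U")
.SPECIES_DEFAULT <- data.frame(
  code = c("bta", "gga", "ssc", "eca", "cfa"),
  name = c("cow", "chicken", "pig", "horse", "dog"),
  stringsAsFactors = FALSE
)

#' Default animal species panel
#'
#' The ordered (code, name) table of animal species considered by the
#' pipeline. Human (`hsa`) is never part of the animal panel; it is the
#' reference species every comparison starts from.
#'
#' @param codes,names optional character vectors overriding the default
#'   panel of cow (`bta`), chicken (`gga`), pig (`ssc`), horse (`eca`) and
#'   dog (`cfa`).
#' @return a data.frame with columns `code` and `name`.
#' @examples
#' speciesTable()
#' @export
speciesTable <- function(codes = NULL, names = NULL) {
  if (is.null(codes)) return(.SPECIES_DEFAULT)
  stopifnot(is.character(codes), length(codes) >= 1)
  if (is.null(names)) names <- codes
  stopifnot(length(names) == length(codes))
  if (anyDuplicated(codes) > 0)
    stop("species codes must be unique")
  if ("hsa" %in% codes)
    stop("'hsa' (human) cannot be listed as an animal species")
  data.frame(code = codes, name = names, stringsAsFactors = FALSE)
}

# ---- MirnaSet --------------------------------------------------------------

#' MirnaSet: a set of mature or precursor miRNA records
#'
#' Wraps a [Biostrings::RNAStringSet] of normalized sequences (uppercase,
#' T converted to U) together with per-record metadata parsed from
#' miRBase-style FASTA headers: miRNA ID, accession, species code (the ID
#' prefix before the first hyphen), arm (`5p`/`3p`/`unspecified`, mature
#' only) and family ID (precursor only, filled from a family map).
#'
#' @slot seqs an `RNAStringSet`, names are the miRNA IDs.
#' @slot info a data.frame aligned with `seqs` holding `mirna_id`,
#'   `accession`, `species_code`, `arm` or `family_id`, `has_n` (whether the
#'   sequence contains an N) and `known_species`.
#' @slot kind `"mature"` or `"precursor"`.
#' @export
setClass("MirnaSet",
  representation(seqs = "ANY", info = "data.frame", kind = "character"))

setValidity("MirnaSet", function(object) {
  if (!methods::is(object@seqs, "RNAStringSet"))
    return("'seqs' must be an RNAStringSet")
  if (!object@kind %in% c("mature", "precursor"))
    return("'kind' must be 'mature' or 'precursor'")
  if (nrow(object@info) != length(object@seqs))
    return("'info' rows must match number of sequences")
  need <- c("mirna_id", "accession", "species_code")
  if (!all(need %in% colnames(object@info)))
    return(paste("info must contain columns:", paste(need, collapse = ", ")))
  s <- as.character(object@seqs)
  if (any(nchar(s) == 0)) return("empty sequence")
  bad <- grepl("[^ACGUN]", s)
  if (any(bad))
    return(paste0("sequence alphabet outside {A,C,G,U,N}: ",
                  object@info$mirna_id[which(bad)[1]]))
  pref <- sub("-.*$", "", object@info$mirna_id)
  if (!all(pref == object@info$species_code))
    return("species_code must equal the ID prefix before the first hyphen")
  TRUE
})

#' Construct a MirnaSet from parallel vectors
#'
#' @param ids miRBase-style IDs (e.g. `hsa-miR-143-3p`, `hsa-mir-143`).
#' @param sequences raw sequences; normalized with [normalizeSequence()].
#' @param accessions optional accession strings (empty allowed).
#' @param kind `"mature"` or `"precursor"`.
#' @param family optional family IDs (precursor sets).
#' @param species animal species panel used to flag unknown species codes.
#' @return a [MirnaSet-class] object.
#' @examples
#' mirnaSet("hsa-miR-1-3p", "UGGAAUGUAAAGAAGUAUGUAU", "MIMAT0000416")
#' @export
mirnaSet <- function(ids, sequences, accessions = NULL, kind = "mature",
                     family = NULL, species = speciesTable()) {
  stopifnot(length(ids) == length(sequences))
  if (is.null(accessions)) accessions <- rep("", length(ids))
  seqs <- vapply(sequences, normalizeSequence, character(1), USE.NAMES = FALSE)
  info <- data.frame(
    mirna_id = as.character(ids),
    accession = as.character(accessions),
    species_code = sub("-.*$", "", as.character(ids)),
    stringsAsFactors = FALSE
  )
  if (kind == "mature") {
    info$arm <- ifelse(grepl("-5p$", ids), "5p",
                ifelse(grepl("-3p$", ids), "3p", "unspecified"))
  } else {
    info$family_id <- if (is.null(family)) rep("", length(ids))
                      else as.character(family)
  }
  info$has_n <- grepl("N", seqs, fixed = TRUE)
  info$known_species <- info$species_code %in% c("hsa", species$code)
  if (kind == "mature") {
    len <- nchar(seqs)
    out <- len < 16L | len > 28L
    if (any(out))
      warning(sum(out), " mature sequence(s) outside the typical 16-28 nt range")
  }
  ss <- Biostrings::RNAStringSet(seqs)
  names(ss) <- info$mirna_id
  methods::new("MirnaSet", seqs = ss, info = info, kind = kind)
}

#' @describeIn MirnaSet-class number of records
#' @param x a `MirnaSet`
#' @export
setMethod("length", "MirnaSet", function(x) length(x@seqs))

#' @describeIn MirnaSet-class subset records
#' @param i index vector
#' @param j,drop ignored
#' @param ... ignored
#' @export
setMethod("[", "MirnaSet", function(x, i, j, ..., drop = TRUE) {
  methods::new("MirnaSet", seqs = x@seqs[i],
               info = x@info[i, , drop = FALSE], kind = x@kind)
})

setMethod("show", "MirnaSet", function(object) {
  cat("MirnaSet of", length(object), object@kind, "records\n")
  tab <- table(object@info$species_code)
  cat("  species:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  if (length(object) > 0)
    cat("  first:", object@info$mirna_id[1], "(",
        as.character(object@seqs[[1]]), ")\n")
})

#' @rdname MirnaSet-class
#' @param x a `MirnaSet`
#' @export
mirnaID <- function(x) x@info$mirna_id

#' @rdname MirnaSet-class
#' @export
accession <- function(x) x@info$accession

#' @rdname MirnaSet-class
#' @export
speciesCode <- function(x) x@info$species_code

#' @rdname MirnaSet-class
#' @export
mirnaArm <- function(x) {
  if (x@kind != "mature") stop("arm is defined for mature sets only")
  x@info$arm
}

#' @rdname MirnaSet-class
#' @export
familyID <- function(x) {
  if (x@kind != "precursor") stop("family ID is defined for precursor sets only")
  x@info$family_id
}

#' @rdname MirnaSet-class
#' @export
sequences <- function(x) stats::setNames(as.character(x@seqs), x@info$mirna_id)

#' @rdname MirnaSet-class
#' @export
mirnaInfo <- function(x) x@info

#' @rdname MirnaSet-class
#' @export
mirnaKind <- function(x) x@kind

# ---- HdmacMap --------------------------------------------------------------

#' HdmacMap: human disease miRNAs with animal counterparts
#'
#' The result of exact-sequence matching: each human mature miRNA that has
#' at least one animal mature miRNA with a byte-identical (normalized)
#' sequence, together with every qualifying animal record.
#'
#' @slot matches data.frame with one row per (human, animal) exact match:
#'   `human_id`, `animal_id`, `species_code`, `animal_accession`, `sequence`.
#' @slot human data.frame of the matched human records
#'   (`mirna_id`, `accession`, `sequence`).
#' @export
setClass("HdmacMap",
  representation(matches = "data.frame", human = "data.frame"))

setValidity("HdmacMap", function(object) {
  m <- object@matches
  need <- c("human_id", "animal_id", "species_code", "animal_accession",
            "sequence")
  if (!all(need %in% colnames(m)))
    return(paste("matches must contain:", paste(need, collapse = ", ")))
  if (!all(c("mirna_id", "accession", "sequence") %in% colnames(object@human)))
    return("human must contain mirna_id, accession, sequence")
  if (nrow(m) > 0) {
    hs <- stats::setNames(object@human$sequence, object@human$mirna_id)
    if (any(!m$human_id %in% names(hs)))
      return("every matched human_id must appear in the human table")
    if (any(hs[m$human_id] != m$sequence))
      return("animal sequence differs from its human key's sequence")
  }
  if (!all(object@human$mirna_id %in% m$human_id))
    return("human table lists an ID with no animal match")
  TRUE
})

setMethod("show", "HdmacMap", function(object) {
  cat("HdmacMap:", nrow(object@human), "human disease miRNAs matched by",
      nrow(object@matches), "animal mature miRNAs\n")
  if (nrow(object@matches) > 0) {
    tab <- table(object@matches$species_code)
    cat("  per species:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
})

#' @rdname HdmacMap-class
#' @param x an `HdmacMap`
#' @export
hdmacMatches <- function(x) x@matches

#' @rdname HdmacMap-class
#' @export
hdmacHuman <- function(x) x@human

#' @describeIn HdmacMap-class number of matched human miRNAs
#' @export
setMethod("length", "HdmacMap", function(x) nrow(x@human))

# ---- PresenceMatrix --------------------------------------------------------

#' PresenceMatrix: human miRNA x species conservation matrix
#'
#' Boolean matrix with one row per matched human disease miRNA and one
#' column per animal species; `TRUE` means at least one 100%-identical
#' mature miRNA exists in that species. The per-row `speciesCount` is the
#' number of `TRUE` cells.
#'
#' @slot mat logical matrix; rownames are human miRNA IDs, colnames species
#'   codes.
#' @export
setClass("PresenceMatrix", representation(mat = "matrix"))

setValidity("PresenceMatrix", function(object) {
  m <- object@mat
  if (nrow(m) > 0 || ncol(m) > 0) {
    if (!is.logical(m)) return("matrix must be logical")
    if (is.null(colnames(m))) return("matrix must have species colnames")
    if (nrow(m) > 0 && is.null(rownames(m)))
      return("matrix must have human miRNA rownames")
  }
  TRUE
})

#' Construct a PresenceMatrix from a logical matrix
#'
#' Useful for encoding externally published presence/absence tables.
#'
#' @param mat logical matrix, rownames human miRNA IDs, colnames species
#'   codes.
#' @return a [PresenceMatrix-class].
#' @export
presenceMatrix <- function(mat) {
  storage.mode(mat) <- "logical"
  methods::new("PresenceMatrix", mat = mat)
}

setMethod("show", "PresenceMatrix", function(object) {
  cat("PresenceMatrix:", nrow(object@mat), "human miRNAs x",
      ncol(object@mat), "species\n")
  if (nrow(object@mat) > 0) {
    cnt <- speciesCount(object)
    cat("  species counts:",
        paste(names(table(cnt)), table(cnt), sep = "->", collapse = " "), "\n")
  }
})

#' @rdname PresenceMatrix-class
#' @param x a `PresenceMatrix`
#' @export
presenceCells <- function(x) x@mat

#' @rdname PresenceMatrix-class
#' @export
speciesCount <- function(x) {
  if (nrow(x@mat) == 0) return(stats::setNames(integer(0), character(0)))
  stats::setNames(as.integer(rowSums(x@mat)), rownames(x@mat))
}

#' @describeIn PresenceMatrix-class number of rows (human miRNAs)
#' @export
setMethod("length", "PresenceMatrix", function(x) nrow(x@mat))

# ---- ScoringScheme ---------------------------------------------------------

#' ScoringScheme: alignment scoring parameters
#'
#' Affine-gap global alignment parameters. A gap run of length k costs
#' `gapOpen + (k - 1) * gapExtend`. In protein mode a substitution table
#' (BLOSUM62 by default) replaces the flat match/mismatch scores.
#'
#' @slot match,mismatch per-column scores (nucleotide mode).
#' @slot gapOpen,gapExtend gap penalties, `gapOpen <= gapExtend <= 0`.
#' @slot alphabet `"nucleotide"` or `"protein"`.
#' @slot substitutionMatrix symbol-pair score matrix (protein mode) or a
#'   0x0 matrix.
#' @export
setClass("ScoringScheme",
  representation(match = "numeric", mismatch = "numeric",
                 gapOpen = "numeric", gapExtend = "numeric",
                 alphabet = "character", substitutionMatrix = "matrix"))

setValidity("ScoringScheme", function(object) {
  if (!object@alphabet %in% c("nucleotide", "protein"))
    return("alphabet must be 'nucleotide' or 'protein'")
  if (object@match <= object@mismatch) return("match must exceed mismatch")
  if (!(object@gapOpen <= object@gapExtend && object@gapExtend <= 0))
    return("gap penalties must satisfy gapOpen <= gapExtend <= 0")
  TRUE
})

#' Create an alignment scoring scheme
#'
#' Nucleotide defaults (match +2, mismatch -1, gap open -5, gap extend -2)
#' favour gap-free alignments of near-identical hairpins. Protein mode uses
#' BLOSUM62 with gap open -10 / extend -1.
#'
#' @param match,mismatch,gapOpen,gapExtend numeric scores (see
#'   [ScoringScheme-class]).
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param substitutionMatrix optional symbol-pair score matrix; defaults to
#'   BLOSUM62 in protein mode.
#' @return a [ScoringScheme-class].
#' @examples
#' scoringScheme()
#' scoringScheme(alphabet = "protein")
#' @export
scoringScheme <- function(match = 2, mismatch = -1, gapOpen = -5,
                          gapExtend = -2, alphabet = "nucleotide",
                          substitutionMatrix = NULL) {
  if (alphabet == "protein") {
    if (missing(gapOpen)) gapOpen <- -10
    if (missing(gapExtend)) gapExtend <- -1
    if (is.null(substitutionMatrix)) substitutionMatrix <- .blosum62()
  }
  if (is.null(substitutionMatrix))
    substitutionMatrix <- matrix(numeric(0), 0, 0)
  methods::new("ScoringScheme", match = match, mismatch = mismatch,
               gapOpen = gapOpen, gapExtend = gapExtend, alphabet = alphabet,
               substitutionMatrix = substitutionMatrix)
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

setMethod("show", "ScoringScheme", function(object) {
  cat("ScoringScheme (", object@alphabet, "): ", sep = "")
  if (object@alphabet == "nucleotide")
    cat("match ", object@match, ", mismatch ", object@mismatch, ", ", sep = "")
  else
    cat("substitution table ", nrow(object@substitutionMatrix), "x",
        ncol(object@substitutionMatrix), ", ", sep = "")
  cat("gap open ", object@gapOpen, ", extend ", object@gapExtend, "\n", sep = "")
})

# ---- MirnaMsa --------------------------------------------------------------

#' MirnaMsa: a multiple sequence alignment of miRNA precursors
#'
#' Equal-length gapped rows; degapping any row recovers the input sequence.
#'
#' @slot rows character vector of gapped sequences (gap = `-`), named by
#'   source ID.
#' @export
setClass("MirnaMsa", representation(rows = "character"))

setValidity("MirnaMsa", function(object) {
  if (length(object@rows) < 1) return("an MSA needs at least one row")
  if (length(unique(nchar(object@rows))) != 1)
    return("all MSA rows must have equal length")
  if (is.null(names(object@rows)) || anyDuplicated(names(object@rows)) > 0)
    return("MSA rows must have unique names")
  TRUE
})

setMethod("show", "MirnaMsa", function(object) {
  cat("MirnaMsa:", length(object@rows), "rows x",
      nchar(object@rows[1]), "columns\n")
})

#' @rdname MirnaMsa-class
#' @param x a `MirnaMsa`
#' @export
msaRows <- function(x) x@rows

#' @describeIn MirnaMsa-class number of rows
#' @export
setMethod("length", "MirnaMsa", function(x) length(x@rows))
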