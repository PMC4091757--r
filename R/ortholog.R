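# Reciprocal percent identity between human miRNA-target proteins and
# candidate animal orthologs, and the one-to-one, >70% filter.

#' Reciprocal percent identity of two proteins
#'
#' Computes one global full-length alignment (BLOSUM62, affine gaps) and
#' reports identity twice: the number of identical aligned residue pairs
#' as a percentage of each sequence's full length in turn. Terminal gaps
#' therefore penalize identity, matching a full-length (not local)
#' comparison.
#'
#' @param a,b non-empty protein sequences.
#' @param scheme protein [ScoringScheme-class].
#' @return named numeric: `identity_a2b` (over `length(a)`),
#'   `identity_b2a` (over `length(b)`).
#' @examples
#' percentIdentity("MKVLA", "MKVLA")  # 100, 100
#' @export
percentIdentity <- function(a, b, scheme = scoringScheme(alphabet = "protein")) {
  if (scheme@alphabet != "protein")
    stop("percentIdentity requires a protein scoring scheme")
  al <- globalAlign(a, b, scheme)
  ca <- strsplit(al@alignedA, "")[[1]]
  cb <- strsplit(al@alignedB, "")[[1]]
  ident <- sum(ca == cb & ca != "-")
  c(identity_a2b = 100 * ident / nchar(a),
    identity_b2a = 100 * ident / nchar(b))
}

#' Filter candidate ortholog pairs (one-to-one, reciprocal identity > 70)
#'
#' A pair is kept iff it is one-to-one AND both identities are strictly
#' greater than 70 (70 itself is rejected). One-to-one status is
#' recomputed from the input: within a species, the human gene must map to
#' exactly one animal gene and vice versa. Within one species the kept
#' pairs therefore form a partial bijection between human and animal gene
#' symbols.
#'
#' @param pairs data.frame with `human_gene`, `animal_gene`,
#'   `species_code`, `identity_h2a`, `identity_a2h` and optionally
#'   `confidence` (0/1, Ensembl-style; absent values become 0).
#' @return the kept subset, with a recomputed `one_to_one` column.
#' @export
filterOrthologs <- function(pairs) {
  need <- c("human_gene", "animal_gene", "species_code",
            "identity_h2a", "identity_a2h")
  missing_col <- setdiff(need, colnames(pairs))
  if (length(missing_col) > 0)
    stop("pairs is missing column(s): ", paste(missing_col, collapse = ", "))
  if (nrow(pairs) == 0) {
    pairs$one_to_one <- logical(0)
    return(pairs)
  }
  if (!"confidence" %in% colnames(pairs)) pairs$confidence <- 0L
  pairs$confidence[is.na(pairs$confidence)] <- 0L
  hkey <- paste(pairs$species_code, pairs$human_gene)
  akey <- paste(pairs$species_code, pairs$animal_gene)
  pairs$one_to_one <-
    stats::ave(seq_len(nrow(pairs)), hkey, FUN = length) == 1 &
    stats::ave(seq_len(nrow(pairs)), akey, FUN = length) == 1
  keep <- pairs$one_to_one &
          pairs$identity_h2a > 70 & pairs$identity_a2h > 70
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
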