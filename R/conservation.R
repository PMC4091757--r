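# Conservation calls: per-family multiple alignment, pairwise divergence,
# NJ tree, and binning of each human pre-miRNA's best animal counterpart
# at the <=5% (<=0.05) divergence threshold.

.CONS_BINS <- c("zero", "conserved_le_5pct", "diverged_gt_5pct")

#' Classify a divergence proportion into conservation bins
#'
#' A divergence of exactly 0 is `zero`; (0, 0.05] is `conserved_le_5pct`;
#' above 0.05 is `diverged_gt_5pct`. "Highly conserved" covers the first
#' two bins, i.e. the 0.05 boundary itself is highly conserved.
#'
#' @param divergence numeric vector in \[0, 1\].
#' @return factor with levels `zero`, `conserved_le_5pct`,
#'   `diverged_gt_5pct`.
#' @examples
#' classifyConservation(c(0, 0.05, 0.051))
#' @export
classifyConservation <- function(divergence) {
  if (any(is.na(divergence)) || any(divergence < 0) || any(divergence > 1))
    stop("divergence must lie in [0, 1]")
  bin <- ifelse(divergence == 0, "zero",
         ifelse(divergence <= 0.05, "conserved_le_5pct", "diverged_gt_5pct"))
  factor(bin, levels = .CONS_BINS)
}

#' Is a conservation bin highly conserved?
#' @param bin factor/character of bins from [classifyConservation()].
#' @return logical vector.
#' @export
isHighlyConserved <- function(bin) as.character(bin) != "diverged_gt_5pct"

#' Per-family conservation profile of human pre-miRNAs in animals
#'
#' For each family with at least two members, aligns the members with
#' [progressiveMsa()], computes pairwise p-distances and the NJ tree, and
#' for every (human pre-miRNA, species) pair with at least one candidate
#' reports the minimum divergence to that species' family members (the
#' most conserved counterpart) together with its conservation bin.
#' Families with fewer than two members present, and pre-miRNAs with no
#' family assignment, are skipped with a warning.
#'
#' @param humanPre,animalPre precursor [MirnaSet-class] objects.
#' @param families data.frame with `family_id`, `pre_id`; every pre-miRNA
#'   must be assigned to exactly one family.
#' @param scheme nucleotide [ScoringScheme-class].
#' @return list with `calls` (data.frame: `human_pre`, `species_code`,
#'   `best_animal_pre`, `divergence`, `bin`), `binCounts` (species x bin
#'   table over calls) and `families` (per-family list of `msa`, `dist`,
#'   `tree`).
#' @export
conservationProfile <- function(humanPre, animalPre, families,
                                scheme = scoringScheme()) {
  stopifnot(methods::is(humanPre, "MirnaSet"),
            methods::is(animalPre, "MirnaSet"))
  if (humanPre@kind != "precursor" || animalPre@kind != "precursor")
    stop("inputs must be precursor MirnaSets")
  if (anyDuplicated(families$pre_id) > 0)
    stop("a pre-miRNA is assigned to more than one family")
  allIDs <- c(mirnaID(humanPre), mirnaID(animalPre))
  allSeq <- c(sequences(humanPre), sequences(animalPre))
  allSp <- c(speciesCode(humanPre), speciesCode(animalPre))
  names(allSp) <- allIDs
  unassigned <- setdiff(allIDs, families$pre_id)
  if (length(unassigned) > 0)
    warning(length(unassigned), " pre-miRNA(s) without family assignment skipped")

  callRows <- list()
  famOut <- list()
  for (fam in unique(families$family_id)) {
    members <- intersect(families$pre_id[families$family_id == fam], allIDs)
    if (length(members) < 2) {
      warning("family '", fam, "' has fewer than 2 members present; skipped")
      next
    }
    msa <- progressiveMsa(allSeq[members], scheme)
    D <- msaDistanceMatrix(msa)
    tree <- njTree(D)
    famOut[[fam]] <- list(msa = msa, dist = D, tree = tree)
    hum <- members[allSp[members] == "hsa"]
    for (h in hum) {
      for (sp in unique(allSp[members])) {
        if (sp == "hsa") next
        cand <- members[allSp[members] == sp]
        if (length(cand) == 0) next
        dmin <- min(D[h, cand])
        bestidx <- cand[which(D[h, cand] == dmin)[1]]
        callRows[[length(callRows) + 1L]] <- data.frame(
          family_id = fam, human_pre = h, species_code = sp,
          best_animal_pre = bestidx, divergence = dmin,
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(callRows) > 0) do.call(rbind, callRows)
           else data.frame(family_id = character(0), human_pre = character(0),
                           species_code = character(0),
                           best_animal_pre = character(0),
                           divergence = numeric(0), stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  calls$bin <- classifyConservation(calls$divergence)
  binCounts <- table(species = calls$species_code, bin = calls$bin)
  list(calls = calls, binCounts = binCounts, families = famOut)
}
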