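# Global pairwise alignment (affine-gap Needleman-Wunsch, Gotoh recursion
# in compiled code), p-distances, UPGMA guide trees and progressive
# profile-based multiple alignment of pre-miRNA families. Everything here
# is fully deterministic for fixed inputs and scoring scheme.

#' PairAlignment: a global pairwise alignment
#'
#' @slot alignedA,alignedB equal-length gapped strings; degapping recovers
#'   the inputs; no column is gap-gap.
#' @slot score alignment score under the scheme used.
#' @export
setClass("PairAlignment",
  representation(alignedA = "character", alignedB = "character",
                 score = "numeric"))

setValidity("PairAlignment", function(object) {
  if (nchar(object@alignedA) != nchar(object@alignedB))
    return("aligned strings must have equal length")
  a <- strsplit(object@alignedA, "")[[1]]
  b <- strsplit(object@alignedB, "")[[1]]
  if (any(a == "-" & b == "-")) return("gap-gap column")
  TRUE
})

setMethod("show", "PairAlignment", function(object) {
  cat("PairAlignment (score ", object@score, ")\n  ",
      object@alignedA, "\n  ", object@alignedB, "\n", sep = "")
})

#' @rdname PairAlignment-class
#' @param x a `PairAlignment`
#' @export
alignedSeqs <- function(x) c(x@alignedA, x@alignedB)

#' @rdname PairAlignment-class
#' @export
alignmentScore <- function(x) x@score

.validProteinChars <- function() setdiff(rownames(.blosum62()), "*")

.checkAlphabet <- function(seq, scheme) {
  if (scheme@alphabet == "nucleotide") {
    normalizeSequence(seq)
  } else {
    up <- toupper(seq)
    ok <- .validProteinChars()
    ch <- strsplit(up, "")[[1]]
    if (any(!ch %in% ok))
      stop("non-amino-acid symbol in protein sequence: ",
           ch[which(!ch %in% ok)[1]])
    up
  }
}

.pairScoreMatrix <- function(a, b, scheme) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  if (scheme@alphabet == "protein" || nrow(scheme@substitutionMatrix) > 0) {
    sm <- if (nrow(scheme@substitutionMatrix) > 0) scheme@substitutionMatrix
          else .blosum62()
    matrix(sm[av, bv], nrow = length(av))
  } else {
    ifelse(outer(av, bv, "=="), scheme@match, scheme@mismatch)
  }
}

.alignFromIdx <- function(av, bv, ai, bi) {
  ca <- ifelse(ai == 0, "-", av[pmax(ai, 1)])
  cb <- ifelse(bi == 0, "-", bv[pmax(bi, 1)])
  list(a = paste(ca, collapse = ""), b = paste(cb, collapse = ""))
}

#' Optimal global alignment of two sequences
#'
#' End-to-end (Needleman-Wunsch) alignment with affine gap costs: a gap
#' run of length k costs `gapOpen + (k - 1) * gapExtend`. Traceback ties
#' prefer the diagonal, then the up (gap in `b`), then the left move, so
#' the reported alignment is deterministic.
#'
#' @param a,b non-empty sequences in the scheme's alphabet. Nucleotide
#'   input is normalized (uppercase, T to U) before alignment.
#' @param scheme a [ScoringScheme-class].
#' @return a [PairAlignment-class].
#' @examples
#' globalAlign("ACGU", "ACGU")
#' @export
globalAlign <- function(a, b, scheme = scoringScheme()) {
  stopifnot(methods::is(scheme, "ScoringScheme"))
  if (!is.character(a) || !is.character(b) || length(a) != 1 ||
      length(b) != 1 || nchar(a) == 0 || nchar(b) == 0)
    stop("'a' and 'b' must be non-empty sequences")
  a <- .checkAlphabet(a, scheme)
  b <- .checkAlphabet(b, scheme)
  S <- .pairScoreMatrix(a, b, scheme)
  res <- gotoh_align(S, scheme@gapOpen, scheme@gapExtend)
  al <- .alignFromIdx(strsplit(a, "")[[1]], strsplit(b, "")[[1]],
                      res$ai, res$bi)
  methods::new("PairAlignment", alignedA = al$a, alignedB = al$b,
               score = res$score)
}

#' Pairwise divergence proportion (p-distance)
#'
#' The fraction of comparable columns at which two aligned rows differ.
#' A column is comparable when both rows carry a non-gap, non-N symbol.
#' Zero comparable columns are an error, never 0 or 1.
#'
#' @param alignedA,alignedB equal-length gapped strings.
#' @return divergence proportion in \[0, 1\].
#' @examples
#' pDistance("ACGU", "ACGA")   # 0.25
#' pDistance("AC-GU", "ACAGU") # 0
#' @export
pDistance <- function(alignedA, alignedB) {
  if (nchar(alignedA) != nchar(alignedB))
    stop("aligned strings must have equal length")
  a <- strsplit(alignedA, "")[[1]]
  b <- strsplit(alignedB, "")[[1]]
  comparable <- a != "-" & b != "-" & a != "N" & b != "N"
  if (!any(comparable))
    stop("no comparable columns between the two rows")
  sum(a[comparable] != b[comparable]) / sum(comparable)
}

#' UPGMA guide tree for progressive alignment
#'
#' Average-linkage agglomerative clustering of a distance matrix. Ties are
#' broken by the lexicographically smallest pair of taxon indices (each
#' cluster is represented by its smallest original leaf index), so the
#' merge order is deterministic; with all-equal distances the result is a
#' left-to-right ladder.
#'
#' @param d symmetric distance matrix over >= 2 taxa.
#' @return a nested list: a leaf is `list(leaf = i)`, an internal node
#'   `list(left = , right = , height = )`.
#' @export
buildGuideTree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 taxa")
  nodes <- lapply(seq_len(n), function(i) list(leaf = i))
  reps <- seq_len(n)          # smallest original leaf index per cluster
  sizes <- rep(1L, n)
  D <- d
  alive <- rep(TRUE, n)
  while (sum(alive) > 1) {
    act <- which(alive)
    act <- act[order(reps[act])]
    best <- Inf; bi <- bj <- NA_integer_
    for (x in seq_along(act)) for (y in seq_len(length(act) - x)) {
      i <- act[x]; j <- act[x + y]
      if (D[i, j] < best) { best <- D[i, j]; bi <- i; bj <- j }
    }
    newnode <- list(left = nodes[[bi]], right = nodes[[bj]], height = best / 2)
    # weighted (size-proportional) average linkage
    for (k in which(alive)) {
      if (k == bi || k == bj) next
      D[bi, k] <- D[k, bi] <-
        (sizes[bi] * D[bi, k] + sizes[bj] * D[bj, k]) / (sizes[bi] + sizes[bj])
    }
    sizes[bi] <- sizes[bi] + sizes[bj]
    reps[bi] <- min(reps[bi], reps[bj])
    nodes[[bi]] <- newnode
    alive[bj] <- FALSE
  }
  nodes[[which(alive)]]
}

# column frequency profile over A, C, G, U and gap (N folded into gap:
# an N cannot certify identity and is excluded from distances anyway)
.profileOf <- function(charmat) {
  L <- ncol(charmat)
  p <- matrix(0, nrow = 5, ncol = L,
              dimnames = list(c("A", "C", "G", "U", "-"), NULL))
  for (s in c("A", "C", "G", "U"))
    p[s, ] <- colSums(charmat == s)
  p["-", ] <- nrow(charmat) - colSums(p[1:4, , drop = FALSE])
  p / nrow(charmat)
}

.profileScoreMatrix <- function(pa, pb, scheme) {
  K <- matrix(scheme@mismatch, 4, 4)
  diag(K) <- scheme@match
  S <- t(pa[1:4, , drop = FALSE]) %*% K %*% pb[1:4, , drop = FALSE]
  ga <- pa[5, ]; gb <- pb[5, ]
  S + (outer(ga, 1 - gb) + outer(1 - ga, gb)) * scheme@gapExtend
}

.mergeByIdx <- function(charmat, idx) {
  out <- matrix("-", nrow = nrow(charmat), ncol = length(idx))
  nz <- idx > 0
  out[, nz] <- charmat[, idx[nz], drop = FALSE]
  rownames(out) <- rownames(charmat)
  out
}

#' Progressive multiple alignment of a sequence family
#'
#' Pairwise p-distances from [globalAlign()] feed a UPGMA guide tree
#' ([buildGuideTree()]); profiles are then merged leaf-to-root with
#' sum-of-pairs profile scoring under the same affine gap costs. Gaps
#' introduced at a merge are never removed ("once a gap, always a gap").
#'
#' @param seqs named character vector of >= 2 sequences.
#' @param scheme a nucleotide [ScoringScheme-class].
#' @return a [MirnaMsa-class]; row order equals input order.
#' @export
progressiveMsa <- function(seqs, scheme = scoringScheme()) {
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- vapply(seqs, normalizeSequence, character(1))
  n <- length(seqs)
  if (n == 2) {
    al <- globalAlign(seqs[1], seqs[2], scheme)
    rows <- stats::setNames(alignedSeqs(al), names(seqs))
    return(methods::new("MirnaMsa", rows = rows))
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- globalAlign(seqs[i], seqs[j], scheme)
    D[i, j] <- D[j, i] <- pDistance(al@alignedA, al@alignedB)
  }
  guide <- buildGuideTree(D)
  alignNode <- function(node) {
    if (!is.null(node$leaf)) {
      m <- matrix(strsplit(seqs[node$leaf], "")[[1]], nrow = 1)
      rownames(m) <- names(seqs)[node$leaf]
      return(m)
    }
    A <- alignNode(node$left)
    B <- alignNode(node$right)
    S <- .profileScoreMatrix(.profileOf(A), .profileOf(B), scheme)
    res <- gotoh_align(S, scheme@gapOpen, scheme@gapExtend)
    rbind(.mergeByIdx(A, res$ai), .mergeByIdx(B, res$bi))
  }
  m <- alignNode(guide)
  m <- m[names(seqs), , drop = FALSE]
  rows <- stats::setNames(apply(m, 1, paste, collapse = ""), rownames(m))
  methods::new("MirnaMsa", rows = rows)
}

#' Pairwise divergence matrix from a multiple alignment
#'
#' @param m a [MirnaMsa-class] with >= 2 rows.
#' @return symmetric matrix of p-distances with zero diagonal, dimnames =
#'   row IDs.
#' @export
msaDistanceMatrix <- function(m) {
  stopifnot(methods::is(m, "MirnaMsa"))
  rows <- msaRows(m)
  if (length(rows) < 2) stop("need at least 2 rows")
  n <- length(rows)
  D <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- pDistance(rows[i], rows[j])
  D
}
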