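# Independent oracles used across the suite.

# ---- exhaustive global-alignment oracle ------------------------------------
# Enumerates every monotone alignment path (diag/up/left move sequences) of
# two short sequences and scores each under the affine model: a gap run of
# length k costs gapOpen + (k-1)*gapExtend; consecutive up- and left-runs
# are distinct runs. Path sets depend only on the two lengths, so they are
# enumerated once and cached; per-sequence scoring is vectorized.

.pathCache <- new.env(parent = emptyenv())

.enumPaths <- function(la, lb) {
  key <- paste(la, lb)
  if (!is.null(.pathCache[[key]])) return(.pathCache[[key]])
  paths <- list()
  walk <- function(i, j, moves) {
    if (i == la && j == lb) {
      paths[[length(paths) + 1L]] <<- moves
      return(invisible())
    }
    if (i < la && j < lb) walk(i + 1, j + 1, c(moves, 1L))
    if (i < la) walk(i + 1, j, c(moves, 2L))
    if (j < lb) walk(i, j + 1, c(moves, 3L))
  }
  walk(0L, 0L, integer(0))
  maxlen <- la + lb
  P <- length(paths)
  AI <- matrix(0L, P, maxlen)
  BI <- matrix(0L, P, maxlen)
  nruns <- integer(P)
  ngap <- integer(P)
  for (p in seq_len(P)) {
    mv <- paths[[p]]
    ai <- cumsum(mv != 3L) * (mv != 3L)
    bi <- cumsum(mv != 2L) * (mv != 2L)
    AI[p, seq_along(mv)] <- as.integer(ai)
    BI[p, seq_along(mv)] <- as.integer(bi)
    r <- rle(mv)
    nruns[p] <- sum(r$values != 1L)
    ngap[p] <- sum(mv != 1L)
  }
  out <- list(AI = AI, BI = BI, nruns = nruns, ngap = ngap)
  .pathCache[[key]] <- out
  out
}

enumAlignScore <- function(a, b, match = 2, mismatch = -1,
                           gapOpen = -5, gapExtend = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  pp <- .enumPaths(length(av), length(bv))
  ae <- matrix(c("", av)[pp$AI + 1L], nrow = nrow(pp$AI))
  be <- matrix(c("", bv)[pp$BI + 1L], nrow = nrow(pp$BI))
  diagcol <- pp$AI > 0L & pp$BI > 0L
  nmatch <- rowSums(diagcol & ae == be)
  ndiag <- rowSums(diagcol)
  scores <- match * nmatch + mismatch * (ndiag - nmatch) +
    gapOpen * pp$nruns + gapExtend * (pp$ngap - pp$nruns)
  max(scores)
}

# score an explicit gapped alignment under the same affine model
scoreAlignment <- function(alnA, alnB, match = 2, mismatch = -1,
                           gapOpen = -5, gapExtend = -2) {
  a <- strsplit(alnA, "")[[1]]
  b <- strsplit(alnB, "")[[1]]
  stopifnot(length(a) == length(b), !any(a == "-" & b == "-"))
  gap <- a == "-" | b == "-"
  sc <- sum(ifelse(!gap, ifelse(a == b, match, mismatch), 0))
  if (any(gap)) {
    state <- ifelse(a == "-", "A", ifelse(b == "-", "B", "."))
    r <- rle(state)
    runs <- sum(r$values != ".")
    sc <- sc + gapOpen * runs + gapExtend * (sum(gap) - runs)
  }
  sc
}

# ---- brute-force exact-homolog oracle --------------------------------------
# O(n*m) all-pairs string comparison, independent of the package's lookup.
bruteForceMatches <- function(human, animals) {
  hseq <- sequences(human); hN <- mirnaInfo(human)$has_n
  aseq <- sequences(animals); aN <- mirnaInfo(animals)$has_n
  out <- list()
  for (i in seq_along(hseq)) {
    if (hN[i]) next
    for (j in seq_along(aseq)) {
      if (aN[j]) next
      if (hseq[[i]] == aseq[[j]])
        out[[length(out) + 1L]] <- c(names(hseq)[i], names(aseq)[j])
    }
  }
  if (length(out) == 0) return(character(0))
  sort(vapply(out, paste, character(1), collapse = " "))
}

# random RNA string
randRNA <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                             collapse = "")
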