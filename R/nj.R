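# Saitou-Nei neighbor joining over a divergence matrix. Returns an ape
# "phylo" tree; on an additive matrix the leaf-to-leaf path lengths
# reproduce the input distances exactly.

#' Neighbor-Joining tree from a distance matrix
#'
#' At each step the pair minimizing
#' `Q(i, j) = (n - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k)` is joined;
#' branch lengths follow the standard two-point formulas. A negative
#' estimated branch length is clamped to zero and its deficit moved to the
#' sister branch, so the joined pair's total length is preserved. Ties are
#' broken by the lexicographically smallest pair of original taxon
#' indices, making the result deterministic. With two taxa the distance is
#' split evenly across the single internal node, so the leaf-to-leaf path
#' length equals the input distance.
#'
#' @param d symmetric matrix of non-negative distances with zero diagonal;
#'   dimnames give the taxa labels.
#' @param labels optional taxa labels overriding `rownames(d)`.
#' @return an unrooted [ape::phylo] tree with branch lengths in
#'   substitutions per site.
#' @examples
#' d <- matrix(c(0, .1, .1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' njTree(d)
#' @export
njTree <- function(d, labels = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 taxa")
  if (ncol(d) != n) stop("distance matrix must be square")
  if (any(d < 0)) stop("negative input distances")
  if (max(abs(d - t(d))) > 1e-9) stop("non-symmetric distance matrix")
  if (is.null(labels)) labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (anyDuplicated(labels) > 0) stop("duplicate taxa labels")

  fmt <- function(x) sprintf("%.12g", max(x, 0))
  if (n == 2) {
    txt <- sprintf("(%s:%s,%s:%s);", labels[1], fmt(d[1, 2] / 2),
                   labels[2], fmt(d[1, 2] / 2))
    return(ape::read.tree(text = txt))
  }

  nwk <- labels
  reps <- seq_len(n)   # smallest original taxon index per cluster
  D <- d
  alive <- rep(TRUE, n)
  m <- n
  while (m > 3) {
    act <- which(alive)
    act <- act[order(reps[act])]
    r <- rowSums(D[act, act, drop = FALSE])
    names(r) <- as.character(act)
    best <- Inf; bi <- bj <- NA_integer_
    for (x in seq_along(act)) for (y in seq_len(length(act) - x)) {
      i <- act[x]; j <- act[x + y]
      q <- (m - 2) * D[i, j] - r[as.character(i)] - r[as.character(j)]
      if (q < best) { best <- q; bi <- i; bj <- j }
    }
    dij <- D[bi, bj]
    li <- dij / 2 + (r[as.character(bi)] - r[as.character(bj)]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(li + lj, 0); lj <- 0 }
    newick <- sprintf("(%s:%s,%s:%s)", nwk[bi], fmt(li), nwk[bj], fmt(lj))
    for (k in which(alive)) {
      if (k == bi || k == bj) next
      D[bi, k] <- D[k, bi] <- (D[bi, k] + D[bj, k] - dij) / 2
    }
    nwk[bi] <- newick
    reps[bi] <- min(reps[bi], reps[bj])
    alive[bj] <- FALSE
    m <- m - 1
  }
  act <- which(alive)
  act <- act[order(reps[act])]
  a <- act[1]; b <- act[2]; c3 <- act[3]
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  lc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 nwk[a], fmt(la), nwk[b], fmt(lb), nwk[c3], fmt(lc))
  ape::read.tree(text = txt)
}
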