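## Interaction-conservation phylogeny: pairwise similarity of remapped
## edge sets (SS), distance D, and an agglomerative dendrogram in Newick.

#' Interaction-conservation similarity between two remapped networks
#'
#' In the default binary mode an edge is conserved when it is present in
#' both remapped networks (virtual-node pairs can never qualify), and
#' `SS = conserved / denominator` with the denominator taken over the
#' union of the two edge sets (Jaccard), or alternatively the smaller or
#' the mean of the two edge counts. In energy mode (`tol` given together
#' with the two remapped energy matrices) an edge is conserved when both
#' energies are at or below the cutoff and differ by at most `tol`.
#'
#' @param remA,remB [RemappedPEN-class] objects sharing L and cutoff.
#' @param denominator `"union"` (default), `"min"` or `"mean"`.
#' @param tol optional energy tolerance (kJ/mol) enabling energy mode.
#' @param energyA,energyB L x L remapped energy matrices from
#'   [remapEnergyMatrix()]; required when `tol` is given.
#' @return list with `S` (logical L x L conserved-edge matrix), `SS`
#'   (scalar in `[0, 1]`) and the member ids. Two empty edge sets give
#'   `SS = 1` with a warning.
#' @export
pairSimilarity <- function(remA, remB,
                           denominator = c("union", "min", "mean"),
                           tol = NULL, energyA = NULL, energyB = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(is(remA, "RemappedPEN"), is(remB, "RemappedPEN"))
  L <- alignedLength(remA)
  if (alignedLength(remB) != L)
    stop("remapped networks differ in alignment length")
  if (cutoffE(remA) != cutoffE(remB))
    stop("remapped networks differ in cutoff e")
  e <- cutoffE(remA)

  if (is.null(tol)) {
    edgeA <- remA@adjacency
    edgeB <- remB@adjacency
    S <- edgeA & edgeB
  } else {
    if (is.null(energyA) || is.null(energyB))
      stop("energy mode needs energyA and energyB (see remapEnergyMatrix)")
    if (any(dim(energyA) != L) || any(dim(energyB) != L))
      stop("energy matrices must be L x L")
    edgeA <- !is.na(energyA) & energyA <= e
    edgeB <- !is.na(energyB) & energyB <= e
    S <- edgeA & edgeB & !is.na(energyA) & !is.na(energyB) &
      (abs(energyA - energyB) <= tol)
  }
  ut <- upper.tri(S)
  nCons <- sum(S[ut])
  nA <- sum(edgeA[ut]); nB <- sum(edgeB[ut])
  denom <- switch(denominator,
                  union = sum((edgeA | edgeB)[ut]),
                  min = min(nA, nB),
                  mean = (nA + nB) / 2)
  ss <- if (denom == 0) {
    warning("both edge sets are empty; SS defined as 1")
    1
  } else nCons / denom
  list(memberA = remA@memberId, memberB = remB@memberId, S = S, SS = ss)
}

#' Pairwise similarity matrix over a family
#'
#' @param remapped list of [RemappedPEN-class] over a shared alignment.
#' @param ... passed to [pairSimilarity()].
#' @return symmetric SS matrix with unit diagonal, member ids as dimnames.
#' @export
familySimilarity <- function(remapped, ...) {
  ids <- vapply(remapped, function(r) r@memberId, "")
  n <- length(ids)
  if (n < 2L) stop("need at least two members")
  if (anyDuplicated(ids)) stop("duplicate member ids")
  ss <- diag(1, n)
  dimnames(ss) <- list(ids, ids)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- suppressWarnings(pairSimilarity(remapped[[i]], remapped[[j]], ...))$SS
    ss[i, j] <- v
    ss[j, i] <- v
  }
  ss
}

#' Distance matrix from interaction similarity
#'
#' `D = 1 - SS` by default; `"neglog"` uses `-log(SS)` with `SS = 0`
#' mapped to the largest finite distance observed plus one.
#'
#' @param ss symmetric similarity matrix with unit diagonal.
#' @param method `"complement"` (default) or `"neglog"`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
distanceFromSimilarity <- function(ss, method = c("complement", "neglog")) {
  method <- match.arg(method)
  if (max(abs(ss - t(ss))) > 1e-9) stop("similarity matrix must be symmetric")
  if (method == "complement") {
    d <- 1 - ss
  } else {
    d <- -log(ss)
    if (any(is.infinite(d))) {
      cap <- max(d[is.finite(d)], 0) + 1
      d[is.infinite(d)] <- cap
    }
  }
  diag(d) <- 0
  d
}

#' Hierarchical clustering of a distance matrix into a cladogram
#'
#' Agglomerative clustering (default average linkage, i.e. UPGMA) of the
#' member distance matrix. Members are ordered lexicographically before
#' clustering so that the result is invariant to input order.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal and
#'   member ids as dimnames.
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @param ss optional similarity matrix stored alongside.
#' @return a [PENPhylogeny-class].
#' @export
buildTree <- function(d, linkage = c("average", "single", "complete"),
                      ss = NULL) {
  linkage <- match.arg(linkage)
  if (is.null(rownames(d))) stop("distance matrix needs member ids as dimnames")
  if (nrow(d) < 2L) stop("need at least two members")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  if (any(d < -1e-12)) stop("distances must be non-negative")
  ord <- order(rownames(d), method = "radix")
  d <- d[ord, ord]
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  tree <- ape::as.phylo(hc)
  if (is.null(ss)) ss <- 1 - d else ss <- ss[rownames(d), rownames(d)]
  new("PENPhylogeny", memberIds = rownames(d), SS = ss, D = d,
      tree = tree, clustering = hc)
}

#' Full interaction-conservation phylogeny of a family
#'
#' Computes all pairwise SS scores, converts them to distances and builds
#' the cladogram in one call.
#'
#' @param remapped list of [RemappedPEN-class] over a shared alignment.
#' @param denominator,tol passed to [pairSimilarity()].
#' @param distMethod passed to [distanceFromSimilarity()].
#' @param linkage passed to [buildTree()].
#' @return a [PENPhylogeny-class].
#' @export
networkPhylogeny <- function(remapped, denominator = "union", tol = NULL,
                             distMethod = "complement",
                             linkage = "average") {
  ss <- familySimilarity(remapped, denominator = denominator, tol = tol)
  d <- distanceFromSimilarity(ss, method = distMethod)
  buildTree(d, linkage = linkage, ss = ss)
}

#' Newick serialization of a phylogeny
#'
#' @param x a [PENPhylogeny-class].
#' @return single Newick string with branch lengths.
#' @export
newickString <- function(x) {
  stopifnot(is(x, "PENPhylogeny"))
  ape::write.tree(x@tree)
}

#' Write the Newick tree of a phylogeny to file
#'
#' @param x a [PENPhylogeny-class].
#' @param path output file.
#' @export
writeNewick <- function(x, path) {
  stopifnot(is(x, "PENPhylogeny"))
  ape::write.tree(x@tree, file = path)
  invisible(path)
}

#' Split a phylogeny into k groups
#'
#' Cuts the underlying agglomerative clustering into `k` groups; used for
#' checking whether planted clades are recovered as sister groups.
#'
#' @param x a [PENPhylogeny-class].
#' @param k number of groups.
#' @return named integer vector of group memberships.
#' @export
cutPhylogeny <- function(x, k) {
  stopifnot(is(x, "PENPhylogeny"))
  stats::cutree(x@clustering, k = k)
}
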