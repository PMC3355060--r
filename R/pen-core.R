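## Thresholded (unweighted) energy networks and their analytics:
## connected clusters, hubs, largest-cluster transition profiles and
## secondary-structure interface classification.

#' Threshold an energy matrix into an unweighted network
#'
#' Edge (i, j) is present iff the matrix holds an energy for the pair and
#' that energy is at or below the cutoff `e`. Favourable energies are
#' negative, so lower cutoffs keep only the strongest interactions; edge
#' sets are nested as `e` increases.
#'
#' @param em an [EnergyMatrix-class].
#' @param e energy cutoff in kJ/mol.
#' @return a [ThresholdedNetwork-class].
#' @export
thresholdNetwork <- function(em, e) {
  stopifnot(is(em, "EnergyMatrix"))
  if (length(e) != 1L || !is.finite(e)) stop("cutoff e must be finite")
  hit <- which(upper.tri(em@values) & !is.na(em@values) & em@values <= e,
               arr.ind = TRUE)
  edges <- cbind(em@residueIds[hit[, 1]], em@residueIds[hit[, 2]])
  if (nrow(edges) == 0L) edges <- matrix(character(0), ncol = 2)
  colnames(edges) <- c("res_i", "res_j")
  new("ThresholdedNetwork", nodes = em@residueIds, edges = edges,
      cutoffE = e, mode = em@mode)
}

# components of a network as a list of node-name vectors
.components <- function(net) {
  g <- asIgraph(net)
  comp <- igraph::components(g)
  split(names(comp$membership), comp$membership)
}

#' Connected clusters of a thresholded network
#'
#' Maximal connected components with at least `minSize` nodes; isolated
#' pairwise interactions (size-2 components) are not clusters under the
#' default. Clusters are ordered by decreasing size, ties broken by the
#' lexicographically smallest member; members are sorted lexicographically.
#'
#' @param net a [ThresholdedNetwork-class].
#' @param minSize minimum component size retained (default 3).
#' @return a [ClusterSet-class]. `largestClusterSize` reports the largest
#'   edge-bearing component of any size (0 for an edgeless network).
#' @export
connectedClusters <- function(net, minSize = 3L) {
  stopifnot(is(net, "ThresholdedNetwork"), minSize >= 1L)
  comps <- .components(net)
  sizes <- lengths(comps)
  # components of size 1 are isolated nodes, never edge-bearing
  lc <- if (any(sizes >= 2L)) max(sizes[sizes >= 2L]) else 0L
  keep <- comps[sizes >= minSize & sizes >= 2L]
  keep <- lapply(keep, function(x) sort(x, method = "radix"))
  if (length(keep)) {
    ord <- order(-lengths(keep), vapply(keep, `[`, "", 1L), method = "radix")
    keep <- keep[ord]
  }
  new("ClusterSet", clusters = unname(keep),
      largestClusterSize = as.integer(lc), minSize = as.integer(minSize))
}

#' Hub nodes of a thresholded network
#'
#' Hubs are the nodes whose degree (number of incident edges) reaches a
#' threshold. Family-level hubs are fixed at degree >= 3; for a single
#' protein the threshold is a free parameter.
#'
#' @param net a [ThresholdedNetwork-class].
#' @param degreeMin minimum degree (>= 1).
#' @return character vector of hub node ids, in network node order.
#' @export
hubs <- function(net, degreeMin = 4L) {
  stopifnot(is(net, "ThresholdedNetwork"))
  if (degreeMin < 1L) stop("degreeMin must be >= 1")
  deg <- table(factor(c(net@edges), levels = net@nodes))
  net@nodes[deg >= degreeMin]
}

#' Largest-cluster transition profile
#'
#' For each cutoff in `eGrid`, the size of the largest connected component
#' of PEN_e divided by the number of residues. Components are counted only
#' when they carry at least one edge, so an edgeless network scores 0.
#' Because edge sets are nested in `e`, the profile is non-decreasing; its
#' sigmoidal rise traces the transition from a few strong electrostatic
#' contacts to a network spanning the protein.
#'
#' @param em an [EnergyMatrix-class].
#' @param eGrid numeric vector of cutoffs (kJ/mol), sorted ascending.
#' @return data.frame with columns `e` and `normalized_lc`.
#' @export
lcProfile <- function(em, eGrid) {
  stopifnot(is(em, "EnergyMatrix"))
  if (length(eGrid) == 0L) stop("eGrid must be non-empty")
  if (is.unsorted(eGrid)) stop("eGrid must be sorted ascending")
  n <- length(em@residueIds)
  lc <- vapply(eGrid, function(e)
    largestClusterSize(connectedClusters(thresholdNetwork(em, e), 2L)),
    integer(1))
  data.frame(e = eGrid, normalized_lc = lc / n)
}

#' Mid-transition cutoff of a largest-cluster profile
#'
#' The cutoff at which the normalized largest-cluster size first reaches
#' one half, linearly interpolated between grid points. Descriptive output
#' characterizing the sigmoidal network transition.
#'
#' @param profile data.frame from [lcProfile()].
#' @return the interpolated cutoff (kJ/mol), or `NA` if 0.5 is not reached.
#' @export
lcMidpoint <- function(profile) {
  y <- profile$normalized_lc
  x <- profile$e
  k <- which(y >= 0.5)[1]
  if (is.na(k)) return(NA_real_)
  if (k == 1L || y[k] == 0.5) return(x[k])
  x[k - 1] + (0.5 - y[k - 1]) / (y[k] - y[k - 1]) * (x[k] - x[k - 1])
}

#' Classify network edges by secondary-structure interface
#'
#' Each edge gets exactly one class, with precedence:
#' \describe{
#'   \item{loop}{either endpoint labelled other (`C`).}
#'   \item{ab}{one helix endpoint, one strand endpoint.}
#'   \item{aa}{both endpoints helical.}
#'   \item{bb_long_range / bb_contiguous}{both endpoints in strands;
#'     long-range when the strands are non-neighbouring (strand-index
#'     difference >= 2), contiguous for adjacent strands or the same
#'     strand. With `wrapAround = TRUE` the first and last strands count
#'     as adjacent, as in a closed beta barrel.}
#' }
#' Only the long-range beta-beta edges are free of trivial backbone
#' hydrogen-bond neighbourhood effects, which is why barrel analyses focus
#' on them.
#'
#' @param net a [ThresholdedNetwork-class].
#' @param sse data.frame from [readSSE()] covering every network node.
#' @param wrapAround logical; treat the strand sequence as circular.
#' @return list with `counts` (named integer vector over the five classes)
#'   and `edges` (data.frame res_i, res_j, class).
#' @export
classifyEdges <- function(net, sse, wrapAround = FALSE) {
  stopifnot(is(net, "ThresholdedNetwork"))
  hit <- match(net@nodes, sse$res_id)
  if (anyNA(hit))
    stop("unannotated node(s): ",
         paste(net@nodes[is.na(hit)], collapse = ", "))
  lab <- sse$label[hit]
  names(lab) <- net@nodes
  sidx <- sse$strand_index[hit]
  names(sidx) <- net@nodes
  nStrand <- if (any(lab == "E")) max(sidx[lab == "E"]) else 0L

  classes <- c("bb_long_range", "bb_contiguous", "ab", "aa", "loop")
  e <- net@edges
  cls <- character(nrow(e))
  for (k in seq_len(nrow(e))) {
    a <- e[k, 1]; b <- e[k, 2]
    la <- lab[[a]]; lb <- lab[[b]]
    if (la == "C" || lb == "C") {
      cls[k] <- "loop"
    } else if (la != lb) {
      cls[k] <- "ab"
    } else if (la == "H") {
      cls[k] <- "aa"
    } else {
      d <- abs(sidx[[a]] - sidx[[b]])
      if (wrapAround && nStrand > 2L) d <- min(d, nStrand - d)
      cls[k] <- if (d >= 2L) "bb_long_range" else "bb_contiguous"
    }
  }
  counts <- table(factor(cls, levels = classes))
  list(counts = stats::setNames(as.integer(counts), classes),
       edges = data.frame(res_i = e[, 1], res_j = e[, 2], class = cls,
                          stringsAsFactors = FALSE))
}
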