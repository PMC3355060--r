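# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately avoid the package's own code paths.

# random symmetric energy matrix over n residues in one chain, energies
# uniform in [lo, hi], self/sequential pairs excluded
randomEnergyMatrix <- function(n, lo = -30, hi = 0) {
  v <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (j - i >= 2) {
      e <- runif(1, lo, hi)
      v[i, j] <- e
      v[j, i] <- e
    }
  }
  ids <- sprintf("r%03d", seq_len(n))
  dimnames(v) <- list(ids, ids)
  new("EnergyMatrix", values = v, residueIds = ids, chain = rep("A", n),
      mode = "full", nFrames = 1L)
}

# breadth-first connected components from an edge list; returns a list of
# sorted character vectors covering every node incident to an edge, plus
# isolated nodes as singletons
bfsComponents <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- character(0)
  comps <- list()
  for (start in nodes) {
    if (start %in% seen) next
    queue <- start
    comp <- character(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# degree of every node by explicit edge counting
bruteDegree <- function(nodes, edges) {
  vapply(nodes, function(v) sum(edges == v), integer(1))
}

# random ThresholdedNetwork over n nodes with each possible edge present
# with probability p
randomNetwork <- function(n, p = 0.15) {
  ids <- sprintf("n%03d", seq_len(n))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p
  edges <- pairs[keep, , drop = FALSE]
  if (nrow(edges) == 0L) edges <- matrix(character(0), ncol = 2)
  colnames(edges) <- c("res_i", "res_j")
  new("ThresholdedNetwork", nodes = ids, edges = edges,
      cutoffE = -10, mode = "full")
}

# build a ThresholdedNetwork directly from node ids and an edge matrix
netFromEdges <- function(nodes, edges, e = -10) {
  edges <- matrix(as.character(edges), ncol = 2)
  colnames(edges) <- c("res_i", "res_j")
  new("ThresholdedNetwork", nodes = nodes, edges = edges,
      cutoffE = e, mode = "full")
}

# single-chain energy matrix over n residues with the named residue pairs
# set to eEdge and every other admissible pair set to bg
memberMatrix <- function(n, edges, eEdge = -20, bg = -1) {
  v <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (abs(i - j) >= 2) v[i, j] <- bg
  if (length(edges)) {
    edges <- matrix(edges, ncol = 2)
    for (k in seq_len(nrow(edges))) {
      v[edges[k, 1], edges[k, 2]] <- eEdge
      v[edges[k, 2], edges[k, 1]] <- eEdge
    }
  }
  ids <- sprintf("r%03d", seq_len(n))
  dimnames(v) <- list(ids, ids)
  new("EnergyMatrix", values = v, residueIds = ids, chain = rep("A", n),
      mode = "full", nFrames = 1L)
}

# write a minimal (synthetic) multi-MODEL PDB file: one single-atom
# residue per row of `coords[[frame]]`, chain/resno taken from `resdef`
writeToyPDB <- function(path, resdef, coords) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(coords)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- coords[[f]]
    for (i in seq_len(nrow(resdef))) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        i, resdef$atom[i], resdef$res[i], resdef$chain[i], resdef$resno[i],
        xyz[i, 1], xyz[i, 2], xyz[i, 3]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
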