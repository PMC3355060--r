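## Seeded synthetic fixtures: toy structures whose pair energies are
## hand-computable, and families of energy matrices + MSSA with planted
## conserved edges, gap patterns and optional clade structure.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Toy parameterized structures with analytic energies
#'
#' `"two_particles"` places one single-atom residue on each of two chains
#' a distance `r` apart, so the residue pair energy equals one Coulomb
#' plus one Lennard-Jones term exactly. `"mini_chain"` places `nResidues`
#' single-atom residues on a line within one chain, exercising the
#' sequential-neighbour exclusion (a 4-residue chain yields exactly the
#' three entries (1,3), (1,4), (2,4)). Passing a vector for `r` (or
#' `spacing`) produces one ensemble frame per value, so frame averaging
#' is hand-checkable too.
#'
#' @param kind `"two_particles"` or `"mini_chain"`.
#' @param r separation(s) in nm for `two_particles`.
#' @param charges partial charges (e): length 2 for `two_particles`,
#'   length `nResidues` (or scalar) for `mini_chain`.
#' @param sigma,epsilon LJ parameters shared by all atoms (nm, kJ/mol).
#' @param nResidues chain length for `mini_chain` (>= 4).
#' @param spacing inter-residue spacing(s) in nm for `mini_chain`.
#' @return list with `ensemble` (a [StructureEnsemble-class]) and
#'   `params` (force-field data.frame ready for [buildEnergyMatrix()]).
#' @export
makeToyStructure <- function(kind = c("two_particles", "mini_chain"),
                             r = 0.5, charges = c(0, 0),
                             sigma = 0.33, epsilon = 0.5,
                             nResidues = 4L, spacing = 0.5) {
  kind <- match.arg(kind)
  if (sigma <= 0 || epsilon < 0) stop("invalid LJ parameters")
  if (kind == "two_particles") {
    if (any(r <= 0)) stop("invalid geometry: separation must be positive")
    if (length(charges) != 2L) stop("two_particles needs two charges")
    atoms <- data.frame(atomName = "X", resName = c("TPA", "TPB"),
                        resIndex = 1:2, chain = c("A", "B"),
                        stringsAsFactors = FALSE)
    frames <- lapply(r, function(ri)
      rbind(c(0, 0, 0), c(10 * ri, 0, 0)))  # nm -> Angstrom
    ens <- new("StructureEnsemble", atoms = atoms, frames = frames,
               residueIds = c("A:1", "B:1"), residueChain = c("A", "B"))
    params <- data.frame(res_name = c("TPA", "TPB"), atom_name = "X",
                         charge_e = charges, sigma_nm = sigma,
                         epsilon_kjmol = epsilon, stringsAsFactors = FALSE)
  } else {
    nResidues <- as.integer(nResidues)
    if (nResidues < 4L) stop("mini_chain needs at least four residues")
    if (any(spacing <= 0)) stop("invalid geometry: spacing must be positive")
    charges <- rep_len(charges, nResidues)
    resNames <- sprintf("CH%02d", seq_len(nResidues))
    atoms <- data.frame(atomName = "X", resName = resNames,
                        resIndex = seq_len(nResidues), chain = "A",
                        stringsAsFactors = FALSE)
    frames <- lapply(spacing, function(s)
      cbind((seq_len(nResidues) - 1) * 10 * s, 0, 0))
    ens <- new("StructureEnsemble", atoms = atoms, frames = frames,
               residueIds = sprintf("A:%d", seq_len(nResidues)),
               residueChain = rep("A", nResidues))
    params <- data.frame(res_name = resNames, atom_name = "X",
                         charge_e = charges, sigma_nm = sigma,
                         epsilon_kjmol = epsilon, stringsAsFactors = FALSE)
  }
  list(ensemble = ens, params = params)
}

.checkRange <- function(x, name) {
  if (length(x) != 2L || x[1] >= x[2])
    stop(name, " must be an ascending (lo, hi) pair")
}

# residue-index separation of column pair (i, j) for a member with the
# given gap vector; NA if either endpoint is gapped
.resSeparation <- function(gap, i, j) {
  if (gap[i] || gap[j]) return(NA_integer_)
  resIdx <- cumsum(!gap)
  abs(resIdx[j] - resIdx[i])
}

.samplePairs <- function(L, n, minSep, exclude = NULL) {
  all <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  all <- all[all[, 2] - all[, 1] >= minSep, , drop = FALSE]
  if (!is.null(exclude) && nrow(exclude)) {
    key <- paste(all[, 1], all[, 2])
    exKey <- paste(pmin(exclude[, 1], exclude[, 2]),
                   pmax(exclude[, 1], exclude[, 2]))
    all <- all[!key %in% exKey, , drop = FALSE]
  }
  if (nrow(all) < n)
    stop(sprintf("infeasible spec: %d edges requested but only %d eligible column pairs",
                 n, nrow(all)))
  sel <- all[sample.int(nrow(all), n), , drop = FALSE]
  sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
}

#' Synthetic family of energy matrices with planted conserved edges
#'
#' Generates an M-member family over an L-column alignment: a planted set
#' of conserved edges present in every member, optional clade-specific
#' edge pools shared within (but not across) member clades, per-member
#' private noise edges, and per-member gap patterns. Energies are drawn
#' uniformly from three disjoint ranges so that a single cutoff between
#' the noise and non-edge ranges separates interactions from background.
#'
#' Noise edges are drawn disjointly across members, so each is genuinely
#' private to one member; gaps are placed only at columns not touched by
#' planted or clade edges, and gap patterns are re-drawn if gap removal
#' would ever turn a planted edge into an excluded sequential-neighbour
#' pair. Identical seeds give byte-identical outputs.
#'
#' @param M members (>= 2).
#' @param L alignment columns.
#' @param nPlanted number of planted conserved edges (ignored when
#'   `plantedEdges` is given).
#' @param plantedEdges optional two-column matrix of column pairs.
#' @param privateEdgeRate Poisson mean of per-member private noise edges.
#' @param gapRate per member-column gap probability at eligible columns.
#' @param conservedRange,noiseRange,nonEdgeRange ascending (lo, hi) energy
#'   ranges in kJ/mol; must be pairwise disjoint. Defaults:
#'   conserved U(-30, -15), noise U(-14, -8), non-edges U(-5, 0).
#' @param cladePartition optional list of disjoint member-index vectors.
#' @param nCladeEdges clade-specific conserved edges per clade.
#' @param mode `"full"` or `"lj_only"` tag on the matrices.
#' @param seed integer RNG seed.
#' @param outDir optional directory; when given, writes `mssa.fasta`,
#'   one dense energy TSV per member, `manifest.tsv` and `truth.json`.
#' @return list with `mssa` (an [MSSA-class]), `matrices` (named list of
#'   [EnergyMatrix-class]) and `truth` (planted/clade/private edges, gap
#'   matrix, clade partition, seed).
#' @export
makeFamily <- function(M = 5L, L = 60L, nPlanted = 10L, plantedEdges = NULL,
                       privateEdgeRate = 2, gapRate = 0.05,
                       conservedRange = c(-30, -15),
                       noiseRange = c(-14, -8),
                       nonEdgeRange = c(-5, 0),
                       cladePartition = NULL, nCladeEdges = 0L,
                       mode = c("full", "lj_only"),
                       seed = 1L, outDir = NULL) {
  mode <- match.arg(mode)
  M <- as.integer(M); L <- as.integer(L)
  if (M < 2L) stop("a family needs at least two members")
  .checkRange(conservedRange, "conservedRange")
  .checkRange(noiseRange, "noiseRange")
  .checkRange(nonEdgeRange, "nonEdgeRange")
  rngs <- rbind(conservedRange, noiseRange, nonEdgeRange)
  rngs <- rngs[order(rngs[, 1]), ]
  if (any(rngs[-1, 1] < rngs[-nrow(rngs), 2]))
    stop("energy ranges must be pairwise disjoint")
  if (!is.null(cladePartition)) {
    idx <- unlist(cladePartition)
    if (anyDuplicated(idx) || any(idx < 1L | idx > M))
      stop("cladePartition must contain disjoint member indices in 1..M")
  }
  set.seed(as.integer(seed))

  if (is.null(plantedEdges)) {
    if (nPlanted > choose(L, 2))
      stop("infeasible spec: more planted edges than column pairs")
    plantedEdges <- .samplePairs(L, nPlanted, minSep = 4L)
  } else {
    plantedEdges <- cbind(pmin(plantedEdges[, 1], plantedEdges[, 2]),
                          pmax(plantedEdges[, 1], plantedEdges[, 2]))
    if (any(plantedEdges[, 2] - plantedEdges[, 1] < 2L))
      stop("planted edges need column separation >= 2")
  }
  cladeEdges <- list()
  if (!is.null(cladePartition) && nCladeEdges > 0L) {
    used <- plantedEdges
    for (k in seq_along(cladePartition)) {
      ce <- .samplePairs(L, nCladeEdges, minSep = 4L, exclude = used)
      cladeEdges[[k]] <- ce
      used <- rbind(used, ce)
    }
  }
  requiredAll <- rbind(plantedEdges, do.call(rbind, cladeEdges))
  protectedCols <- unique(c(requiredAll))

  cladeOf <- rep(NA_integer_, M)
  if (!is.null(cladePartition))
    for (k in seq_along(cladePartition)) cladeOf[cladePartition[[k]]] <- k

  memberIds <- sprintf("m%02d", seq_len(M))
  eligibleGap <- setdiff(seq_len(L), protectedCols)

  gaps <- matrix(FALSE, M, L)
  for (m in seq_len(M)) {
    req <- plantedEdges
    if (!is.na(cladeOf[m]) && length(cladeEdges))
      req <- rbind(req, cladeEdges[[cladeOf[m]]])
    for (try in seq_len(100L)) {
      g <- rep(FALSE, L)
      g[eligibleGap] <- stats::runif(length(eligibleGap)) < gapRate
      seps <- vapply(seq_len(nrow(req)), function(k)
        .resSeparation(g, req[k, 1], req[k, 2]), integer(1))
      if (all(seps >= 2L, na.rm = FALSE) && sum(!g) >= 1L) break
      if (try == 100L)
        stop("infeasible spec: could not place gaps without breaking a planted edge")
    }
    gaps[m, ] <- g
  }

  # conserved residue letters at protected columns, random letters elsewhere
  aln <- matrix("-", M, L)
  consLetter <- sample(.AA20, L, replace = TRUE)
  for (m in seq_len(M)) {
    lets <- sample(.AA20, L, replace = TRUE)
    lets[protectedCols] <- consLetter[protectedCols]
    lets[gaps[m, ]] <- "-"
    aln[m, ] <- lets
  }
  msa <- mssa(stats::setNames(apply(aln, 1, paste, collapse = ""), memberIds))

  pairKey <- function(p) paste(p[, 1], p[, 2], sep = "_")
  requiredKeyAll <- pairKey(requiredAll)

  matrices <- list()
  privateEdges <- vector("list", M)
  usedNoise <- character(0)
  for (m in seq_len(M)) {
    g <- gaps[m, ]
    realCols <- which(!g)
    n <- length(realCols)
    reqKey <- pairKey(plantedEdges)
    if (!is.na(cladeOf[m]) && length(cladeEdges))
      reqKey <- c(reqKey, pairKey(cladeEdges[[cladeOf[m]]]))

    # candidate noise pairs: both columns real, residue separation >= 2,
    # outside every conserved pool and every other member's noise
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    ut <- ut[ut[, 2] - ut[, 1] >= 2L, , drop = FALSE]
    colPair <- cbind(realCols[ut[, 1]], realCols[ut[, 2]])
    keys <- pairKey(colPair)
    eligible <- !(keys %in% requiredKeyAll) & !(keys %in% usedNoise)
    nNoise <- min(stats::rpois(1, privateEdgeRate), sum(eligible))
    noiseIdx <- if (nNoise > 0)
      sample(which(eligible), nNoise) else integer(0)
    privateEdges[[m]] <- colPair[noiseIdx, , drop = FALSE]
    usedNoise <- c(usedNoise, keys[noiseIdx])

    # fill energies: background first, then overwrite edge classes
    v <- matrix(NA_real_, n, n)
    bg <- stats::runif(nrow(ut), nonEdgeRange[1], nonEdgeRange[2])
    v[cbind(ut[, 1], ut[, 2])] <- bg
    isReq <- keys %in% reqKey
    v[ut[isReq, , drop = FALSE]] <-
      stats::runif(sum(isReq), conservedRange[1], conservedRange[2])
    if (length(noiseIdx))
      v[ut[noiseIdx, , drop = FALSE]] <-
        stats::runif(length(noiseIdx), noiseRange[1], noiseRange[2])
    v[lower.tri(v)] <- t(v)[lower.tri(v)]
    ids <- sprintf("r%03d", seq_len(n))
    dimnames(v) <- list(ids, ids)
    matrices[[memberIds[m]]] <- new("EnergyMatrix", values = v,
                                    residueIds = ids,
                                    chain = rep("A", n), mode = mode,
                                    nFrames = 1L)
  }

  truth <- list(plantedEdges = plantedEdges, cladeEdges = cladeEdges,
                privateEdges = stats::setNames(privateEdges, memberIds),
                gaps = gaps, cladePartition = cladePartition,
                seed = as.integer(seed))

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeMSSA(msa, file.path(outDir, "mssa.fasta"))
    paths <- sprintf("%s.tsv", memberIds)
    for (m in seq_len(M))
      writeEnergyMatrix(matrices[[m]], file.path(outDir, paths[m]))
    utils::write.table(
      data.frame(member_id = memberIds, path = paths),
      file.path(outDir, "manifest.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(planted_edges = plantedEdges,
           clade_edges = cladeEdges,
           private_edges = lapply(privateEdges, function(x)
             if (nrow(x)) unname(x) else list()),
           gaps = gaps,
           clade_partition = cladePartition,
           seed = as.integer(seed)),
      file.path(outDir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }

  list(mssa = msa, matrices = matrices, truth = truth)
}
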