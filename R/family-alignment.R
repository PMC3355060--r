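## Family-level network alignment: member PENs are remapped onto the
## columns of a multiple structure-based sequence alignment (MSSA); gap
## columns become virtual nodes that can never form edges; per-edge
## commonality coefficients cc = X/M quantify interaction conservation.

# sentinel energy assigned to virtual-node pairs, kJ/mol
.VIRTUAL_ENERGY <- 100

.colLabel <- function(i) sprintf("c%03d", i)

#' Construct an MSSA from aligned strings
#'
#' @param seqs named character vector of equal-length aligned sequences;
#'   `-` (or `.`) marks a gap.
#' @return an [MSSA-class].
#' @export
mssa <- function(seqs) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("aligned sequences must be named by member id")
  if (anyDuplicated(names(seqs)))
    stop("duplicate member ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  w <- nchar(seqs)
  if (length(unique(w)) != 1L)
    stop("aligned sequences must all have the same length")
  aln <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(aln) <- names(seqs)
  isGap <- aln %in% c("-", ".")
  dim(isGap) <- dim(aln)
  aln[isGap] <- "-"
  mapping <- t(apply(!isGap, 1, cumsum))
  mapping[isGap] <- NA_integer_
  storage.mode(mapping) <- "integer"
  dimnames(mapping) <- list(names(seqs), NULL)
  new("MSSA", memberIds = names(seqs), aln = aln, mapping = mapping)
}

#' Read a multiple structure-based sequence alignment from aligned FASTA
#'
#' Consumes the aligned-FASTA output of a structural aligner (e.g.
#' MUSTANG). All records must share the aligned length; aligned columns
#' define the equivalent residues of the family.
#'
#' @param path aligned FASTA file.
#' @return an [MSSA-class].
#' @export
readMSSA <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(unique(Biostrings::width(ss))) > 1L)
    stop("alignment records differ in length in ", path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  mssa(seqs)
}

#' Write an MSSA to aligned FASTA
#'
#' @param x an [MSSA-class].
#' @param path output file.
#' @export
writeMSSA <- function(x, path) {
  stopifnot(is(x, "MSSA"))
  lines <- as.vector(rbind(paste0(">", x@memberIds),
                           apply(x@aln, 1, paste, collapse = "")))
  writeLines(lines, path)
  invisible(path)
}

#' Remap a member network onto alignment columns
#'
#' Relabels the nodes of a member's thresholded network from residues to
#' the columns of the family MSSA. Columns that are gaps for the member
#' become virtual nodes with zero degree; an ungapped member's remapped
#' network is a pure relabelling with the same edge count.
#'
#' @param net the member's [ThresholdedNetwork-class]; its k-th node must
#'   be the member's k-th aligned residue.
#' @param msa an [MSSA-class].
#' @param memberId which member of the alignment.
#' @return a [RemappedPEN-class] of dimension L x L.
#' @export
remapPEN <- function(net, msa, memberId) {
  stopifnot(is(net, "ThresholdedNetwork"), is(msa, "MSSA"))
  m <- match(memberId, msa@memberIds)
  if (is.na(m)) stop("member '", memberId, "' not in the alignment")
  map <- msa@mapping[m, ]
  nMapped <- sum(!is.na(map))
  if (length(net@nodes) != nMapped)
    stop(sprintf(
      "member '%s': network has %d nodes but the alignment maps %d residues",
      memberId, length(net@nodes), nMapped))
  L <- length(map)
  colOf <- integer(nMapped)
  colOf[map[!is.na(map)]] <- which(!is.na(map))
  adj <- matrix(FALSE, L, L)
  if (nrow(net@edges) > 0L) {
    a <- colOf[match(net@edges[, 1], net@nodes)]
    b <- colOf[match(net@edges[, 2], net@nodes)]
    adj[cbind(a, b)] <- TRUE
    adj[cbind(b, a)] <- TRUE
  }
  new("RemappedPEN", memberId = memberId, adjacency = adj,
      virtualNodes = which(is.na(map)), cutoffE = net@cutoffE,
      mode = net@mode)
}

#' Remap a member energy matrix onto alignment columns
#'
#' Column-space L x L energy matrix for one member: real column pairs keep
#' their residue-pair energies (`NA` where the pair is excluded), and any
#' pair involving a virtual node carries the sentinel +100 kJ/mol, so a
#' virtual pair can never pass a realistic (negative) cutoff.
#'
#' @param em the member's [EnergyMatrix-class].
#' @param msa an [MSSA-class].
#' @param memberId which member of the alignment.
#' @param virtualEnergy sentinel for virtual pairs, kJ/mol (default 100).
#' @return L x L numeric matrix with `NA` diagonal.
#' @export
remapEnergyMatrix <- function(em, msa, memberId,
                              virtualEnergy = .VIRTUAL_ENERGY) {
  stopifnot(is(em, "EnergyMatrix"), is(msa, "MSSA"))
  m <- match(memberId, msa@memberIds)
  if (is.na(m)) stop("member '", memberId, "' not in the alignment")
  map <- msa@mapping[m, ]
  if (length(em@residueIds) != sum(!is.na(map)))
    stop(sprintf(
      "member '%s': energy matrix has %d residues but the alignment maps %d",
      memberId, length(em@residueIds), sum(!is.na(map))))
  L <- length(map)
  v <- matrix(virtualEnergy, L, L)
  real <- which(!is.na(map))
  v[real, real] <- em@values[map[real], map[real]]
  diag(v) <- NA_real_
  v
}

#' Commonality coefficients of a family of remapped networks
#'
#' For every alignment-column pair (i, j), `cc[i, j] = X / M` where X is
#' the number of members whose remapped network has the edge and M is the
#' family size. A member for which either column is a gap (virtual node)
#' cannot have the edge and contributes 0 to X, while M stays the family
#' size.
#'
#' @param remapped list of [RemappedPEN-class], all sharing L and cutoff.
#' @return a [FamilyNetwork-class].
#' @export
commonality <- function(remapped) {
  if (length(remapped) < 2L) stop("a family needs at least two members")
  if (!all(vapply(remapped, is, TRUE, "RemappedPEN")))
    stop("remapped must be a list of RemappedPEN objects")
  L <- alignedLength(remapped[[1]])
  e <- cutoffE(remapped[[1]])
  md <- energyMode(remapped[[1]])
  for (r in remapped[-1]) {
    if (alignedLength(r) != L) stop("remapped networks differ in L")
    if (cutoffE(r) != e) stop("remapped networks differ in cutoff e")
    if (energyMode(r) != md) stop("remapped networks mix energy modes")
  }
  X <- Reduce(`+`, lapply(remapped, function(r) r@adjacency * 1))
  M <- length(remapped)
  cc <- X / M
  diag(cc) <- 0
  dimnames(cc) <- list(.colLabel(seq_len(L)), .colLabel(seq_len(L)))
  new("FamilyNetwork", ccMatrix = cc, M = as.integer(M), cutoffE = e,
      mode = md)
}

#' Edges of the family network at a commonality threshold
#'
#' The f-PEN_e(cc) edge set: column pairs whose commonality coefficient is
#' at least `ccThreshold` (so `ccThreshold = 1` keeps the edges present in
#' every member, and thresholds near 0 approach the union of all members'
#' edges). Edge sets are nested as the threshold tightens.
#'
#' @param fam a [FamilyNetwork-class].
#' @param ccThreshold commonality threshold in (0, 1].
#' @return data.frame with columns `col_a`, `col_b`, `cc`, `X`
#'   (`X = cc * M`), ordered by column indices.
#' @export
fpenEdges <- function(fam, ccThreshold) {
  stopifnot(is(fam, "FamilyNetwork"))
  if (length(ccThreshold) != 1L || ccThreshold <= 0 || ccThreshold > 1)
    stop("ccThreshold must lie in (0, 1]")
  cc <- fam@ccMatrix
  hit <- which(upper.tri(cc) & cc >= ccThreshold - 1e-12, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  data.frame(col_a = hit[, 1], col_b = hit[, 2],
             cc = cc[hit], X = as.integer(round(cc[hit] * fam@M)))
}

# family network at a cc threshold as a ThresholdedNetwork over columns
.familyAsNetwork <- function(fam, ccThreshold) {
  ed <- fpenEdges(fam, ccThreshold)
  edges <- cbind(.colLabel(ed$col_a), .colLabel(ed$col_b))
  if (nrow(edges) == 0L) edges <- matrix(character(0), ncol = 2)
  new("ThresholdedNetwork",
      nodes = .colLabel(seq_len(alignedLength(fam))),
      edges = edges, cutoffE = fam@cutoffE, mode = fam@mode)
}

#' Conserved clusters of a family network
#'
#' Connected components of f-PEN_e(cc) with at least `minSize` columns.
#'
#' @param fam a [FamilyNetwork-class].
#' @param ccThreshold commonality threshold in (0, 1].
#' @param minSize minimum cluster size (default 3).
#' @return a [ClusterSet-class] over column labels `c001`, `c002`, ...
#' @export
familyClusters <- function(fam, ccThreshold, minSize = 3L) {
  connectedClusters(.familyAsNetwork(fam, ccThreshold), minSize)
}

#' Conserved family hubs
#'
#' A column is a family hub when, in at least `memberFraction` of the
#' members, the member's remapped node at that column has degree >= 3
#' (virtual nodes have degree 0 and therefore count against the fraction).
#'
#' @param remapped list of [RemappedPEN-class] over a shared alignment.
#' @param degreeMin minimum per-member degree (default 3).
#' @param memberFraction required fraction of members in (0, 1]
#'   (default 0.7).
#' @return data.frame with columns `column`, `hub_fraction`, restricted to
#'   columns meeting the fraction.
#' @export
familyHubs <- function(remapped, degreeMin = 3L, memberFraction = 0.7) {
  if (memberFraction <= 0 || memberFraction > 1)
    stop("memberFraction must lie in (0, 1]")
  if (!length(remapped)) stop("no remapped networks given")
  deg <- vapply(remapped, function(r) rowSums(r@adjacency),
                numeric(alignedLength(remapped[[1]])))
  frac <- rowMeans(deg >= degreeMin)
  hit <- which(frac >= memberFraction - 1e-12)
  data.frame(column = hit, hub_fraction = frac[hit])
}

#' Threshold and remap a whole family in one call
#'
#' @param msa an [MSSA-class].
#' @param matrices named list of per-member [EnergyMatrix-class]; names
#'   must cover the alignment's member ids.
#' @param e energy cutoff in kJ/mol.
#' @return list with `remapped` (list of [RemappedPEN-class], in alignment
#'   member order) and `family` (a [FamilyNetwork-class]).
#' @export
familyNetwork <- function(msa, matrices, e) {
  stopifnot(is(msa, "MSSA"))
  missing <- setdiff(msa@memberIds, names(matrices))
  if (length(missing))
    stop("no energy matrix for member(s): ", paste(missing, collapse = ", "))
  remapped <- lapply(msa@memberIds, function(id)
    remapPEN(thresholdNetwork(matrices[[id]], e), msa, id))
  names(remapped) <- msa@memberIds
  list(remapped = remapped, family = commonality(remapped))
}

#' Write a commonality matrix to TSV
#'
#' @param fam a [FamilyNetwork-class].
#' @param path output file.
#' @export
writeCCMatrix <- function(fam, path) {
  stopifnot(is(fam, "FamilyNetwork"))
  cc <- fam@ccMatrix
  df <- data.frame(col_id = rownames(cc), cc, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a family manifest
#'
#' Two-column TSV (`member_id`, `path`) locating each member's energy
#' matrix; relative paths are resolved against the manifest's directory.
#'
#' @param path manifest TSV.
#' @return named list of [EnergyMatrix-class].
#' @export
readFamilyManifest <- function(path) {
  man <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("member_id", "path") %in% names(man)))
    stop("manifest must have columns member_id and path")
  base <- dirname(path)
  mats <- lapply(man$path, function(p) {
    if (!file.exists(p)) p <- file.path(base, p)
    readEnergyMatrix(p)
  })
  names(mats) <- man$member_id
  mats
}
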