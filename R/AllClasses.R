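#' @import methods
NULL

# Internal helper: TRUE where a square numeric matrix is symmetric including
# its NA pattern.
.symmetricWithNA <- function(x, tol = 1e-9) {
  if (nrow(x) != ncol(x)) return(FALSE)
  na <- is.na(x)
  if (!identical(na, t(na))) return(FALSE)
  ok <- abs(x - t(x)) <= tol
  all(ok[!na])
}

#' EnergyMatrix: averaged residue-residue interaction energies
#'
#' Symmetric matrix of pairwise non-bonded interaction energies (kJ/mol)
#' between residues, averaged over the frames of a conformational ensemble.
#' Self pairs and sequential neighbours (|i - j| <= 1 within one chain) carry
#' no energy and are stored as `NA`; inter-chain pairs are never excluded.
#'
#' @slot values numeric matrix, kJ/mol; `NA` marks excluded pairs.
#' @slot residueIds character vector of residue labels, in chain order.
#' @slot chain character vector, chain identifier per residue.
#' @slot mode `"full"` (Coulomb + Lennard-Jones) or `"lj_only"`.
#' @slot nFrames integer, number of ensemble frames averaged.
#'
#' @seealso [buildEnergyMatrix()], [thresholdNetwork()]
#' @export
setClass("EnergyMatrix",
  representation(
    values     = "matrix",
    residueIds = "character",
    chain      = "character",
    mode       = "character",
    nFrames    = "integer"
  )
)

setValidity("EnergyMatrix", function(object) {
  v <- object@values
  n <- length(object@residueIds)
  if (nrow(v) != n || ncol(v) != n)
    return("values must be an n x n matrix matching residueIds")
  if (length(object@chain) != n)
    return("chain must have one entry per residue")
  if (!object@mode %in% c("full", "lj_only"))
    return("mode must be 'full' or 'lj_only'")
  if (length(object@nFrames) != 1L || object@nFrames < 1L)
    return("nFrames must be a positive integer")
  if (!.symmetricWithNA(v))
    return("values must be symmetric (including the NA pattern)")
  if (any(!is.na(diag(v))))
    return("self pairs must be NA")
  if (n > 1) {
    same <- object@chain[-n] == object@chain[-1]
    seqv <- v[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)]
    if (any(same & !is.na(seqv)))
      return("sequential-neighbour pairs within a chain must be NA")
  }
  if (any(!is.finite(v[!is.na(v)])))
    return("all present energies must be finite")
  TRUE
})

#' StructureEnsemble: atom roster plus one or more coordinate frames
#'
#' @slot atoms data.frame with columns `atomName`, `resName`, `resIndex`
#'   (1-based residue ordinal along the roster), `chain`.
#' @slot frames list of N x 3 numeric coordinate matrices in Angstrom, all
#'   over the identical atom roster.
#' @slot residueIds character, one label per residue in roster order.
#' @slot residueChain character, chain per residue.
#' @export
setClass("StructureEnsemble",
  representation(
    atoms        = "data.frame",
    frames       = "list",
    residueIds   = "character",
    residueChain = "character"
  )
)

setValidity("StructureEnsemble", function(object) {
  need <- c("atomName", "resName", "resIndex", "chain")
  if (!all(need %in% names(object@atoms)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (length(object@frames) < 1L)
    return("at least one coordinate frame is required")
  na <- nrow(object@atoms)
  for (f in object@frames) {
    if (!is.matrix(f) || nrow(f) != na || ncol(f) != 3L)
      return("every frame must be an N x 3 matrix over the same atom roster")
    if (any(!is.finite(f)))
      return("coordinates must be finite")
  }
  nr <- length(object@residueIds)
  if (length(object@residueChain) != nr)
    return("residueChain must match residueIds in length")
  if (max(object@atoms$resIndex) > nr || min(object@atoms$resIndex) < 1L)
    return("atom resIndex out of residue roster range")
  TRUE
})

#' ThresholdedNetwork: unweighted PEN at an energy cutoff
#'
#' Nodes are residues; an edge is present iff the source energy matrix has a
#' value at or below the cutoff `e` (energies are negative when favourable,
#' so "at or below" means "at least as favourable").
#'
#' @slot nodes character, residue ids in chain order.
#' @slot edges two-column character matrix of unordered node pairs.
#' @slot cutoffE numeric, the energy cutoff in kJ/mol.
#' @slot mode `"full"` or `"lj_only"`, inherited from the energy matrix.
#' @export
setClass("ThresholdedNetwork",
  representation(
    nodes   = "character",
    edges   = "matrix",
    cutoffE = "numeric",
    mode    = "character"
  )
)

setValidity("ThresholdedNetwork", function(object) {
  e <- object@edges
  if (ncol(e) != 2L && nrow(e) > 0L)
    return("edges must be a two-column matrix")
  if (nrow(e) > 0L) {
    if (!all(c(e) %in% object@nodes))
      return("edge endpoints must be network nodes")
    if (any(e[, 1] == e[, 2]))
      return("self-edges are not allowed")
  }
  if (length(object@cutoffE) != 1L || !is.finite(object@cutoffE))
    return("cutoffE must be a single finite number")
  TRUE
})

#' ClusterSet: connected components of minimum size
#'
#' @slot clusters list of character vectors (node sets), sorted by
#'   decreasing size then by lexicographically smallest member.
#' @slot largestClusterSize integer, size of the largest component of any
#'   size in the source network (0 when the network has no edges).
#' @slot minSize integer, the minimum component size retained.
#' @export
setClass("ClusterSet",
  representation(
    clusters           = "list",
    largestClusterSize = "integer",
    minSize            = "integer"
  )
)

#' MSSA: multiple structure-based sequence alignment
#'
#' M members by L aligned columns, with a per-member map from columns to
#' 1-based residue indices (`NA` at gap columns). Aligned columns define the
#' "equivalent residues" across family members.
#'
#' @slot memberIds character of length M.
#' @slot aln M x L character matrix of residue letters and `"-"` gaps.
#' @slot mapping M x L integer matrix; entry (m, c) is the residue index of
#'   member m at column c, or `NA` for a gap.
#' @export
setClass("MSSA",
  representation(
    memberIds = "character",
    aln       = "matrix",
    mapping   = "matrix"
  )
)

setValidity("MSSA", function(object) {
  m <- length(object@memberIds)
  if (nrow(object@aln) != m || nrow(object@mapping) != m)
    return("aln and mapping must have one row per member")
  if (ncol(object@aln) != ncol(object@mapping))
    return("aln and mapping must share the aligned length")
  if (anyDuplicated(object@memberIds))
    return("member ids must be unique")
  for (i in seq_len(m)) {
    r <- object@mapping[i, ]
    r <- r[!is.na(r)]
    if (length(r) == 0L)
      return(sprintf("member '%s' maps no columns (all gaps)",
                     object@memberIds[i]))
    if (any(diff(r) <= 0L))
      return("non-gap residue indices must be strictly increasing")
  }
  TRUE
})

#' RemappedPEN: a member network in alignment-column coordinates
#'
#' A member's thresholded network relabelled onto the L alignment columns of
#' its family MSSA. Columns that are gaps for the member become virtual
#' nodes: they carry the sentinel energy +100 kJ/mol towards every other
#' node and can never form an edge.
#'
#' @slot memberId character scalar.
#' @slot adjacency L x L logical matrix (symmetric, FALSE diagonal).
#' @slot virtualNodes integer, the gap columns of this member.
#' @slot cutoffE numeric, kJ/mol.
#' @slot mode `"full"` or `"lj_only"`.
#' @export
setClass("RemappedPEN",
  representation(
    memberId     = "character",
    adjacency    = "matrix",
    virtualNodes = "integer",
    cutoffE      = "numeric",
    mode         = "character"
  )
)

setValidity("RemappedPEN", function(object) {
  a <- object@adjacency
  if (nrow(a) != ncol(a)) return("adjacency must be square")
  if (!is.logical(a)) return("adjacency must be logical")
  if (!identical(a, t(a))) return("adjacency must be symmetric")
  if (any(diag(a))) return("no self-edges")
  if (length(object@virtualNodes) &&
      any(rowSums(a)[object@virtualNodes] > 0))
    return("virtual nodes must have zero degree")
  TRUE
})

#' FamilyNetwork: commonality coefficients over alignment columns
#'
#' For a family of M remapped member networks at cutoff e, `cc[i, j] = X/M`
#' where X counts the members possessing edge (i, j). The family network at
#' commonality threshold cc, f-PEN_e(cc), keeps the column pairs with
#' `cc[i, j] >= cc`.
#'
#' @slot ccMatrix L x L numeric in [0, 1].
#' @slot M integer, family size.
#' @slot cutoffE numeric, kJ/mol.
#' @slot mode `"full"` or `"lj_only"`.
#' @export
setClass("FamilyNetwork",
  representation(
    ccMatrix = "matrix",
    M        = "integer",
    cutoffE  = "numeric",
    mode     = "character"
  )
)

setValidity("FamilyNetwork", function(object) {
  cc <- object@ccMatrix
  if (nrow(cc) != ncol(cc)) return("ccMatrix must be square")
  if (any(cc < 0 | cc > 1, na.rm = TRUE)) return("cc values must lie in [0, 1]")
  if (!.symmetricWithNA(cc)) return("ccMatrix must be symmetric")
  x <- cc * object@M
  if (any(abs(x - round(x)) > 1e-9, na.rm = TRUE))
    return("cc * M must be integral (the member count X)")
  TRUE
})

#' PENPhylogeny: interaction-conservation similarity, distance and tree
#'
#' @slot memberIds character.
#' @slot SS symmetric similarity matrix, unit diagonal.
#' @slot D symmetric distance matrix, zero diagonal.
#' @slot tree an `ape::phylo` dendrogram with branch lengths.
#' @slot clustering the underlying `stats::hclust` object.
#' @export
setClass("PENPhylogeny",
  representation(
    memberIds  = "character",
    SS         = "matrix",
    D          = "matrix",
    tree       = "ANY",
    clustering = "ANY"
  )
)

setValidity("PENPhylogeny", function(object) {
  n <- length(object@memberIds)
  if (any(dim(object@SS) != n) || any(dim(object@D) != n))
    return("SS and D must be n x n over memberIds")
  if (max(abs(object@D - t(object@D))) > 1e-9)
    return("D must be symmetric")
  if (any(abs(diag(object@D)) > 1e-9))
    return("D must have zero diagonal")
  if (any(object@D < -1e-12))
    return("distances must be non-negative")
  TRUE
})
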