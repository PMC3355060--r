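#' @include AllClasses.R
NULL

#' Accessors for penet classes
#'
#' Small accessor generics exposing the slots of the package's S4 classes
#' without direct slot access.
#'
#' @param x a penet object.
#' @name penet-accessors
NULL

#' @rdname penet-accessors
#' @export
setGeneric("residueIds", function(x) standardGeneric("residueIds"))

#' @rdname penet-accessors
#' @export
setGeneric("energyValues", function(x) standardGeneric("energyValues"))

#' @rdname penet-accessors
#' @export
setGeneric("energyMode", function(x) standardGeneric("energyMode"))

#' @rdname penet-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname penet-accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname penet-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname penet-accessors
#' @export
setGeneric("cutoffE", function(x) standardGeneric("cutoffE"))

#' @rdname penet-accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname penet-accessors
#' @export
setGeneric("largestClusterSize", function(x) standardGeneric("largestClusterSize"))

#' @rdname penet-accessors
#' @export
setGeneric("memberIds", function(x) standardGeneric("memberIds"))

#' @rdname penet-accessors
#' @export
setGeneric("alignedLength", function(x) standardGeneric("alignedLength"))

#' @rdname penet-accessors
#' @export
setGeneric("residueMapping", function(x) standardGeneric("residueMapping"))

#' @rdname penet-accessors
#' @export
setGeneric("virtualNodes", function(x) standardGeneric("virtualNodes"))

#' @rdname penet-accessors
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname penet-accessors
#' @export
setGeneric("ccMatrix", function(x) standardGeneric("ccMatrix"))

#' @rdname penet-accessors
#' @export
setGeneric("familySize", function(x) standardGeneric("familySize"))

#' @rdname penet-accessors
#' @export
setGeneric("similarityMatrix", function(x) standardGeneric("similarityMatrix"))

#' @rdname penet-accessors
#' @export
setGeneric("distanceMatrix", function(x) standardGeneric("distanceMatrix"))

#' @rdname penet-accessors
#' @export
setGeneric("phyloTree", function(x) standardGeneric("phyloTree"))

# ---- methods -------------------------------------------------------------

#' @rdname penet-accessors
setMethod("residueIds", "EnergyMatrix", function(x) x@residueIds)
#' @rdname penet-accessors
setMethod("residueIds", "StructureEnsemble", function(x) x@residueIds)
#' @rdname penet-accessors
setMethod("energyValues", "EnergyMatrix", function(x) x@values)
#' @rdname penet-accessors
setMethod("energyMode", "EnergyMatrix", function(x) x@mode)
#' @rdname penet-accessors
setMethod("energyMode", "ThresholdedNetwork", function(x) x@mode)
#' @rdname penet-accessors
setMethod("energyMode", "RemappedPEN", function(x) x@mode)
#' @rdname penet-accessors
setMethod("energyMode", "FamilyNetwork", function(x) x@mode)
#' @rdname penet-accessors
setMethod("nFrames", "EnergyMatrix", function(x) x@nFrames)
#' @rdname penet-accessors
setMethod("nFrames", "StructureEnsemble", function(x) length(x@frames))
#' @rdname penet-accessors
setMethod("networkNodes", "ThresholdedNetwork", function(x) x@nodes)
#' @rdname penet-accessors
setMethod("networkEdges", "ThresholdedNetwork", function(x) x@edges)
#' @rdname penet-accessors
setMethod("cutoffE", "ThresholdedNetwork", function(x) x@cutoffE)
#' @rdname penet-accessors
setMethod("cutoffE", "RemappedPEN", function(x) x@cutoffE)
#' @rdname penet-accessors
setMethod("cutoffE", "FamilyNetwork", function(x) x@cutoffE)
#' @rdname penet-accessors
setMethod("clusters", "ClusterSet", function(x) x@clusters)
#' @rdname penet-accessors
setMethod("largestClusterSize", "ClusterSet", function(x) x@largestClusterSize)
#' @rdname penet-accessors
setMethod("memberIds", "MSSA", function(x) x@memberIds)
#' @rdname penet-accessors
setMethod("memberIds", "RemappedPEN", function(x) x@memberId)
#' @rdname penet-accessors
setMethod("memberIds", "PENPhylogeny", function(x) x@memberIds)
#' @rdname penet-accessors
setMethod("alignedLength", "MSSA", function(x) ncol(x@aln))
#' @rdname penet-accessors
setMethod("alignedLength", "RemappedPEN", function(x) nrow(x@adjacency))
#' @rdname penet-accessors
setMethod("alignedLength", "FamilyNetwork", function(x) nrow(x@ccMatrix))
#' @rdname penet-accessors
setMethod("residueMapping", "MSSA", function(x) x@mapping)
#' @rdname penet-accessors
setMethod("virtualNodes", "RemappedPEN", function(x) x@virtualNodes)
#' @rdname penet-accessors
setMethod("adjacencyMatrix", "RemappedPEN", function(x) x@adjacency)
#' @rdname penet-accessors
setMethod("ccMatrix", "FamilyNetwork", function(x) x@ccMatrix)
#' @rdname penet-accessors
setMethod("familySize", "FamilyNetwork", function(x) x@M)
#' @rdname penet-accessors
setMethod("similarityMatrix", "PENPhylogeny", function(x) x@SS)
#' @rdname penet-accessors
setMethod("distanceMatrix", "PENPhylogeny", function(x) x@D)
#' @rdname penet-accessors
setMethod("phyloTree", "PENPhylogeny", function(x) x@tree)

# ---- show methods --------------------------------------------------------

setMethod("show", "EnergyMatrix", function(object) {
  n <- length(object@residueIds)
  present <- sum(!is.na(object@values[upper.tri(object@values)]))
  cat(sprintf("EnergyMatrix: %d residues, %d pair energies (%s mode, %d frame%s)\n",
              n, present, object@mode, object@nFrames,
              if (object@nFrames == 1L) "" else "s"))
  if (present > 0) {
    v <- object@values[upper.tri(object@values)]
    cat(sprintf("  energy range: [%.3f, %.3f] kJ/mol\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  }
})

setMethod("show", "StructureEnsemble", function(object) {
  cat(sprintf("StructureEnsemble: %d atoms, %d residues, %d frame%s\n",
              nrow(object@atoms), length(object@residueIds),
              length(object@frames),
              if (length(object@frames) == 1L) "" else "s"))
})

setMethod("show", "ThresholdedNetwork", function(object) {
  cat(sprintf("ThresholdedNetwork (%s): %d nodes, %d edges at e <= %g kJ/mol\n",
              object@mode, length(object@nodes), nrow(object@edges),
              object@cutoffE))
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet: %d cluster%s of size >= %d; largest cluster = %d nodes\n",
              length(object@clusters),
              if (length(object@clusters) == 1L) "" else "s",
              object@minSize, object@largestClusterSize))
  for (cl in utils::head(object@clusters, 5))
    cat("  [", length(cl), "] ", paste(utils::head(cl, 8), collapse = " "),
        if (length(cl) > 8) " ..." else "", "\n", sep = "")
})

setMethod("show", "MSSA", function(object) {
  cat(sprintf("MSSA: %d members x %d columns (%.1f%% gaps)\n",
              length(object@memberIds), ncol(object@aln),
              100 * mean(is.na(object@mapping))))
})

setMethod("show", "RemappedPEN", function(object) {
  cat(sprintf("RemappedPEN '%s': L = %d columns, %d edges, %d virtual nodes (e = %g)\n",
              object@memberId, nrow(object@adjacency),
              sum(object@adjacency[upper.tri(object@adjacency)]),
              length(object@virtualNodes), object@cutoffE))
})

setMethod("show", "FamilyNetwork", function(object) {
  cc <- object@ccMatrix[upper.tri(object@ccMatrix)]
  cat(sprintf("FamilyNetwork: M = %d members, L = %d columns at e = %g kJ/mol\n",
              object@M, nrow(object@ccMatrix), object@cutoffE))
  cat(sprintf("  edges with cc = 1: %d; with cc > 0: %d\n",
              sum(cc >= 1 - 1e-12, na.rm = TRUE), sum(cc > 0, na.rm = TRUE)))
})

setMethod("show", "PENPhylogeny", function(object) {
  cat(sprintf("PENPhylogeny: %d members; mean off-diagonal SS = %.3f\n",
              length(object@memberIds),
              mean(object@SS[upper.tri(object@SS)])))
  cat("  newick: ", newickString(object), "\n", sep = "")
})
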