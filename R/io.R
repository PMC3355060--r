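## Readers and writers for the plain-text formats the pipeline consumes:
## PDB structures (via bio3d), force-field tables, energy matrices,
## secondary-structure labels and network edge lists.

#' Read a PDB file as a structure ensemble
#'
#' Multi-MODEL files become multi-frame ensembles over the shared atom
#' roster. Only ATOM records are kept; for alternate locations the first
#' altloc is retained.
#'
#' @param path PDB file.
#' @return a [StructureEnsemble-class]; residue ids are `chain:resno`.
#' @export
readPDBEnsemble <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM"
  if ("alt" %in% names(at))
    keep <- keep & (is.na(at$alt) | at$alt %in% c("", "A"))
  idx <- which(keep)
  if (length(idx) == 0L) stop("no ATOM records in ", path)
  at <- at[idx, , drop = FALSE]
  ch <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  resKey <- paste(ch, at$resno, sep = ":")
  resIds <- unique(resKey)
  resIndex <- match(resKey, resIds)

  atoms <- data.frame(
    atomName = trimws(at$elety),
    resName  = trimws(at$resid),
    resIndex = resIndex,
    chain    = ch,
    stringsAsFactors = FALSE
  )

  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  frames <- lapply(seq_len(nrow(xyz)), function(f)
    matrix(xyz[f, cols], ncol = 3, byrow = TRUE))

  new("StructureEnsemble", atoms = atoms, frames = frames,
      residueIds = resIds,
      residueChain = ch[!duplicated(resKey)])
}

#' Read a force-field parameter table
#'
#' Tab-separated with columns `res_name`, `atom_name`, `charge_e`,
#' `sigma_nm`, `epsilon_kjmol`. Real force fields are user-supplied; the
#' package bundles only a toy set for its synthetic fixtures.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readForceField <- function(path) {
  p <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  need <- c("res_name", "atom_name", "charge_e", "sigma_nm", "epsilon_kjmol")
  if (!all(need %in% names(p)))
    stop("force-field table must have columns: ", paste(need, collapse = ", "))
  p
}

#' Write an energy matrix to TSV
#'
#' `"matrix"` format is a dense table with residue ids as header row and
#' first column, preceded by `#` metadata lines (mode, frame count, chain
#' per residue) so the matrix round-trips through [readEnergyMatrix()].
#' `"long"` format lists one present residue pair per row.
#'
#' @param em an [EnergyMatrix-class].
#' @param path output file.
#' @param format `"matrix"` (default, round-trippable) or `"long"`.
#' @export
writeEnergyMatrix <- function(em, path, format = c("matrix", "long")) {
  format <- match.arg(format)
  stopifnot(is(em, "EnergyMatrix"))
  if (format == "matrix") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      paste0("# mode: ", em@mode),
      paste0("# n_frames: ", em@nFrames),
      paste0("# chain: ", paste(em@chain, collapse = " "))
    ), con)
    writeLines(paste(c("res_id", em@residueIds), collapse = "\t"), con)
    for (i in seq_along(em@residueIds))
      writeLines(paste(c(em@residueIds[i],
                         format(em@values[i, ], digits = 12, trim = TRUE)),
                       collapse = "\t"), con)
  } else {
    ut <- which(upper.tri(em@values) & !is.na(em@values), arr.ind = TRUE)
    df <- data.frame(res_i = em@residueIds[ut[, 1]],
                     res_j = em@residueIds[ut[, 2]],
                     energy_kjmol = em@values[ut],
                     mode = em@mode)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read an energy matrix written by [writeEnergyMatrix()] (matrix format)
#'
#' @param path TSV file in dense matrix format.
#' @return an [EnergyMatrix-class].
#' @export
readEnergyMatrix <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  getMeta <- function(tag, default) {
    hit <- grep(paste0("^# ", tag, ": "), meta, value = TRUE)
    if (length(hit)) sub(paste0("^# ", tag, ": "), "", hit[1]) else default
  }
  mode <- getMeta("mode", "full")
  nFrames <- as.integer(getMeta("n_frames", "1"))
  body <- lines[!grepl("^#", lines)]
  con <- textConnection(body)
  on.exit(close(con))
  tab <- utils::read.table(con, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  v <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  dimnames(v) <- list(ids, ids)
  chainStr <- getMeta("chain", paste(rep("A", length(ids)), collapse = " "))
  chain <- strsplit(chainStr, " ")[[1]]
  new("EnergyMatrix", values = v, residueIds = ids, chain = chain,
      mode = mode, nFrames = nFrames)
}

#' Read per-residue secondary-structure labels
#'
#' Tab-separated with columns `res_id`, `label` (`H` helix, `E` strand,
#' `C` other) and `strand_index` (ordinal of the strand, empty/NA unless
#' `label == "E"`), as produced from a DSSP-style assignment.
#'
#' @param path TSV file.
#' @return data.frame with columns `res_id`, `label`, `strand_index`.
#' @export
readSSE <- function(path) {
  s <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  need <- c("res_id", "label", "strand_index")
  if (!all(need %in% names(s)))
    stop("SSE table must have columns: ", paste(need, collapse = ", "))
  if (!all(s$label %in% c("H", "E", "C")))
    stop("SSE labels must be H, E or C")
  s$res_id <- as.character(s$res_id)
  bad <- (s$label == "E") != !is.na(s$strand_index)
  if (any(bad))
    stop("strand_index must be present exactly for strand (E) residues: ",
         paste(s$res_id[bad], collapse = ", "))
  s
}

#' Export a thresholded network
#'
#' @param net a [ThresholdedNetwork-class].
#' @param path output file.
#' @param em optional source [EnergyMatrix-class]; adds an energy column.
#' @param sse optional [readSSE()] table; adds an interface-class column.
#' @param ... passed to [classifyEdges()] when `sse` is given.
#' @return the path, invisibly.
#' @export
writeEdgeList <- function(net, path, em = NULL, sse = NULL, ...) {
  df <- data.frame(res_i = net@edges[, 1], res_j = net@edges[, 2],
                   stringsAsFactors = FALSE)
  if (!is.null(em)) {
    i <- match(df$res_i, em@residueIds)
    j <- match(df$res_j, em@residueIds)
    df$energy_kjmol <- em@values[cbind(i, j)]
  }
  if (!is.null(sse))
    df$interface_class <- classifyEdges(net, sse, ...)$edges$class
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a thresholded network to an igraph object
#'
#' @param net a [ThresholdedNetwork-class].
#' @return an undirected `igraph` graph whose vertices are all residues
#'   (including isolated ones).
#' @export
asIgraph <- function(net) {
  igraph::graph_from_data_frame(
    as.data.frame(net@edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net@nodes, stringsAsFactors = FALSE))
}

#' Export a thresholded network as GraphML
#'
#' @param net a [ThresholdedNetwork-class].
#' @param path output file.
#' @export
writeGraphML <- function(net, path) {
  igraph::write_graph(asIgraph(net), path, format = "graphml")
  invisible(path)
}
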