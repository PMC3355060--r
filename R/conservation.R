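## Entropy-based residue conservation per alignment column, z-normalized
## across columns: positive scores mark conserved positions.

#' Raw entropy conservation of one alignment column
#'
#' Negative Shannon entropy (nats) of the amino-acid frequencies among the
#' column's non-gap symbols: a fully conserved column scores 0, and a
#' column uniform over k residue types scores `-log(k)` (at most
#' `-log(20)` for the 20 amino acids). Gaps are excluded from the counts.
#'
#' @param msa an [MSSA-class].
#' @param column column index.
#' @return raw conservation in nats (<= 0), or `NA` for an all-gap column.
#' @export
columnConservation <- function(msa, column) {
  stopifnot(is(msa, "MSSA"))
  if (column < 1L || column > alignedLength(msa))
    stop("column out of range")
  sym <- msa@aln[, column]
  sym <- sym[sym != "-"]
  if (length(sym) == 0L) return(NA_real_)
  p <- table(sym) / length(sym)
  sum(p * log(p))
}

#' Entropy-based conservation (EC) scores for all columns
#'
#' Raw per-column conservation, z-normalized by the mean and standard
#' deviation across columns with a defined score: conserved columns get
#' EC > 0, diverse columns EC < 0. All-gap columns are reported `NA` and
#' excluded from the normalization. If every column has identical raw
#' conservation, all EC scores are set to 0 with a warning.
#'
#' @param msa an [MSSA-class].
#' @param sdType `"population"` (divide by n; default) or `"sample"`
#'   (divide by n - 1).
#' @return data.frame with columns `column`, `raw`, `EC`, `n_non_gap`.
#' @export
ecScores <- function(msa, sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  L <- alignedLength(msa)
  raw <- vapply(seq_len(L), function(j) columnConservation(msa, j),
                numeric(1))
  nNonGap <- colSums(msa@aln != "-")
  def <- !is.na(raw)
  if (sum(def) < 2L)
    stop("need at least two columns with a defined conservation score")
  mu <- mean(raw[def])
  n <- sum(def)
  sdv <- if (sdType == "population")
    sqrt(sum((raw[def] - mu)^2) / n)
  else
    stats::sd(raw[def])
  ec <- rep(NA_real_, L)
  if (sdv == 0) {
    warning("all columns have identical conservation; EC set to 0")
    ec[def] <- 0
  } else {
    ec[def] <- (raw[def] - mu) / sdv
  }
  data.frame(column = seq_len(L), raw = raw, EC = ec,
             n_non_gap = as.integer(nNonGap))
}

#' Write EC scores to TSV
#'
#' @param scores data.frame from [ecScores()].
#' @param path output file.
#' @export
writeECScores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
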