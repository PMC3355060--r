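## Non-bonded pairwise energies: Coulomb + Lennard-Jones, summed over
## inter-residue atom pairs and averaged over ensemble frames.

# Molecular-mechanics Coulomb constant, kJ mol^-1 nm e^-2
.KE <- 138.935485

#' Coulomb interaction energy between two point charges
#'
#' Electrostatic pair energy in molecular-mechanics units:
#' `f * q_i * q_j / (dielectric * r)` with
#' `f = 138.935485 kJ mol^-1 nm e^-2`.
#'
#' @param qi,qj partial charges in elementary-charge units.
#' @param r separation in nm; must be positive.
#' @param dielectric relative dielectric constant (default 1, vacuum).
#' @return energy in kJ/mol; the sign follows the charge product.
#' @examples
#' coulombEnergy(1, 1, 1)        # the Coulomb constant itself
#' coulombEnergy(1, -1, 0.5)     # attractive
#' @export
coulombEnergy <- function(qi, qj, r, dielectric = 1) {
  if (any(!is.finite(qi)) || any(!is.finite(qj)) || any(!is.finite(r)) ||
      !is.finite(dielectric))
    stop("coulombEnergy: inputs must be finite")
  if (any(r <= 0)) stop("coulombEnergy: r must be positive")
  if (dielectric <= 0) stop("coulombEnergy: dielectric must be positive")
  .KE * qi * qj / (dielectric * r)
}

#' Lennard-Jones interaction energy
#'
#' `4 * epsilon * ((sigma/r)^12 - (sigma/r)^6)`: zero at `r = sigma`,
#' minimum of `-epsilon` at `r = 2^(1/6) * sigma`.
#'
#' @param sigma LJ size parameter in nm; positive.
#' @param epsilon LJ well depth in kJ/mol; non-negative.
#' @param r separation in nm; positive.
#' @return energy in kJ/mol.
#' @examples
#' ljEnergy(0.3, 0.5, 0.3)            # 0 at r = sigma
#' ljEnergy(0.3, 0.5, 0.3 * 2^(1/6))  # -epsilon at the minimum
#' @export
ljEnergy <- function(sigma, epsilon, r) {
  if (any(r <= 0)) stop("ljEnergy: r must be positive")
  if (any(sigma <= 0)) stop("ljEnergy: sigma must be positive")
  if (any(epsilon < 0)) stop("ljEnergy: epsilon must be non-negative")
  sr6 <- (sigma / r)^6
  4 * epsilon * (sr6 * sr6 - sr6)
}

#' Cross-pair Lennard-Jones parameters
#'
#' Combines per-atom sigma/epsilon into pair parameters. The default
#' Lorentz-Berthelot rule uses the arithmetic mean of sigma and the
#' geometric mean of epsilon; `"geometric"` uses geometric means for both.
#'
#' @param sigmaI,sigmaJ per-atom sigma, nm.
#' @param epsilonI,epsilonJ per-atom epsilon, kJ/mol.
#' @param rule `"lorentz-berthelot"` (default) or `"geometric"`.
#' @return list with numeric elements `sigma` and `epsilon`.
#' @export
combineLJ <- function(sigmaI, sigmaJ, epsilonI, epsilonJ,
                      rule = c("lorentz-berthelot", "geometric")) {
  rule <- match.arg(rule)
  sigma <- if (rule == "lorentz-berthelot") (sigmaI + sigmaJ) / 2
           else sqrt(sigmaI * sigmaJ)
  list(sigma = sigma, epsilon = sqrt(epsilonI * epsilonJ))
}

#' Interaction energy between two residues
#'
#' Sum over all inter-residue atom pairs of the Lennard-Jones energy plus,
#' in `"full"` mode, the Coulomb energy. Symmetric in its two arguments.
#'
#' @param atomsI,atomsJ data.frames with columns `x`, `y`, `z` (Angstrom),
#'   `charge` (e), `sigma` (nm), `epsilon` (kJ/mol); one row per atom.
#' @param mode `"full"` (Coulomb + LJ) or `"lj_only"`.
#' @param dielectric relative dielectric constant.
#' @param combiningRule passed to [combineLJ()].
#' @return energy in kJ/mol.
#' @export
residuePairEnergy <- function(atomsI, atomsJ, mode = c("full", "lj_only"),
                              dielectric = 1,
                              combiningRule = c("lorentz-berthelot",
                                                "geometric")) {
  mode <- match.arg(mode)
  combiningRule <- match.arg(combiningRule)
  if (nrow(atomsI) == 0L || nrow(atomsJ) == 0L)
    stop("residuePairEnergy: both residues must have at least one atom")
  ii <- rep(seq_len(nrow(atomsI)), times = nrow(atomsJ))
  jj <- rep(seq_len(nrow(atomsJ)), each = nrow(atomsI))
  dx <- atomsI$x[ii] - atomsJ$x[jj]
  dy <- atomsI$y[ii] - atomsJ$y[jj]
  dz <- atomsI$z[ii] - atomsJ$z[jj]
  r <- sqrt(dx^2 + dy^2 + dz^2) / 10  # Angstrom -> nm
  if (any(r == 0)) {
    k <- which(r == 0)[1]
    stop(sprintf("residuePairEnergy: overlapping atoms (atom %d of residue i, atom %d of residue j)",
                 ii[k], jj[k]))
  }
  lj <- combineLJ(atomsI$sigma[ii], atomsJ$sigma[jj],
                  atomsI$epsilon[ii], atomsJ$epsilon[jj], combiningRule)
  e <- sum(ljEnergy(lj$sigma, lj$epsilon, r))
  if (mode == "full")
    e <- e + sum(coulombEnergy(atomsI$charge[ii], atomsJ$charge[jj], r,
                               dielectric))
  e
}

# Attach force-field parameters to an atom roster; errors list every
# (residue, atom) combination without a parameter row.
.assignParams <- function(atoms, params) {
  need <- c("res_name", "atom_name", "charge_e", "sigma_nm", "epsilon_kjmol")
  if (!all(need %in% names(params)))
    stop("force-field table must have columns: ", paste(need, collapse = ", "))
  key <- paste(atoms$resName, atoms$atomName)
  pkey <- paste(params$res_name, params$atom_name)
  if (anyDuplicated(pkey))
    stop("duplicate force-field entries for: ",
         paste(unique(pkey[duplicated(pkey)]), collapse = ", "))
  hit <- match(key, pkey)
  if (anyNA(hit)) {
    miss <- sort(unique(key[is.na(hit)]))
    stop("no force-field parameters for atom(s): ",
         paste(miss, collapse = ", "))
  }
  atoms$charge  <- params$charge_e[hit]
  atoms$sigma   <- params$sigma_nm[hit]
  atoms$epsilon <- params$epsilon_kjmol[hit]
  if (any(atoms$sigma <= 0)) stop("sigma parameters must be positive")
  if (any(atoms$epsilon < 0)) stop("epsilon parameters must be non-negative")
  atoms
}

#' Build an averaged residue-residue energy matrix from an ensemble
#'
#' Computes the residue-pair interaction energy for every non-sequential
#' residue pair in every frame and averages arithmetically over frames.
#' Self pairs and sequential neighbours (|i - j| <= 1 within one chain) are
#' excluded; pairs across different chains are never excluded.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param params force-field table (data.frame with columns `res_name`,
#'   `atom_name`, `charge_e`, `sigma_nm`, `epsilon_kjmol`), e.g. from
#'   [readForceField()].
#' @param mode `"full"` or `"lj_only"`.
#' @param dielectric relative dielectric constant (default 1).
#' @param combiningRule passed to [combineLJ()].
#' @param distanceCutoff optional atom-pair distance cutoff in nm; atom
#'   pairs farther apart contribute zero. Default `NULL` sums all pairs.
#' @return an [EnergyMatrix-class].
#' @export
buildEnergyMatrix <- function(ensemble, params,
                              mode = c("full", "lj_only"),
                              dielectric = 1,
                              combiningRule = c("lorentz-berthelot",
                                                "geometric"),
                              distanceCutoff = NULL) {
  mode <- match.arg(mode)
  combiningRule <- match.arg(combiningRule)
  stopifnot(is(ensemble, "StructureEnsemble"))
  validObject(ensemble)

  # hydrogens without parameters are dropped (heavy-atom computation);
  # any other unparameterized atom is an error
  key <- paste(ensemble@atoms$resName, ensemble@atoms$atomName)
  pkey <- paste(params$res_name, params$atom_name)
  miss <- which(is.na(match(key, pkey)))
  if (length(miss)) {
    isH <- grepl("^[0-9]*H", ensemble@atoms$atomName[miss])
    if (all(isH)) {
      warning(sprintf("dropping %d unparameterized hydrogen atom(s); proceeding heavy-atom-only",
                      length(miss)))
      ensemble@atoms <- ensemble@atoms[-miss, , drop = FALSE]
      ensemble@frames <- lapply(ensemble@frames,
                                function(x) x[-miss, , drop = FALSE])
    }
  }
  atoms <- .assignParams(ensemble@atoms, params)

  nRes <- length(ensemble@residueIds)
  ri <- atoms$resIndex
  chain <- ensemble@residueChain

  # inter-residue atom pairs excluding sequential neighbours within a chain
  n <- nrow(atoms)
  if (n < 2L) stop("buildEnergyMatrix: need at least two atoms")
  ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- sequence((n - 1L):1L, from = 2L:n)
  a <- ri[ii]; b <- ri[jj]
  keep <- a != b & !(chain[a] == chain[b] & abs(a - b) <= 1L)
  ii <- ii[keep]; jj <- jj[keep]
  ra <- pmin(ri[ii], ri[jj]); rb <- pmax(ri[ii], ri[jj])
  pairKey <- (ra - 1L) * nRes + rb

  lj <- combineLJ(atoms$sigma[ii], atoms$sigma[jj],
                  atoms$epsilon[ii], atoms$epsilon[jj], combiningRule)
  qq <- atoms$charge[ii] * atoms$charge[jj]

  values <- matrix(NA_real_, nRes, nRes,
                   dimnames = list(ensemble@residueIds, ensemble@residueIds))
  resPairs <- unique(cbind(ra, rb))
  values[resPairs] <- 0
  values[resPairs[, 2:1, drop = FALSE]] <- 0

  if (length(ii)) {
    acc <- numeric(0)
    for (f in seq_along(ensemble@frames)) {
      xyz <- ensemble@frames[[f]]
      d <- sqrt((xyz[ii, 1] - xyz[jj, 1])^2 +
                (xyz[ii, 2] - xyz[jj, 2])^2 +
                (xyz[ii, 3] - xyz[jj, 3])^2) / 10  # Angstrom -> nm
      if (any(d == 0)) {
        k <- which(d == 0)[1]
        stop(sprintf(
          "buildEnergyMatrix: overlapping atoms in frame %d: %s %s (residue %s) and %s %s (residue %s)",
          f, atoms$resName[ii[k]], atoms$atomName[ii[k]],
          ensemble@residueIds[ri[ii[k]]],
          atoms$resName[jj[k]], atoms$atomName[jj[k]],
          ensemble@residueIds[ri[jj[k]]]))
      }
      inRange <- if (is.null(distanceCutoff)) rep(TRUE, length(d))
                 else d <= distanceCutoff
      e <- numeric(length(d))
      e[inRange] <- ljEnergy(lj$sigma[inRange], lj$epsilon[inRange],
                             d[inRange])
      if (mode == "full")
        e[inRange] <- e[inRange] + .KE * qq[inRange] /
          (dielectric * d[inRange])
      s <- rowsum(e, pairKey)
      if (f == 1L) {
        acc <- s
      } else {
        acc <- acc + s[rownames(acc), , drop = FALSE]
      }
    }
    acc <- acc / length(ensemble@frames)
    key <- as.integer(rownames(acc))
    pa <- (key - 1L) %/% nRes + 1L
    pb <- (key - 1L) %% nRes + 1L
    values[cbind(pa, pb)] <- acc[, 1]
    values[cbind(pb, pa)] <- acc[, 1]
  }

  new("EnergyMatrix", values = values, residueIds = ensemble@residueIds,
      chain = ensemble@residueChain, mode = mode,
      nFrames = length(ensemble@frames))
}
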