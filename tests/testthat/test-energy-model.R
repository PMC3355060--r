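# Pairwise non-bonded energies and ensemble-averaged energy matrices.

test_that("Coulomb term matches hand evaluation and scales as 1/r", {
  expect_identical(coulombEnergy(0, 1, 0.5), 0)
  expect_equal(coulombEnergy(1, 1, 1), 138.935485, tolerance = 1e-12)
  expect_equal(coulombEnergy(1, -1, 0.5), -277.87097, tolerance = 1e-7)
  # halving r doubles the energy exactly
  r <- c(0.3, 0.8, 1.7)
  expect_equal(coulombEnergy(0.4, -0.2, r / 2), 2 * coulombEnergy(0.4, -0.2, r))
  # dielectric screens linearly
  expect_equal(coulombEnergy(1, 1, 1, dielectric = 4),
               coulombEnergy(1, 1, 1) / 4)
  expect_error(coulombEnergy(1, 1, 0), "positive")
  expect_error(coulombEnergy(1, 1, -0.2), "positive")
  expect_error(coulombEnergy(NaN, 1, 1), "finite")
})

test_that("Lennard-Jones term hits its analytic anchors", {
  # V(sigma) = 0 and V(2^(1/6) sigma) = -epsilon
  expect_equal(ljEnergy(0.3, 0.5, 0.3), 0, tolerance = 1e-12)
  expect_equal(ljEnergy(0.3, 0.5, 0.3 * 2^(1 / 6)), -0.5, tolerance = 1e-12)
  expect_identical(ljEnergy(0.3, 0, 0.2), 0)
  # repulsive inside sigma, attractive outside
  expect_gt(ljEnergy(0.3, 0.5, 0.25), 0)
  expect_lt(ljEnergy(0.3, 0.5, 0.4), 0)
  expect_error(ljEnergy(0.3, 0.5, 0), "positive")
  expect_error(ljEnergy(-1, 0.5, 0.3), "positive")
})

test_that("combining rules form cross parameters as stated", {
  lb <- combineLJ(0.3, 0.5, 0.4, 0.9)
  expect_equal(lb$sigma, 0.4)
  expect_equal(lb$epsilon, sqrt(0.36))
  gg <- combineLJ(0.3, 0.5, 0.4, 0.9, rule = "geometric")
  expect_equal(gg$sigma, sqrt(0.15))
  expect_equal(gg$epsilon, sqrt(0.36))
})

atomRow <- function(x, y, z, q, s, e)
  data.frame(x = x, y = y, z = z, charge = q, sigma = s, epsilon = e)

test_that("residue pair energy reduces to the atomic case and sums pairs", {
  a <- atomRow(0, 0, 0, 0.4, 0.3, 0.5)
  b <- atomRow(10, 0, 0, -0.2, 0.35, 0.7)  # 1 nm apart
  lj <- combineLJ(0.3, 0.35, 0.5, 0.7)
  expected <- coulombEnergy(0.4, -0.2, 1) + ljEnergy(lj$sigma, lj$epsilon, 1)
  expect_equal(residuePairEnergy(a, b), expected, tolerance = 1e-12)
  # symmetric in its arguments
  expect_equal(residuePairEnergy(b, a), residuePairEnergy(a, b))
  # two atoms vs one atom: brute-force enumeration of the 2 atom pairs
  a2 <- rbind(a, atomRow(0, 4, 0, 0.1, 0.32, 0.6))
  byHand <- residuePairEnergy(a2[1, ], b) + residuePairEnergy(a2[2, ], b)
  expect_equal(residuePairEnergy(a2, b), byHand, tolerance = 1e-12)
  # zero charges and epsilon give exactly zero
  z1 <- atomRow(0, 0, 0, 0, 0.3, 0)
  z2 <- atomRow(5, 0, 0, 0, 0.3, 0)
  expect_identical(residuePairEnergy(z1, z2), 0)
  # lj_only drops the Coulomb term
  expect_equal(residuePairEnergy(a, b, mode = "lj_only"),
               ljEnergy(lj$sigma, lj$epsilon, 1), tolerance = 1e-12)
  expect_error(residuePairEnergy(a, a), "overlapping")
})

test_that("energy matrix excludes self and sequential pairs, averages frames", {
  mc <- makeToyStructure("mini_chain", nResidues = 4, spacing = 0.5,
                         charges = 0.2)
  em <- buildEnergyMatrix(mc$ensemble, mc$params)
  v <- energyValues(em)
  present <- !is.na(v)
  expect_true(all(present[cbind(c(1, 1, 2), c(3, 4, 4))]))
  expect_false(any(present[cbind(c(1, 2, 3), c(2, 3, 4))]))
  expect_false(any(present[cbind(1:4, 1:4)]))
  expect_equal(v, t(v))

  # an ensemble of identical frames equals the single-frame matrix
  mc3 <- makeToyStructure("mini_chain", nResidues = 4,
                          spacing = c(0.5, 0.5, 0.5), charges = 0.2)
  em3 <- buildEnergyMatrix(mc3$ensemble, mc3$params)
  expect_equal(energyValues(em3), v)
  expect_equal(nFrames(em3), 3L)

  # two frames average arithmetically: (x + y) / 2
  tp <- makeToyStructure("two_particles", r = c(0.5, 0.8),
                         charges = c(0.3, -0.3))
  x <- residuePairEnergy(atomRow(0, 0, 0, 0.3, 0.33, 0.5),
                         atomRow(5, 0, 0, -0.3, 0.33, 0.5))
  y <- residuePairEnergy(atomRow(0, 0, 0, 0.3, 0.33, 0.5),
                         atomRow(8, 0, 0, -0.3, 0.33, 0.5))
  em2 <- buildEnergyMatrix(tp$ensemble, tp$params)
  expect_equal(energyValues(em2)[1, 2], (x + y) / 2, tolerance = 1e-12)
})

test_that("matrix construction matches a naive atom-pair double loop", {
  set.seed(7)
  # 3 residues x up to 4 atoms each in one chain, plus 2 single-atom
  # residues on a second chain
  nAtoms <- c(3, 4, 2, 1, 1)
  resChain <- c("A", "A", "A", "B", "B")
  atoms <- data.frame(
    atomName = unlist(lapply(nAtoms, function(k) sprintf("X%d", seq_len(k)))),
    resName = rep(sprintf("R%d", 1:5), nAtoms),
    resIndex = rep(1:5, nAtoms),
    chain = rep(resChain, nAtoms))
  coords <- matrix(runif(sum(nAtoms) * 3, 0, 15), ncol = 3)
  ens <- new("StructureEnsemble", atoms = atoms, frames = list(coords),
             residueIds = sprintf("%s:%d", resChain, 1:5),
             residueChain = resChain)
  params <- data.frame(res_name = atoms$resName, atom_name = atoms$atomName,
                       charge_e = runif(sum(nAtoms), -0.5, 0.5),
                       sigma_nm = runif(sum(nAtoms), 0.25, 0.4),
                       epsilon_kjmol = runif(sum(nAtoms), 0.1, 1))
  em <- buildEnergyMatrix(ens, params)

  # oracle: naive loop over every atom pair
  oracle <- matrix(0, 5, 5)
  for (p in seq_len(sum(nAtoms) - 1)) for (q in (p + 1):sum(nAtoms)) {
    i <- atoms$resIndex[p]; j <- atoms$resIndex[q]
    if (i == j) next
    if (resChain[i] == resChain[j] && abs(i - j) <= 1) next
    rnm <- sqrt(sum((coords[p, ] - coords[q, ])^2)) / 10
    s <- (params$sigma_nm[p] + params$sigma_nm[q]) / 2
    e <- sqrt(params$epsilon_kjmol[p] * params$epsilon_kjmol[q])
    val <- 4 * e * ((s / rnm)^12 - (s / rnm)^6) +
      138.935485 * params$charge_e[p] * params$charge_e[q] / rnm
    oracle[i, j] <- oracle[i, j] + val
    oracle[j, i] <- oracle[i, j]
  }
  v <- energyValues(em)
  for (i in 1:4) for (j in (i + 1):5) {
    excluded <- i == j - 1 && resChain[i] == resChain[j]
    if (excluded) expect_true(is.na(v[i, j]))
    else expect_equal(v[i, j], oracle[i, j], tolerance = 1e-9)
  }

  # lj_only equals full mode with all charges zeroed
  paramsZ <- params
  paramsZ$charge_e <- 0
  expect_equal(energyValues(buildEnergyMatrix(ens, params, mode = "lj_only")),
               energyValues(buildEnergyMatrix(ens, paramsZ)),
               tolerance = 1e-12)

  # missing parameters name the offending atom
  expect_error(buildEnergyMatrix(ens, params[-2, ]),
               "no force-field parameters for atom")
  expect_error(buildEnergyMatrix(ens, params[-2, ]), "R1 X2")
})

test_that("unparameterized hydrogens are dropped with a warning", {
  tp <- makeToyStructure("two_particles", r = 0.5, charges = c(0.2, -0.2))
  ens <- tp$ensemble
  ens@atoms <- rbind(ens@atoms,
                     data.frame(atomName = "H1", resName = "TPA",
                                resIndex = 1L, chain = "A"))
  ens@frames <- lapply(ens@frames, function(f) rbind(f, c(0, 1, 0)))
  expect_warning(emH <- buildEnergyMatrix(ens, tp$params),
                 "hydrogen")
  em <- buildEnergyMatrix(tp$ensemble, tp$params)
  expect_equal(energyValues(emH), energyValues(em))
})

test_that("energy matrices survive a TSV round trip", {
  fam <- makeFamily(M = 2, L = 12, nPlanted = 3, gapRate = 0, seed = 5)
  em <- fam$matrices[[1]]
  path <- tempfile(fileext = ".tsv")
  writeEnergyMatrix(em, path)
  back <- readEnergyMatrix(path)
  expect_equal(energyValues(back), energyValues(em), tolerance = 1e-10)
  expect_identical(residueIds(back), residueIds(em))
  expect_identical(energyMode(back), energyMode(em))
  # long format lists each present pair once
  pathL <- tempfile(fileext = ".tsv")
  writeEnergyMatrix(em, pathL, format = "long")
  long <- read.table(pathL, header = TRUE, sep = "\t")
  expect_equal(nrow(long), sum(!is.na(energyValues(em))) / 2)
})

test_that("multi-MODEL PDB files are read as ensembles", {
  resdef <- data.frame(atom = "X", res = c("TPA", "TPB"),
                       chain = c("A", "B"), resno = c(1L, 1L))
  # frame separations 0.5 nm and 0.8 nm along x
  path <- tempfile(fileext = ".pdb")
  writeToyPDB(path, resdef,
              list(rbind(c(0, 0, 0), c(5, 0, 0)),
                   rbind(c(0, 0, 0), c(8, 0, 0))))
  ens <- readPDBEnsemble(path)
  expect_equal(nFrames(ens), 2L)
  expect_identical(residueIds(ens), c("A:1", "B:1"))
  tp <- makeToyStructure("two_particles", r = c(0.5, 0.8),
                         charges = c(0.3, -0.3))
  emPDB <- buildEnergyMatrix(ens, tp$params)
  emDirect <- buildEnergyMatrix(tp$ensemble, tp$params)
  expect_equal(energyValues(emPDB), energyValues(emDirect),
               tolerance = 1e-6, ignore_attr = TRUE)
})
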