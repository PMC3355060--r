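# MSSA ingestion, network remapping with virtual nodes, commonality
# coefficients and family-level clusters and hubs.

test_that("aligned FASTA round-trips into column-residue mappings", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">s1", "VLKY--AD", ">s2", "LCIKVEAD"), path)
  msa <- readMSSA(path)
  expect_equal(memberIds(msa), c("s1", "s2"))
  expect_equal(alignedLength(msa), 8L)
  map <- residueMapping(msa)
  expect_equal(unname(map["s1", ]), c(1L, 2L, 3L, 4L, NA, NA, 5L, 6L))
  expect_equal(unname(map["s2", ]), 1:8)
  out <- tempfile(fileext = ".fasta")
  writeMSSA(msa, out)
  expect_equal(residueMapping(readMSSA(out)), map)
  # single ungapped record maps 1..n identically
  one <- mssa(c(solo = "ACDEFGHI"))
  expect_equal(unname(residueMapping(one)[1, ]), 1:8)
})

test_that("malformed alignments are rejected", {
  expect_error(mssa(c(a = "AC-", b = "ACDE")), "same length")
  expect_error(mssa(c(a = "ACD", a = "ACD")), "duplicate")
  expect_error(mssa(c(a = "----", b = "ACDE")), "gaps")
  expect_error(mssa(c("ACD", "ACD")), "named")
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACD", ">b", "ACDE"), path)
  expect_error(readMSSA(path), "length")
})

test_that("remapping relabels edges and gives virtual nodes zero degree", {
  msa <- mssa(c(s1 = "VLKY--AD", s2 = "LCIKVEAD"))
  # member s1: 6 residues, edges (1,4) and (2,6) in residue space
  em1 <- memberMatrix(6, rbind(c(1, 4), c(2, 6)))
  net1 <- thresholdNetwork(em1, -10)
  rem1 <- remapPEN(net1, msa, "s1")
  expect_equal(alignedLength(rem1), 8L)
  expect_equal(virtualNodes(rem1), c(5L, 6L))
  adj <- adjacencyMatrix(rem1)
  # residue pair (1,4) -> columns (1,4); (2,6) -> columns (2,8)
  expect_true(adj[1, 4] && adj[2, 8])
  expect_equal(sum(adj) / 2, nrow(networkEdges(net1)))
  # gap columns have degree zero
  expect_equal(unname(rowSums(adj)[5:6]), c(0, 0))
  # ungapped member: pure relabelling, same edge count
  em2 <- memberMatrix(8, rbind(c(1, 4), c(3, 7)))
  rem2 <- remapPEN(thresholdNetwork(em2, -10), msa, "s2")
  expect_equal(sum(adjacencyMatrix(rem2)) / 2, 2)
  expect_equal(dim(adjacencyMatrix(rem2)), dim(adj))
  # node count inconsistent with the mapping
  expect_error(remapPEN(net1, msa, "s2"), "8 nodes|maps 8")
  expect_error(remapPEN(net1, msa, "nope"), "not in the alignment")
})

test_that("remapped energies carry the +100 sentinel at virtual pairs", {
  msa <- mssa(c(s1 = "VLKY--AD", s2 = "LCIKVEAD"))
  em1 <- memberMatrix(6, rbind(c(1, 4)))
  v <- remapEnergyMatrix(em1, msa, "s1")
  expect_equal(dim(v), c(8L, 8L))
  expect_true(all(v[5:6, -c(5, 6)] == 100))
  expect_equal(v[1, 4], -20)
  expect_true(is.na(v[1, 2]))  # sequential exclusion survives remapping
  # a virtual pair can never pass a realistic cutoff
  expect_true(all(v[5, -c(5, 6)] > -10))
})

test_that("commonality counts the members carrying each aligned edge", {
  msa <- mssa(c(s1 = "VLKY--AD", s2 = "LCIKVEAD"))
  # the aligned edge columns (1,4) is present in both members; (2,8)
  # only in s1
  em1 <- memberMatrix(6, rbind(c(1, 4), c(2, 6)))
  em2 <- memberMatrix(8, rbind(c(1, 4)))
  fn <- familyNetwork(msa, list(s1 = em1, s2 = em2), e = -10)
  cc <- ccMatrix(fn$family)
  expect_equal(cc[1, 4], 1.0)     # X = 2, M = 2
  expect_equal(cc[2, 8], 0.5)     # X = 1
  expect_equal(cc[3, 6], 0)       # absent everywhere
  expect_equal(familySize(fn$family), 2L)
  # cc * M is always integral
  expect_true(all(abs(cc * 2 - round(cc * 2)) < 1e-12))
  # edge present in 1 of 4 members has cc = 0.25
  msa4 <- mssa(c(a = "AAAAAA", b = "CCCCCC", d = "DDDDDD", e = "EEEEEE"))
  ems <- list(a = memberMatrix(6, rbind(c(1, 5))),
              b = memberMatrix(6, NULL), d = memberMatrix(6, NULL),
              e = memberMatrix(6, NULL))
  fn4 <- familyNetwork(msa4, ems, e = -10)
  expect_equal(ccMatrix(fn4$family)[1, 5], 0.25)
  # mixed cutoffs are rejected
  r1 <- remapPEN(thresholdNetwork(em1, -10), msa, "s1")
  r2 <- remapPEN(thresholdNetwork(em2, -15), msa, "s2")
  expect_error(commonality(list(r1, r2)), "cutoff")
  expect_error(commonality(list(r1)), "two members")
})

test_that("family edges are nested in cc and recover common/union sets", {
  msa <- mssa(c(s1 = "VLKY--AD", s2 = "LCIKVEAD"))
  em1 <- memberMatrix(6, rbind(c(1, 4), c(2, 6)))
  em2 <- memberMatrix(8, rbind(c(1, 4), c(3, 7)))
  fam <- familyNetwork(msa, list(s1 = em1, s2 = em2), e = -10)$family
  # cc = 1 keeps exactly the edges common to both structures
  common <- fpenEdges(fam, 1.0)
  expect_equal(common[, c("col_a", "col_b")],
               data.frame(col_a = 1L, col_b = 4L))
  expect_equal(common$X, 2L)
  # cc -> 0+ gives the union of member edges
  expect_equal(nrow(fpenEdges(fam, 1e-9)), 3L)
  # nestedness in the threshold
  for (cc in c(0.25, 0.5, 0.75, 1)) {
    lo <- fpenEdges(fam, cc)
    hi <- fpenEdges(fam, min(cc + 0.25, 1))
    expect_true(all(paste(hi$col_a, hi$col_b) %in% paste(lo$col_a, lo$col_b)))
  }
  expect_error(fpenEdges(fam, 0), "\\(0, 1\\]")
  expect_error(fpenEdges(fam, 1.5), "\\(0, 1\\]")
  # an all-zero commonality matrix yields no edges
  none <- familyNetwork(msa, list(s1 = memberMatrix(6, NULL),
                                  s2 = memberMatrix(8, NULL)), e = -10)$family
  expect_equal(nrow(fpenEdges(none, 0.5)), 0L)
})

test_that("adding members moves cc in the documented direction", {
  msa3 <- mssa(c(a = "AAAAAA", b = "CCCCCC", d = "DDDDDD"))
  withEdge <- memberMatrix(6, rbind(c(2, 5)))
  without <- memberMatrix(6, NULL)
  two <- mssa(c(a = "AAAAAA", b = "CCCCCC"))
  ccTwo <- ccMatrix(familyNetwork(two, list(a = withEdge, b = withEdge),
                                  e = -10)$family)[2, 5]
  ccLack <- ccMatrix(familyNetwork(msa3,
                                   list(a = withEdge, b = withEdge,
                                        d = without), e = -10)$family)[2, 5]
  ccGain <- ccMatrix(familyNetwork(msa3,
                                   list(a = withEdge, b = withEdge,
                                        d = withEdge), e = -10)$family)[2, 5]
  expect_lt(ccLack, ccTwo)    # a member lacking the edge strictly lowers cc
  expect_equal(ccGain, ccTwo) # one carrying it keeps cc at 1 here
})

test_that("family clusters apply the size-three rule over columns", {
  msa <- mssa(c(a = "AAAAAAAA", b = "CCCCCCCC"))
  clique4 <- rbind(c(1, 3), c(1, 5), c(1, 7), c(3, 5), c(3, 7), c(5, 7))
  em <- memberMatrix(8, clique4)
  fam <- familyNetwork(msa, list(a = em, b = em), e = -10)$family
  cs <- familyClusters(fam, 1.0)
  expect_equal(clusters(cs), list(c("c001", "c003", "c005", "c007")))
  # two disjoint conserved pairs are not clusters
  pairs <- memberMatrix(8, rbind(c(1, 3), c(5, 7)))
  famP <- familyNetwork(msa, list(a = pairs, b = pairs), e = -10)$family
  expect_equal(length(clusters(familyClusters(famP, 1.0))), 0L)
  # empty family network
  famE <- familyNetwork(msa, list(a = memberMatrix(8, NULL),
                                  b = memberMatrix(8, NULL)), e = -10)$family
  expect_equal(length(clusters(familyClusters(famE, 1.0))), 0L)
})

test_that("family hubs require the degree in enough members", {
  msa <- mssa(c(a = "AAAAAAAA", b = "CCCCCCCC", d = "DDDDDDDD",
                e = "EEEEEEEE"))
  # column 1 has degree 3 via edges to columns 3, 5, 7
  hubEdges <- rbind(c(1, 3), c(1, 5), c(1, 7))
  withHub <- memberMatrix(8, hubEdges)
  without <- memberMatrix(8, rbind(c(2, 6)))
  mk <- function(mats) familyNetwork(msa, mats, e = -10)$remapped
  # hub in all members at fraction 1.0
  all4 <- mk(list(a = withHub, b = withHub, d = withHub, e = withHub))
  expect_equal(familyHubs(all4, memberFraction = 1.0)$column, 1L)
  # hub in 2 of 4 members fails fraction 0.7
  two4 <- mk(list(a = withHub, b = withHub, d = without, e = without))
  expect_equal(nrow(familyHubs(two4, memberFraction = 0.7)), 0L)
  expect_equal(familyHubs(two4, memberFraction = 0.5)$column, 1L)
  expect_error(familyHubs(all4, memberFraction = 0), "\\(0, 1\\]")
})

test_that("family hub calls match a brute-force per-member degree tally", {
  set.seed(77)
  fam <- makeFamily(M = 6, L = 30, nPlanted = 6, privateEdgeRate = 4,
                    gapRate = 0.1, seed = 31)
  fn <- familyNetwork(fam$mssa, fam$matrices, e = -8)
  for (frac in c(0.5, 0.7, 1.0)) {
    got <- familyHubs(fn$remapped, degreeMin = 3, memberFraction = frac)
    expected <- integer(0)
    for (col in 1:30) {
      nHub <- 0
      for (r in fn$remapped)
        if (sum(adjacencyMatrix(r)[col, ]) >= 3) nHub <- nHub + 1
      if (nHub / length(fn$remapped) >= frac - 1e-12)
        expected <- c(expected, col)
    }
    expect_equal(got$column, expected)
  }
})
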