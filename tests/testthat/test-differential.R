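mkResult <- function(method, z, kind = NULL, raw = NULL) {
  labels <- names(z)
  if (is.null(kind)) kind <- rep("residue", length(z))
  new("CentralityResult", method = method,
      table = data.frame(label = labels, kind = kind, chain = "A",
                         interface = FALSE,
                         raw = if (is.null(raw)) unname(z) else raw,
                         z = unname(z)),
      metadata = list(structureId = "toy"))
}

test_that("added and lost central sets are plain set differences", {
  wet <- mkResult("RCA", c(A = 2.5, B = 3, W1 = 2.2, C = 1.0),
                  kind = c("residue", "residue", "water", "residue"))
  dry <- mkResult("RCA", c(A = 1.5, B = 3, C = 2.4))
  d <- diffCentral(wet, dry)
  expect_setequal(d$added, c("A", "W1"))
  expect_setequal(d$lost, "C")
  expect_length(intersect(d$added, d$lost), 0)
  # identical central sets -> both empty
  same <- diffCentral(dry, dry)
  expect_length(same$added, 0)
  expect_length(same$lost, 0)
  expect_error(diffCentral(wet, mkResult("BCA", c(A = 1))), "method mismatch")
})

test_that("union and intersection across methods are plain set algebra", {
  comb <- combineMethods(c("a", "b"), c("b", "c"))
  expect_equal(comb$union, c("a", "b", "c"))
  expect_equal(comb$intersection, "b")
  disj <- combineMethods(c("a"), c("b"))
  expect_length(disj$intersection, 0)
  expect_setequal(disj$union, c("a", "b"))
  # report consistency: |union| <= |added_rca| + |added_bca|
  expect_lte(length(comb$union), 4)
})

test_that("deltaZ statistics cover residues only and use population SD", {
  wet <- mkResult("RCA", c(A = 1, B = -1, W = -0.4),
                  kind = c("residue", "residue", "water"))
  dry <- mkResult("RCA", c(A = 0, B = 0))
  st <- deltaZStats(wet, dry)
  expect_equal(st$deltaZ$deltaZ, c(1, -1))
  expect_equal(st$muDeltaZ, 0)
  expect_equal(st$sigmaDeltaZ, 1)
  expect_equal(st$muWaterZ, -0.4)
  expect_equal(st$sigmaWaterZ, 0)
  # identical analyses -> exact zero shift
  st0 <- deltaZStats(dry, dry)
  expect_identical(st0$muDeltaZ, 0)
  expect_identical(st0$sigmaDeltaZ, 0)
  expect_true(is.na(st0$muWaterZ))
  onlyW <- mkResult("RCA", c(W = 1), kind = "water")
  expect_error(deltaZStats(onlyW, dry), "no residue nodes")
})

test_that("added-residue shift is measured in global deltaZ SDs", {
  wet <- mkResult("RCA", c(A = 2.2, B = -1, C = 0.0, W = 0),
                  kind = c("residue", "residue", "residue", "water"))
  dry <- mkResult("RCA", c(A = 1.0, B = 1.2, C = 0.0))
  st <- deltaZStats(wet, dry)
  # deltaZ = (1.2, -2.2, 0): mu = -1/3, sigma = popSD
  sh <- addedResidueShift(c("A", "W"), st)  # water ignored
  expect_equal(sh, (1.2 - st$muDeltaZ) / st$sigmaDeltaZ)
  # added mean equal to the global mean -> shift 0
  expect_equal(addedResidueShift(c("A", "B", "C"), st), 0, tolerance = 1e-12)
  expect_error(addedResidueShift(character(), st), "no added residue")
  degenerate <- deltaZStats(dry, dry)
  expect_warning(s0 <- addedResidueShift("A", degenerate), "zero")
  expect_true(is.na(s0))
})

test_that("interface restriction counts union members at the interface", {
  wetR <- mkResult("RCA", c(a = 3, b = 2.5, c = 1))
  dryR <- mkResult("RCA", c(a = 1, b = 1, c = 1))
  wetB <- mkResult("BCA", c(a = 1, b = 2.5, c = 2.1))
  dryB <- mkResult("BCA", c(a = 1, b = 1, c = 1))
  rep <- differentialReport(wetR, dryR, wetB, dryB)
  expect_setequal(rep@combined$union, c("a", "b", "c"))
  expect_setequal(rep@combined$intersection, "b")
  rep <- interfaceReport(rep, c("b", "c", "d"))
  expect_equal(rep@metadata$interfaceUnionCount, 2)
  rep0 <- interfaceReport(differentialReport(dryR, dryR, dryB, dryB),
                          c("b", "c"))
  expect_equal(rep0@metadata$interfaceUnionCount, 0)
})

test_that("exclusion policy filters reported sets but never statistics", {
  set.seed(13)
  s <- generateComplex(synthParams(nResPerChain = 10, nWaters = 20, seed = 13))
  wet <- buildRIN(s, "wet"); dry <- buildRIN(s, "dry")
  wr <- rca(wet); dr <- rca(dry); wb <- bca(wet); db <- bca(dry)
  plain <- differentialReport(wr, dr, wb, db)
  excl <- differentialReport(wr, dr, wb, db,
                             exclude = union(plain@rca$added, plain@bca$added))
  expect_length(excl@rca$added, 0)
  expect_length(excl@combined$union, 0)
  expect_identical(excl@rca$stats, plain@rca$stats)
  expect_identical(excl@bca$stats, plain@bca$stats)
  expect_identical(excl@rca$addedShift, plain@rca$addedShift)
  expect_identical(excl@rca$deltaZ, plain@rca$deltaZ)
  expect_equal(hisTagExclusion("A", 92:94),
               c("His92.A", "His93.A", "His94.A"))
})

test_that("deltaZ statistics are invariant under node relabeling", {
  z1 <- c(A = 1.4, B = -0.2, C = 0.7, D = 2.3)
  z2 <- c(A = 0.8, B = 0.1, C = 0.2, D = 1.9)
  st <- deltaZStats(mkResult("RCA", z1), mkResult("RCA", z2))
  perm <- c(A = "Q", B = "R", C = "S", D = "T")
  relab <- function(z) setNames(z, perm[names(z)])
  st2 <- deltaZStats(mkResult("RCA", relab(z1)), mkResult("RCA", relab(z2)))
  expect_equal(st2$muDeltaZ, st$muDeltaZ)
  expect_equal(st2$sigmaDeltaZ, st$sigmaDeltaZ)
})

test_that("removing an isolated water cannot change raw centralities", {
  s <- mkStructure(list(
    res1("A", 1, "ALA", 0), res1("A", 2, "GLY", 3.8),
    res1("A", 3, "LEU", 7.6), res1("A", 4, "ILE", 11.4),
    res1("B", 1, "VAL", 3.8, 4, 0),
    res1("A", 100, "HOH", 50)))  # far from everything: degree 0
  wet <- buildRIN(s, "wet")
  expect_equal(unname(nodeDegrees(wet)["Hoh100.A"]), 0L)
  reduced <- removeWaterNodes(wet, "explicit", labels = "Hoh100.A")
  for (fn in list(rca, bca)) {
    before <- centralityTable(fn(wet))
    after <- centralityTable(fn(reduced))
    # an isolated node is on no shortest path between others: raw unchanged
    expect_equal(after$raw,
                 before$raw[match(after$label, before$label)])
  }
  # away from the Z = 2 boundary the central residue sets also agree
  out <- waterRemovalExperiment(wet, "explicit", labels = "Hoh100.A")
  expect_true(out$RCA$identical)
  expect_true(out$BCA$identical)
  expect_length(out$RCA$symmetricDifference, 0)
})

test_that("a bridging water changes raw values but set equality is what is compared", {
  # two residue triangles joined only through one water node
  nodes <- data.frame(
    label = c("Ra.A", "Rb.A", "Rc.A", "Rd.B", "Re.B", "Rf.B", "Hoh1.A"),
    kind = c(rep("residue", 6), "water"))
  e <- rbind(
    data.frame(from = c("Ra.A", "Rb.A", "Ra.A"), to = c("Rb.A", "Rc.A", "Rc.A")),
    data.frame(from = c("Rd.B", "Re.B", "Rd.B"), to = c("Re.B", "Rf.B", "Rf.B")),
    data.frame(from = "Hoh1.A", to = c("Rc.A", "Rd.B")))
  wet <- RIN(nodes, e, metadata = list(variant = "wet"))
  out <- waterRemovalExperiment(wet, "max_degree")
  expect_equal(out$removed, "Hoh1.A")
  # raw RCA values do change with the bridge removed...
  before <- centralityTable(rca(wet))
  after <- centralityTable(rca(removeWaterNodes(wet, "max_degree")))
  expect_false(isTRUE(all.equal(
    before$raw[match("Rc.A", before$label)],
    after$raw[match("Rc.A", after$label)])))
  # ...and the comparison is made on central residue sets, waters excluded
  expect_type(out$RCA$identical, "logical")
  expect_false("Hoh1.A" %in% c(out$RCA$before, out$RCA$after))
})
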